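#' Alignment filter policies for the two mapping phases
#'
#' Both phases keep only reads that (i) map uniquely to one location,
#' (ii) have mapping quality >= 30, and (iii) have a small edit distance:
#' at most 3 for whole reads (phase 1), at most 1 for the shorter split
#' fragments (phase 2).
#'
#' @param phase 1 (whole reads) or 2 (split fragments).
#' @param min_mapq,max_nm,require_unique Override individual thresholds.
#' @return List with `min_mapq`, `max_nm`, `require_unique`.
#' @export
filter_policy <- function(phase = 1, min_mapq = 30L,
                          max_nm = if (phase == 1) 3L else 1L,
                          require_unique = TRUE) {
  stopifnot(phase %in% 1:2)
  list(min_mapq = as.integer(min_mapq), max_nm = as.integer(max_nm),
       require_unique = isTRUE(require_unique))
}

#' Apply a filter policy to alignment records
#'
#' A record passes iff it is unique (when required), its mapping quality is at
#' least `min_mapq`, and its edit distance at most `max_nm`.  Records with a
#' missing edit-distance annotation fail.
#'
#' @param rec data.frame of alignment records with columns `mapq`, `nm`,
#'   `unique` (see [naive_align] / [read_sam_alignments]).
#' @param policy A [filter_policy].
#' @return Logical vector along the rows of `rec`.
#' @export
pass_filter <- function(rec, policy) {
  ok_unique <- if (policy$require_unique) rec$unique %in% TRUE else TRUE
  ok_q <- !is.na(rec$mapq) & rec$mapq >= policy$min_mapq
  ok_nm <- !is.na(rec$nm) & rec$nm <= policy$max_nm
  ok_unique & ok_q & ok_nm
}

.empty_alignments <- function() {
  data.frame(qname = character(), end = integer(), fragment = character(),
             chrom = character(), pos = numeric(), strand = character(),
             mapq = integer(), nm = integer(), unique = logical(),
             stringsAsFactors = FALSE)
}

#' Exact-match aligner for self-contained tests and simulations
#'
#' Finds every exact occurrence of `fragment` on both strands of `genome`.
#' This is a deliberately simple stand-in for an external short-read aligner,
#' adequate for error-free simulated reads: exact hits get mapping quality 60
#' and edit distance 0, and the `unique` flag is set iff exactly one
#' occurrence exists genome-wide.
#'
#' The reported position `pos` is the 0-based genomic coordinate of the
#' *5' base of the read*: the leftmost matched base for `+` hits, the
#' rightmost for `-` hits.
#'
#' @param fragment DNA string to align.
#' @param genome A [Biostrings::DNAStringSet] (names = chromosomes) or FASTA
#'   path.
#' @param qname,end,frag_label Provenance stored in the records (read id,
#'   end index 1/2, fragment label "whole"/"left"/"right").
#' @return data.frame of alignment records (possibly 0 rows) with columns
#'   `qname`, `end`, `fragment`, `chrom`, `pos`, `strand`, `mapq`, `nm`,
#'   `unique`.
#' @export
naive_align <- function(fragment, genome, qname = "", end = 1L,
                        frag_label = "whole") {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  fragment <- as.character(fragment)
  fwd <- Biostrings::DNAString(fragment)
  rev <- Biostrings::reverseComplement(fwd)
  hits <- list()
  for (cn in names(genome)) {
    subj <- genome[[cn]]
    fs <- Biostrings::start(Biostrings::matchPattern(fwd, subj, fixed = TRUE))
    if (length(fs))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = cn, pos = fs - 1, strand = "+", stringsAsFactors = FALSE)
    rn <- Biostrings::matchPattern(rev, subj, fixed = TRUE)
    if (length(rn))
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = cn, pos = Biostrings::end(rn) - 1, strand = "-",
        stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(.empty_alignments())
  hits <- do.call(rbind, hits)
  data.frame(qname = qname, end = as.integer(end), fragment = frag_label,
             chrom = hits$chrom, pos = hits$pos, strand = hits$strand,
             mapq = 60L, nm = 0L, unique = nrow(hits) == 1L,
             stringsAsFactors = FALSE)
}

#' Read external aligner output (SAM/BAM) into alignment records
#'
#' Consumes standard SAM or BAM from a short-read aligner run on whole read
#' ends (phase 1) or on split fragments (phase 2).  Read names are expected to
#' carry provenance suffixes: `/1` or `/2` for the read end, and `:L` / `:R`
#' appended *before* the end suffix for the left/right split fragment (e.g.
#' `read7:L/2`); names without `:L`/`:R` are whole-read alignments.
#'
#' Uniqueness uses the aligner's alternative-hit annotations when present:
#' a record is unique iff it is a primary, non-supplementary alignment and
#' (`X0` tag == 1 if present, else no `XA` tag).  Edit distance is the `NM`
#' tag (missing `NM` fails downstream filters).  `pos` is converted to the
#' 0-based 5'-base convention used throughout.
#'
#' @param path SAM or BAM file.
#' @return data.frame of alignment records as in [naive_align].
#' @export
read_sam_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "cigar"),
    tag = c("NM", "X0", "XA"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(b$pos)
  if (!any(keep)) return(.empty_alignments())
  flag <- b$flag[keep]
  secondary <- bitwAnd(flag, 256L) > 0L
  supplementary <- bitwAnd(flag, 2048L) > 0L
  x0 <- b$tag$X0[keep]
  xa <- b$tag$XA[keep]
  uniq <- !secondary & !supplementary &
    (if (!is.null(x0)) ifelse(is.na(x0), is.null(xa) | is.na(xa), x0 == 1L)
     else if (!is.null(xa)) is.na(xa) else TRUE)
  qn <- b$qname[keep]
  end <- ifelse(grepl("/2$", qn), 2L, 1L)
  base <- sub("/[12]$", "", qn)
  fragment <- ifelse(grepl(":L$", base), "left",
                     ifelse(grepl(":R$", base), "right", "whole"))
  qname <- sub(":[LR]$", "", base)
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[keep])
  strand <- as.character(b$strand[keep])
  pos0 <- b$pos[keep] - 1                       # 0-based leftmost
  pos5 <- ifelse(strand == "-", pos0 + width - 1, pos0)
  nm <- b$tag$NM[keep]
  if (is.null(nm)) nm <- rep(NA_integer_, sum(keep))
  data.frame(qname = qname, end = end, fragment = fragment,
             chrom = as.character(b$rname[keep]), pos = pos5,
             strand = strand, mapq = b$mapq[keep], nm = nm, unique = uniq,
             stringsAsFactors = FALSE)
}

#' Remove PCR duplicate read pairs
#'
#' Optional: drops contacts from read pairs whose full locus signature
#' (chromosome, position, strand of every mapped locus) is identical to an
#' earlier read pair.  Off by default in the pipeline.
#'
#' @param contacts A contact table (see [enumerate_contacts]).
#' @return The contact table with duplicate-signature reads removed.
#' @export
remove_pcr_duplicates <- function(contacts) {
  if (!nrow(contacts)) return(contacts)
  sig_cols <- grep("^(chr|pos|strand)[0-9]$", names(contacts), value = TRUE)
  key <- apply(contacts[, sig_cols, drop = FALSE], 1, paste, collapse = "|")
  read_sig <- tapply(key, contacts$read_id, function(k) paste(sort(k),
                                                              collapse = ";"))
  keep_reads <- names(read_sig)[!duplicated(read_sig)]
  contacts[contacts$read_id %in% keep_reads, , drop = FALSE]
}
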