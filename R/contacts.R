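#' Classify one read end after two-phase mapping
#'
#' Status `F`: the whole read end passed the phase-1 filter.  Otherwise, if
#' the read contains exactly one cleavage site, its split fragments that
#' passed the phase-2 filter determine the status: `P2` (both fragments
#' mapped), `P1` (one), `none` (neither).  Reads with zero sites are not
#' chimeric, and reads with two or more sites are discarded, so both give
#' `none` when the whole read did not map.
#'
#' @param phase1 data.frame of *passing* phase-1 (whole-read) records for
#'   this end (0 or 1 rows).
#' @param phase2 data.frame of *passing* phase-2 (fragment) records for this
#'   end.
#' @param n_sites Cleavage-site count of the read.
#' @return List with `status` in `c("F","P1","P2","none")` and `loci`, a
#'   data.frame (chrom, pos, strand, fragment).
#' @export
classify_end <- function(phase1, phase2, n_sites) {
  if (!is.null(phase1) && nrow(phase1) >= 1L) {
    if (nrow(phase1) > 1L) stop("conflicting whole-read records for one end")
    return(list(status = "F",
                loci = phase1[, c("chrom", "pos", "strand", "fragment")]))
  }
  if (is.na(n_sites) || n_sites != 1L || is.null(phase2) || !nrow(phase2))
    return(list(status = "none",
                loci = data.frame(chrom = character(), pos = numeric(),
                                  strand = character(), fragment = character(),
                                  stringsAsFactors = FALSE)))
  if (anyDuplicated(phase2$fragment))
    stop("conflicting records for the same split fragment")
  phase2 <- phase2[order(match(phase2$fragment, c("left", "right"))), ,
                   drop = FALSE]
  list(status = if (nrow(phase2) == 2L) "P2" else "P1",
       loci = phase2[, c("chrom", "pos", "strand", "fragment")])
}

.empty_contacts <- function() {
  df <- data.frame(read_id = character(), arity = integer(),
                   class = character(), span = character(),
                   signature = character(), stringsAsFactors = FALSE)
  for (i in 1:4) {
    df[[paste0("chr", i)]] <- character()
    df[[paste0("pos", i)]] <- numeric()
    df[[paste0("strand", i)]] <- character()
    df[[paste0("prov", i)]] <- character()
  }
  df
}

.span_class <- function(chroms) {
  u <- length(unique(chroms))
  if (u == 1L) "intra" else if (u == length(chroms)) "inter" else "mixed"
}

#' Per-end read-orientation signature
#'
#' Concatenates the mapped strand signs of each end's fragments (left then
#' right for split ends), the two ends separated by "/": e.g. `"+/-"` for a
#' fully-mapped pair, `"++/-"` for a split end plus a fully-mapped end.
#' Religation-free chimeric contacts at distance > 1 kb are expected to be
#' distributed uniformly over the sign combinations, whereas unligated
#' sonication products concentrate on inward-pointing combinations; this
#' signature is the basis of that diagnostic.
#'
#' @param end1,end2 [classify_end] results.
#' @return Character signature.
#' @export
orientation_signature <- function(end1, end2) {
  paste(paste(end1$loci$strand, collapse = ""),
        paste(end2$loci$strand, collapse = ""), sep = "/")
}

#' Enumerate multi-locus contacts from a classified read pair
#'
#' With `L` the union of mapped loci over both ends, emits every subset of
#' size 2 (doubles), 3 (triples) and 4 (quadruples) of `L`.  A pair of
#' fully-mapped ends yields one double; a split end with two mapped fragments
#' plus a fully-mapped end yields three doubles and one triple; two split
#' ends with two mapped fragments each yield six doubles, four triples and
#' one quadruple.
#'
#' The contact class reflects the pair's mapping route: `F-F` when both
#' contributing ends mapped fully, `P-F` when a split end combines with a
#' fully-mapped end, `P-P` when only split ends contribute.  Loci within a
#' contact are sorted by (chrom, pos); the original end/fragment provenance
#' of each locus is kept in `prov*` columns (`"1:whole"`, `"2:left"`, ...).
#'
#' @param end1,end2 [classify_end] results.
#' @param read_id Source read identifier.
#' @return data.frame of contacts; columns `read_id`, `arity`, `class`,
#'   `span` (`intra`/`inter`/`mixed`), `signature` (read-level orientation
#'   signature), and `chr1..4`, `pos1..4`, `strand1..4`, `prov1..4`
#'   (NA-padded beyond the arity).
#' @export
enumerate_contacts <- function(end1, end2, read_id = "read") {
  loci <- rbind(
    if (nrow(end1$loci)) cbind(end1$loci, end = 1L) else NULL,
    if (nrow(end2$loci)) cbind(end2$loci, end = 2L) else NULL)
  if (is.null(loci) || nrow(loci) < 2L) return(.empty_contacts())
  statuses <- c(end1$status, end2$status)[c(nrow(end1$loci) > 0,
                                            nrow(end2$loci) > 0)]
  isF <- statuses == "F"
  cls <- if (all(isF)) "F-F" else if (any(isF)) "P-F" else "P-P"
  sig <- orientation_signature(end1, end2)
  nL <- nrow(loci)
  rows <- list()
  for (k in 2:min(4L, nL)) {
    for (sub in .combn_list(nL, k)) {
      sl <- loci[sub, , drop = FALSE]
      ord <- order(sl$chrom, sl$pos)
      sl <- sl[ord, , drop = FALSE]
      row <- .empty_contacts()[0, ]
      row[1, c("read_id", "arity", "class", "span", "signature")] <-
        list(read_id, k, cls, .span_class(sl$chrom), sig)
      for (i in seq_len(k)) {
        row[[paste0("chr", i)]] <- sl$chrom[i]
        row[[paste0("pos", i)]] <- sl$pos[i]
        row[[paste0("strand", i)]] <- sl$strand[i]
        row[[paste0("prov", i)]] <- paste0(sl$end[i], ":", sl$fragment[i])
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.combn_list <- function(n, k) {
  if (k > n) return(list())
  m <- utils::combn(n, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Filter contacts by intrachromosomal genomic distance
#'
#' Drops any contact in which two loci lie on the same chromosome closer than
#' `min_dist` bp.  Purely interchromosomal contacts always pass.  A 1 kb
#' threshold eliminates unligated sonication products (size-selected ~250 bp
#' molecules); a 20 kb threshold is used for genome-scale contact analyses.
#'
#' @param contacts Contact table ([enumerate_contacts]).
#' @param min_dist Minimum intrachromosomal distance in bp (>= 0).
#' @return Filtered contact table.
#' @export
apply_distance_filter <- function(contacts, min_dist) {
  stopifnot(min_dist >= 0)
  if (!nrow(contacts) || min_dist == 0) return(contacts)
  keep <- vapply(seq_len(nrow(contacts)), function(r) {
    k <- contacts$arity[r]
    ch <- unlist(contacts[r, paste0("chr", 1:k)], use.names = FALSE)
    po <- as.numeric(unlist(contacts[r, paste0("pos", 1:k)],
                            use.names = FALSE))
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (ch[a] == ch[b] && abs(po[a] - po[b]) < min_dist) return(FALSE)
    TRUE
  }, logical(1))
  contacts[keep, , drop = FALSE]
}

#' Summarize contacts by arity and chromosomal span
#'
#' The standard library summary: counts of doubles/triples/quadruples broken
#' down into inter (all loci on distinct chromosomes), intra (all on one) and
#' mixed.
#'
#' @param contacts Contact table.
#' @return data.frame with `arity`, `span`, `count`.
#' @export
contact_summary <- function(contacts) {
  grid <- expand.grid(arity = 2:4, span = c("inter", "intra", "mixed"),
                      stringsAsFactors = FALSE)
  grid$count <- mapply(function(a, s)
    sum(contacts$arity == a & contacts$span == s), grid$arity, grid$span)
  grid[order(grid$arity, grid$span), ]
}

#' Write / read contact tables as TSV
#'
#' Doubles can also be exported in a pairs-style format via [write_pairs].
#' The TSV round-trips bit-exactly through [read_contacts].
#'
#' @param contacts Contact table.
#' @param path Output file.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(
                            read_id = "character", arity = "integer",
                            class = "character", span = "character",
                            signature = "character",
                            chr1 = "character", pos1 = "numeric",
                            strand1 = "character", prov1 = "character",
                            chr2 = "character", pos2 = "numeric",
                            strand2 = "character", prov2 = "character",
                            chr3 = "character", pos3 = "numeric",
                            strand3 = "character", prov3 = "character",
                            chr4 = "character", pos4 = "numeric",
                            strand4 = "character", prov4 = "character"),
                          stringsAsFactors = FALSE)
  df
}

#' Export doubles in a pairs-style TSV
#'
#' Columns: readID, chr1, pos1, strand1, chr2, pos2, strand2, class.  One row
#' per pairwise contact.
#'
#' @param contacts Contact table (only `arity == 2` rows are written).
#' @param path Output file.
#' @export
write_pairs <- function(contacts, path) {
  d <- contacts[contacts$arity == 2L, , drop = FALSE]
  utils::write.table(
    data.frame(readID = d$read_id, chr1 = d$chr1, pos1 = d$pos1,
               strand1 = d$strand1, chr2 = d$chr2, pos2 = d$pos2,
               strand2 = d$strand2, class = d$class),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Call contacts from paired FASTQ with the built-in exact-match aligner
#'
#' Runs the full two-phase mapping on simulated (error-free) libraries:
#' phase 1 aligns each whole read end and applies the phase-1 filter
#' (unique, MAPQ >= 30, edit distance <= 3); non-mapped ends with exactly one
#' cleavage site are split, fragments >= `min_frag` bp are aligned and the
#' stricter phase-2 filter applied (edit distance <= 1); contacts are then
#' enumerated per read pair.
#'
#' @param reads1,reads2 [Biostrings::DNAStringSet] of end-1 / end-2 read
#'   sequences (same names), or FASTQ paths.
#' @param genome [Biostrings::DNAStringSet] or FASTA path.
#' @param enzymes Enzyme list ([enzyme_set]).
#' @param min_frag Minimum split-fragment length emitted (default 16).
#' @param min_dist Intrachromosomal distance filter applied at the end
#'   (default 1000 bp, which removes sonication products).
#' @return Contact table.
#' @export
call_contacts <- function(reads1, reads2, genome, enzymes = enzyme_set(),
                          min_frag = 16L, min_dist = 1000) {
  if (is.character(reads1))
    reads1 <- Biostrings::readDNAStringSet(reads1, format = "fastq")
  if (is.character(reads2))
    reads2 <- Biostrings::readDNAStringSet(reads2, format = "fastq")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(reads1) <- sub("[/ ].*$", "", names(reads1))
  names(reads2) <- sub("[/ ].*$", "", names(reads2))
  stopifnot(identical(names(reads1), names(reads2)))
  p1 <- filter_policy(1)
  p2 <- filter_policy(2)
  out <- vector("list", length(reads1))
  for (i in seq_along(reads1)) {
    id <- names(reads1)[i]
    ends <- list()
    for (e in 1:2) {
      read <- as.character(if (e == 1) reads1[[i]] else reads2[[i]])
      whole <- naive_align(read, genome, id, e, "whole")
      whole <- whole[pass_filter(whole, p1), , drop = FALSE]
      if (nrow(whole)) {
        ends[[e]] <- classify_end(whole, NULL, NA_integer_)
      } else {
        frags <- emitted_fragments(read, enzymes, min_frag)
        ph2 <- do.call(rbind, lapply(names(frags), function(side) {
          rec <- naive_align(frags[[side]], genome, id, e,
                             if (side == "left") "left" else "right")
          rec[pass_filter(rec, p2), , drop = FALSE]
        }))
        ends[[e]] <- classify_end(NULL, ph2, attr(frags, "n_sites"))
      }
    }
    out[[i]] <- enumerate_contacts(ends[[1]], ends[[2]], id)
  }
  contacts <- do.call(rbind, c(out, list(.empty_contacts())))
  rownames(contacts) <- NULL
  apply_distance_filter(contacts, min_dist)
}
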