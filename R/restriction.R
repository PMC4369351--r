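#' Restriction enzymes
#'
#' An enzyme is a recognition sequence plus the cut offset within it
#' (0 = cut before the first base).  The bundled 4-base cutters are the ones
#' commonly used for high-resolution proximity-ligation digestion:
#' AluI (AG|CT), DpnII/MboI (|GATC), MspI (C|CGG) and NlaIII (CATG|).
#' All four motifs are reverse-complement palindromes.
#'
#' @param name Enzyme name.
#' @param site Recognition sequence, upper-case DNA over A/C/G/T.
#' @param cut_offset Cut position within the site, `0..nchar(site)`.
#' @return An object of class `enzyme`.
#' @export
enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (!nzchar(site) || grepl("[^ACGT]", site))
    stop("recognition sequence must be non-empty over A/C/G/T")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > nchar(site))
    stop("cut_offset out of range")
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "enzyme")
}

.enzyme_table <- list(
  AluI   = c(site = "AGCT", offset = "2"),
  DpnII  = c(site = "GATC", offset = "0"),
  MboI   = c(site = "GATC", offset = "0"),
  MspI   = c(site = "CCGG", offset = "1"),
  NlaIII = c(site = "CATG", offset = "4"))

#' Look up a named enzyme set
#'
#' Presets: `"single"` = DpnII only (the single 4-cutter library design);
#' `"quad"` = AluI + DpnII + MspI + NlaIII (the four 4-cutter cocktail).
#' Individual enzyme names from the bundled table are also accepted.
#'
#' @param x Preset name, character vector of enzyme names, or a list of
#'   [enzyme] objects (returned unchanged).
#' @return List of `enzyme` objects.
#' @export
enzyme_set <- function(x = "single") {
  if (is.list(x) && all(vapply(x, inherits, TRUE, "enzyme"))) return(x)
  if (identical(x, "single")) x <- "DpnII"
  if (identical(x, "quad")) x <- c("AluI", "DpnII", "MspI", "NlaIII")
  if (!length(x)) stop("empty enzyme set")
  lapply(x, function(nm) {
    e <- .enzyme_table[[nm]]
    if (is.null(e)) stop("unknown enzyme: ", nm)
    enzyme(nm, e[["site"]], as.integer(e[["offset"]]))
  })
}

#' Scan a sequence for restriction recognition sites
#'
#' Finds all (possibly overlapping) occurrences of each enzyme's recognition
#' sequence and of its reverse complement, deduplicating identical intervals
#' (all bundled 4-cutter motifs are palindromic, so the reverse-complement
#' scan only matters for custom non-palindromic enzymes).  Ambiguous bases
#' (N) never match.
#'
#' @param seq A DNA string (character or [Biostrings::DNAString]).
#' @param enzymes A list of [enzyme] objects (see [enzyme_set]).
#' @return data.frame with columns `start` (0-based offset of the recognition
#'   sequence within `seq`), `width`, and `enzyme`, sorted by `start`.
#' @examples
#' scan_sites("TTGATCTT", enzyme_set("single"))$start  # 2
#' @export
scan_sites <- function(seq, enzymes) {
  if (!length(enzymes)) stop("empty enzyme set")
  if (!inherits(seq, "DNAString")) seq <- Biostrings::DNAString(toupper(seq))
  out <- lapply(enzymes, function(e) {
    pats <- unique(c(e$site,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(e$site)))))
    st <- unlist(lapply(pats, function(p) {
      Biostrings::start(Biostrings::matchPattern(p, seq, fixed = TRUE))
    }))
    st <- sort(unique(st))
    if (!length(st)) return(NULL)
    data.frame(start = st - 1L, width = nchar(e$site), enzyme = e$name,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(start = integer(), width = integer(),
                      enzyme = character(), stringsAsFactors = FALSE)
  out[order(out$start, out$enzyme), , drop = FALSE]
}

#' Count cleavage sites in a read
#'
#' @inheritParams scan_sites
#' @return Number of recognition-site occurrences (all enzymes pooled).
#' @export
count_read_sites <- function(seq, enzymes) nrow(scan_sites(seq, enzymes))

#' Split a chimeric read at a cleavage site
#'
#' The read is cut at a single recognition-site occurrence such that the
#' entire recognition sequence is preserved on both fragments: with the site
#' at 0-based offset `s` and width `w`,
#' `left = read[0, s + w)` and `right = read[s, len)`.  Collapsing the
#' duplicated site reconstructs the read exactly.
#'
#' @param read DNA string.
#' @param hit One row of [scan_sites] output (list/data.frame with `start`
#'   and `width`).
#' @return Character vector `c(left =, right =)`.
#' @examples
#' split_read("ACGTGATCTTAA", list(start = 4, width = 4))
#' @export
split_read <- function(read, hit) {
  read <- as.character(read)
  s <- as.integer(hit$start)
  w <- as.integer(hit$width)
  if (s < 0 || s + w > nchar(read)) stop("cut-site hit outside read")
  c(left = substr(read, 1L, s + w), right = substr(read, s + 1L, nchar(read)))
}

#' Fragments emitted for second-phase alignment
#'
#' Applies the split-phase policy: reads with zero sites are not chimeric and
#' emit nothing; reads with exactly one site are split at it; reads with two
#' or more sites are discarded (junction structure ambiguous within a short
#' read).  Split fragments shorter than `min_len` are flagged out: they are
#' too short to align uniquely.
#'
#' @param read DNA string.
#' @param enzymes Enzyme list ([enzyme_set]).
#' @param min_len Minimum emitted fragment length in bp (default 16).
#' @return Named character vector of fragments to align (subset of
#'   `c(left =, right =)`), possibly empty; attribute `n_sites` carries the
#'   site count.
#' @export
emitted_fragments <- function(read, enzymes, min_len = 16L) {
  hits <- scan_sites(read, enzymes)
  frags <- character(0)
  if (nrow(hits) == 1L) {
    fr <- split_read(read, hits[1L, ])
    frags <- fr[nchar(fr) >= min_len]
  }
  attr(frags, "n_sites") <- nrow(hits)
  frags
}

#' Reverse-complement a DNA string
#'
#' @param x Character DNA string.
#' @return Character reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
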