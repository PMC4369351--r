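#' Describe a genome with (possibly partial) diploidy
#'
#' A `genome_layout` records the chromosomes of the reference assembly in a
#' fixed order together with the segments present in two copies.  Near-haploid
#' karyotypes (one copy of most chromosomes, two copies of a few chromosomes
#' or chromosome segments) are the motivating case: copy number matters both
#' for normalization (counts from two-copy loci must be apportioned between
#' homologs) and for 3D inference (two-copy loci are modelled by two beads).
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp
#'   (names are chromosome names), or a data.frame with columns `name` and
#'   `length`.  Order is preserved and defines the global bin order.
#' @param ploidy_segments Optional data.frame with columns `chrom`, `start`,
#'   `end` (0-based, half-open bp coordinates) and `copy_number` (1 or 2).
#'   Regions not covered by any segment have copy number 1.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c(chrA = 2e6, chrB = 1e6),
#'               data.frame(chrom = "chrB", start = 0, end = 1e6,
#'                          copy_number = 2))
#' @export
genome_layout <- function(chromosomes, ploidy_segments = NULL) {
  if (is.data.frame(chromosomes)) {
    stopifnot(all(c("name", "length") %in% names(chromosomes)))
    chroms <- data.frame(name = as.character(chromosomes$name),
                         length = as.numeric(chromosomes$length),
                         stringsAsFactors = FALSE)
  } else {
    if (is.null(names(chromosomes)) || !length(chromosomes))
      stop("chromosomes must be a non-empty named vector or data.frame")
    chroms <- data.frame(name = names(chromosomes),
                         length = as.numeric(chromosomes),
                         stringsAsFactors = FALSE)
  }
  if (!nrow(chroms)) stop("empty genome layout")
  if (any(chroms$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chroms$name)) stop("duplicated chromosome names")

  if (is.null(ploidy_segments)) {
    ploidy_segments <- data.frame(chrom = character(), start = numeric(),
                                  end = numeric(), copy_number = integer(),
                                  stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("chrom", "start", "end", "copy_number") %in%
                    names(ploidy_segments)))
    ploidy_segments <- data.frame(
      chrom = as.character(ploidy_segments$chrom),
      start = as.numeric(ploidy_segments$start),
      end = as.numeric(ploidy_segments$end),
      copy_number = as.integer(ploidy_segments$copy_number),
      stringsAsFactors = FALSE)
    if (!all(ploidy_segments$chrom %in% chroms$name))
      stop("ploidy segment on unknown chromosome")
    if (!all(ploidy_segments$copy_number %in% 1:2))
      stop("copy_number must be 1 or 2")
    len <- chroms$length[match(ploidy_segments$chrom, chroms$name)]
    if (any(ploidy_segments$start < 0) || any(ploidy_segments$end > len) ||
        any(ploidy_segments$start >= ploidy_segments$end))
      stop("ploidy segments must lie within their chromosome")
    # overlap check per chromosome
    for (cn in unique(ploidy_segments$chrom)) {
      s <- ploidy_segments[ploidy_segments$chrom == cn, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping ploidy segments on ", cn)
    }
  }
  structure(list(chromosomes = chroms, ploidy_segments = ploidy_segments),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp;",
      nrow(x$ploidy_segments), "ploidy segment(s)\n")
  invisible(x)
}

#' Read a chrom.sizes table
#'
#' Two-column whitespace-separated text (chromosome name, length in bp), the
#' standard UCSC `chrom.sizes` format.
#'
#' @param path File path.
#' @return Named numeric vector of lengths, in file order.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          col.names = c("name", "length"),
                          colClasses = c("character", "numeric"))
  stats::setNames(df$length, df$name)
}

#' hg19 chromosome lengths (chr1-22, X, Y)
#'
#' Lengths in bp of the 24 human hg19/GRCh37 chromosomes, bundled so that bin
#' arithmetic on the human genome needs no download.  At 1 Mb resolution these
#' lengths yield 3113 bins.
#'
#' @format Named numeric vector of length 24.
#' @export
hg19_chrom_sizes <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)

#' Tile a genome into fixed-width bins
#'
#' Bins are 0-based, half-open, and tile each chromosome contiguously from 0.
#' The last bin of a chromosome may be shorter than `resolution` (the partial
#' bin is retained).  Global bin indices are 0-based and follow the layout's
#' chromosome order.
#'
#' @param layout A [genome_layout].
#' @param resolution Bin width in bp (> 0).
#' @return A `bin_table`: data.frame with columns `chrom`, `start`, `end`,
#'   `index` and annotation columns `gc_fraction` (NA until annotated),
#'   `mappable_fraction` (default 1) and `dhs_count` (default 0);
#'   attribute `resolution`.
#' @examples
#' nrow(make_bins(genome_layout(hg19_chrom_sizes), 1e6))  # 3113
#' @export
make_bins <- function(layout, resolution) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("resolution must be a single positive number")
  if (!nrow(layout$chromosomes)) stop("empty genome layout")
  pieces <- lapply(seq_len(nrow(layout$chromosomes)), function(i) {
    len <- layout$chromosomes$length[i]
    nb <- ceiling(len / resolution)
    start <- (seq_len(nb) - 1) * resolution
    data.frame(chrom = layout$chromosomes$name[i],
               start = start,
               end = pmin(start + resolution, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$index <- seq_len(nrow(bins)) - 1L
  bins$gc_fraction <- NA_real_
  bins$mappable_fraction <- 1
  bins$dhs_count <- 0L
  attr(bins, "resolution") <- resolution
  class(bins) <- c("bin_table", "data.frame")
  bins
}

#' Per-bin copy number implied by a layout
#'
#' Ploidy segment boundaries that are not aligned to bin boundaries are
#' snapped outward: any bin that intersects a copy-number-2 segment is treated
#' as two-copy in full.
#'
#' @param bins A [make_bins] table.
#' @param layout The [genome_layout] the bins were built from.
#' @return Integer vector (1 or 2) along the bins.
#' @export
bin_copy_number <- function(bins, layout) {
  cn <- rep(1L, nrow(bins))
  seg <- layout$ploidy_segments
  if (nrow(seg)) {
    seg <- seg[seg$copy_number == 2L, , drop = FALSE]
    for (i in seq_len(nrow(seg))) {
      hit <- bins$chrom == seg$chrom[i] &
        bins$start < seg$end[i] & bins$end > seg$start[i]
      cn[hit] <- 2L
    }
  }
  cn
}

#' Build the bead-to-locus map used by normalization and 3D inference
#'
#' Observed contact counts live on `m` loci (bins), but the physical model has
#' `n >= m` beads: one bead per copy of each bin.  `phi` maps bead index to
#' locus index; `copy` labels the homolog ("A" for the first copy of every
#' locus, "B" for the second copy of two-copy loci).  Beads 1..m are the "A"
#' copies in bin order; "B" beads follow, in bin order.
#'
#' @param bins A [make_bins] table.
#' @param layout The matching [genome_layout].
#' @return A `bead_map`: list with `n`, `m`, `phi` (integer, length n, 1-based
#'   locus index), `copy` (character, "A"/"B") and `copy_number` (per locus).
#' @export
build_bead_map <- function(bins, layout) {
  cn <- bin_copy_number(bins, layout)
  m <- nrow(bins)
  phi <- c(seq_len(m), which(cn == 2L))
  copy <- c(rep("A", m), rep("B", sum(cn == 2L)))
  structure(list(n = length(phi), m = m, phi = as.integer(phi),
                 copy = copy, copy_number = cn),
            class = "bead_map")
}

#' @export
print.bead_map <- function(x, ...) {
  cat("bead_map: n =", x$n, "beads over m =", x$m, "loci (",
      sum(x$copy_number == 2L), "two-copy loci)\n")
  invisible(x)
}

#' Beads belonging to each locus
#'
#' @param beadmap A [build_bead_map] object.
#' @return List of integer bead-index vectors, one per locus.
#' @export
beads_of_locus <- function(beadmap) {
  split(seq_len(beadmap$n), beadmap$phi)[as.character(seq_len(beadmap$m))]
}

#' Assign genomic positions to bins
#'
#' Loci are assigned by their 5' mapped coordinate.  Positions are 0-based.
#'
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @param bins A [make_bins] table.
#' @return 1-based row index into `bins` (NA for unknown chromosomes or
#'   out-of-range positions).
#' @export
assign_bins <- function(chrom, pos, bins) {
  res <- attr(bins, "resolution")
  first <- tapply(seq_len(nrow(bins)), bins$chrom, min)
  nb <- tapply(seq_len(nrow(bins)), bins$chrom, length)
  off <- first[chrom]
  cnt <- nb[chrom]
  k <- floor(pos / res)
  idx <- as.integer(off + k)
  bad <- is.na(off) | pos < 0 | k >= cnt
  idx[bad] <- NA_integer_
  idx
}

#' Annotate bins with GC content from a genome sequence
#'
#' @param bins A [make_bins] table.
#' @param genome A [Biostrings::DNAStringSet] whose names match the layout's
#'   chromosome names.
#' @return The bin table with `gc_fraction` filled in.
#' @export
annotate_gc <- function(bins, genome) {
  gc <- numeric(nrow(bins))
  for (cn in unique(bins$chrom)) {
    idx <- which(bins$chrom == cn)
    seq <- genome[[cn]]
    v <- Biostrings::Views(seq, start = bins$start[idx] + 1L,
                           end = bins$end[idx])
    f <- Biostrings::letterFrequency(v, c("GC", "ACGT"))
    gc[idx] <- ifelse(f[, 2] > 0, f[, 1] / f[, 2], NA_real_)
  }
  bins$gc_fraction <- gc
  bins
}

#' Annotate bins with mappable fraction and DHS counts from intervals
#'
#' @param bins A [make_bins] table.
#' @param mappable Optional [GenomicRanges::GRanges] (or BED path) of uniquely
#'   mappable intervals; per-bin covered fraction is stored in
#'   `mappable_fraction`.
#' @param dhs Optional [GenomicRanges::GRanges] (or BED/narrowPeak path) of
#'   DNase hypersensitive site peaks; overlap counts go to `dhs_count`.
#' @return The annotated bin table.
#' @export
annotate_intervals <- function(bins, mappable = NULL, dhs = NULL) {
  gr <- GenomicRanges::GRanges(bins$chrom,
                               IRanges::IRanges(bins$start + 1L, bins$end))
  if (!is.null(mappable)) {
    if (is.character(mappable)) mappable <- rtracklayer::import(mappable)
    cov <- GenomicRanges::intersect(
      gr, GenomicRanges::reduce(mappable), ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(gr, cov)
    w <- IRanges::width(IRanges::pintersect(
      gr[S4Vectors::queryHits(ov)], cov[S4Vectors::subjectHits(ov)]))
    tot <- tapply(w, S4Vectors::queryHits(ov), sum)
    frac <- numeric(length(gr))
    frac[as.integer(names(tot))] <- tot
    bins$mappable_fraction <- frac / IRanges::width(gr)
  }
  if (!is.null(dhs)) {
    if (is.character(dhs)) dhs <- rtracklayer::import(dhs)
    bins$dhs_count <- GenomicRanges::countOverlaps(gr, dhs,
                                                   ignore.strand = TRUE)
  }
  bins
}

#' Export a bin table as BED
#'
#' Writes 0-based half-open BED with the global bin index in the name column.
#'
#' @param bins A [make_bins] table.
#' @param path Output file.
#' @export
bins_to_bed <- function(bins, path) {
  utils::write.table(
    data.frame(bins$chrom, format(bins$start, scientific = FALSE, trim = TRUE),
               format(bins$end, scientific = FALSE, trim = TRUE), bins$index),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
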