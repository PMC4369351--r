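#' Call open/closed compartments for one chromosome
#'
#' Computes the Pearson correlation between every pair of rows of the
#' chromosome's intrachromosomal (normalized) contact matrix and applies
#' eigendecomposition to the correlation matrix.  The sign of the leading
#' eigenvector partitions bins into two megabase-scale compartments; the
#' second eigenvector is used instead when the first has single-signed
#' entries (ignoring NA and exact zeros), in which case it reflects overall
#' coverage rather than compartmentalization.  Signs are made reproducible
#' by scaling the eigenvector so its largest-magnitude entry is positive;
#' biological orientation (which sign is "open") is applied afterwards with
#' [orient_by_gc].
#'
#' Bins that are filtered (all-zero/NA rows) are dropped before the
#' correlation and reinserted as NA.  Fewer than 4 usable bins yields an
#' all-NA track.
#'
#' @param mat Normalized contact matrix (`contact_matrix` or bare matrix).
#' @param bins Bin table (defaults to `mat$bins`).
#' @param chrom Chromosome to call.
#' @param retained Optional logical mask of usable loci (length = total
#'   bins); by default loci with all-zero intrachromosomal rows are dropped.
#' @return A `compartment_track` data.frame for that chromosome's bins:
#'   columns `chrom`, `start`, `end`, `index`, `ev` (eigenvector value),
#'   `label` ("open"/"closed"/NA).  Attribute `eig_index` records whether
#'   eigenvector 1 or 2 was used.  Before GC orientation, positive sign is
#'   provisionally labelled "open".
#' @export
correlation_compartments <- function(mat, bins = NULL, chrom,
                                     retained = NULL) {
  if (inherits(mat, "contact_matrix")) {
    if (is.null(bins)) bins <- mat$bins
    mat <- mat$counts
  }
  idx <- which(bins$chrom == chrom)
  if (!length(idx)) stop("unknown chromosome: ", chrom)
  block <- as.matrix(mat[idx, idx, drop = FALSE])
  use <- if (is.null(retained)) rowSums(block != 0) > 0 else retained[idx]
  use <- use & apply(block, 1, function(r) stats::sd(r) > 0)
  track <- data.frame(chrom = bins$chrom[idx], start = bins$start[idx],
                      end = bins$end[idx], index = bins$index[idx],
                      ev = NA_real_, label = NA_character_,
                      stringsAsFactors = FALSE)
  if (sum(use) < 4L) {
    attr(track, "eig_index") <- NA_integer_
    class(track) <- c("compartment_track", "data.frame")
    return(track)
  }
  C <- stats::cor(block[use, use, drop = FALSE])
  eig <- eigen(C, symmetric = TRUE)
  pick <- 1L
  v <- eig$vectors[, 1L]
  nz <- v[v != 0]
  if (length(nz) && (all(nz > 0) || all(nz < 0))) {
    pick <- 2L
    v <- eig$vectors[, 2L]
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  track$ev[use] <- v
  track$label[use] <- ifelse(v > 0, "open", ifelse(v < 0, "closed",
                                                   NA_character_))
  attr(track, "eig_index") <- pick
  class(track) <- c("compartment_track", "data.frame")
  track
}

#' Orient compartment signs by GC content
#'
#' Of the two sign groups of the eigenvector, the one with the higher mean
#' GC fraction is labelled "open" (open chromatin is GC-rich).  Flipping all
#' eigenvector signs therefore leaves the labels unchanged.  An exact GC tie
#' keeps the positive sign as "open" and warns.
#'
#' @param track A [correlation_compartments] track.
#' @param gc GC fraction per bin of the track (same length/order).
#' @return The track with labels oriented.
#' @export
orient_by_gc <- function(track, gc) {
  stopifnot(length(gc) == nrow(track))
  pos <- !is.na(track$ev) & track$ev > 0
  neg <- !is.na(track$ev) & track$ev < 0
  if (!any(pos) || !any(neg)) return(track)
  gp <- mean(gc[pos], na.rm = TRUE)
  gn <- mean(gc[neg], na.rm = TRUE)
  if (isTRUE(all.equal(gp, gn))) {
    warning("equal mean GC in both sign groups; keeping '+' as open")
    open_pos <- TRUE
  } else open_pos <- gp > gn
  track$label[pos] <- if (open_pos) "open" else "closed"
  track$label[neg] <- if (open_pos) "closed" else "open"
  track
}

#' Percent agreement between two compartment tracks
#'
#' Percentage of bins labelled (non-NA) in both tracks that carry the same
#' label.  Tracks are matched on bin `index` when present, else positionally.
#'
#' @param a,b Compartment tracks (or vectors of labels).
#' @return Percentage in `[0, 100]` (NaN when no bin is labelled in both).
#' @export
agreement <- function(a, b) {
  la <- if (is.data.frame(a)) a$label else a
  lb <- if (is.data.frame(b)) b$label else b
  if (is.data.frame(a) && is.data.frame(b) &&
      !is.null(a$index) && !is.null(b$index)) {
    common <- intersect(a$index, b$index)
    la <- la[match(common, a$index)]
    lb <- lb[match(common, b$index)]
  }
  ok <- !is.na(la) & !is.na(lb)
  100 * mean(la[ok] == lb[ok])
}

#' Call and orient compartments genome-wide
#'
#' Runs [correlation_compartments] per chromosome on a normalized matrix and
#' orients each chromosome by GC ([orient_by_gc]) when the bin table carries
#' `gc_fraction`.
#'
#' @param norm A `contact_matrix` (normalized) with annotated bins.
#' @param retained Optional per-locus logical mask.
#' @return A `compartment_track` covering all bins.
#' @export
call_compartments <- function(norm, retained = NULL) {
  bins <- norm$bins
  tracks <- lapply(unique(bins$chrom), function(cn) {
    tr <- correlation_compartments(norm, bins, cn, retained)
    if (!all(is.na(bins$gc_fraction[bins$chrom == cn])))
      tr <- orient_by_gc(tr, bins$gc_fraction[bins$chrom == cn])
    tr
  })
  out <- do.call(rbind, tracks)
  class(out) <- c("compartment_track", "data.frame")
  out
}

#' Export a compartment track as BED
#'
#' Label in the name column, eigenvector value in the score column.
#'
#' @param track Compartment track.
#' @param path Output file.
#' @export
track_to_bed <- function(track, path) {
  utils::write.table(
    data.frame(track$chrom,
               format(track$start, scientific = FALSE, trim = TRUE),
               format(track$end, scientific = FALSE, trim = TRUE),
               ifelse(is.na(track$label), "NA", track$label),
               ifelse(is.na(track$ev), 0, track$ev)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
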