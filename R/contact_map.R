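#' Bin pairwise contacts into a symmetric contact matrix
#'
#' Every double (arity-2 contact) increments exactly one unordered bin pair;
#' the matrix is stored as a sparse symmetric [Matrix::Matrix].  Total matrix
#' mass over the upper triangle plus diagonal equals the number of doubles
#' binned.
#'
#' @param contacts Contact table; only `arity == 2` rows are used.
#' @param bins A [make_bins] table.
#' @return A `contact_matrix`: list with `counts` (m x m `dsCMatrix`) and
#'   `bins`.
#' @export
bin_contacts <- function(contacts, bins) {
  d <- contacts[contacts$arity == 2L, , drop = FALSE]
  m <- nrow(bins)
  i <- assign_bins(d$chr1, d$pos1, bins)
  j <- assign_bins(d$chr2, d$pos2, bins)
  ok <- !is.na(i) & !is.na(j)
  i2 <- pmin(i[ok], j[ok]); j2 <- pmax(i[ok], j[ok])
  counts <- Matrix::sparseMatrix(i = i2, j = j2, x = 1, dims = c(m, m),
                                 symmetric = TRUE)
  structure(list(counts = counts, bins = bins), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$counts), "bins,",
      format(contact_mass(x), big.mark = ","), "contacts\n")
  invisible(x)
}

#' Total contact mass (upper triangle + diagonal)
#'
#' @param cm A `contact_matrix` or matrix.
#' @return Numeric total.
#' @export
contact_mass <- function(cm) {
  m <- if (inherits(cm, "contact_matrix")) cm$counts else cm
  tu <- Matrix::triu(methods::as(m, "generalMatrix"))
  sum(tu)
}

#' Contact probability vs genomic distance (scaling curve)
#'
#' Intrachromosomal doubles are binned by genomic distance into
#' multiplicatively spaced bins (factor `2^0.5` starting at `min_dist`), and
#' each bin's count is normalized by the number of genomic position pairs at
#' that distance range (summed over chromosomes), giving a per-bp contact
#' probability up to a global constant.  Crosslinked libraries show a sharp
#' decay, log-linear over roughly 0.5-7 Mb; libraries without genuine 3D
#' signal show no decay.
#'
#' @param contacts Contact table (arity-2 intra rows are used).
#' @param layout [genome_layout], for chromosome lengths.
#' @param min_dist Smallest distance bin edge (default 1 kb).
#' @param factor Multiplicative bin spacing (default `sqrt(2)`).
#' @return data.frame with `dist_lo`, `dist_hi`, `dist_mid` (geometric mean),
#'   `count`, `n_pairs`, `prob`.
#' @export
scaling_curve <- function(contacts, layout, min_dist = 1e3,
                          factor = sqrt(2)) {
  d <- contacts[contacts$arity == 2L & contacts$span == "intra", ,
                drop = FALSE]
  dist <- abs(d$pos2 - d$pos1)
  maxlen <- max(layout$chromosomes$length)
  edges <- min_dist * factor^(0:ceiling(log(maxlen / min_dist, factor)))
  lo <- edges[-length(edges)]; hi <- edges[-1]
  lens <- layout$chromosomes$length
  # number of (unordered) bp pairs at distance in [lo, hi): per chromosome,
  # integral over s of (L - s)
  npairs <- vapply(seq_along(lo), function(b) {
    a <- lo[b]; z <- pmin(hi[b], lens)
    sum(pmax(0, (z - a) * lens - (z^2 - a^2) / 2))
  }, numeric(1))
  cnt <- vapply(seq_along(lo), function(b)
    sum(dist >= lo[b] & dist < hi[b]), numeric(1))
  data.frame(dist_lo = lo, dist_hi = hi, dist_mid = sqrt(lo * hi),
             count = cnt, n_pairs = npairs,
             prob = ifelse(npairs > 0, cnt / npairs, NA_real_))
}

#' Fit the log-log slope of a scaling curve
#'
#' Ordinary least squares of `log10(prob)` on `log10(dist_mid)` over a
#' distance range.
#'
#' @param curve [scaling_curve] output.
#' @param range Length-2 numeric; only bins with `dist_mid` inside are used.
#' @return Fitted slope (the scaling exponent).
#' @export
fit_scaling_exponent <- function(curve, range = c(5e5, 7e6)) {
  use <- curve$dist_mid >= range[1] & curve$dist_mid <= range[2] &
    curve$count > 0 & !is.na(curve$prob) & curve$prob > 0
  if (sum(use) < 2) stop("not enough populated distance bins in range")
  stats::coef(stats::lm(log10(prob) ~ log10(dist_mid),
                        data = curve[use, ]))[[2]]
}

#' Mean contact count per chromosome pair
#'
#' For every pair of chromosomes, averages the binned contact counts over all
#' pairs of mappable windows (both bins with `mappable_fraction >=
#' min_mappable`).  Copy-number differences and translocations show up as
#' elevated rows/entries of this matrix.
#'
#' @param cm A [bin_contacts] matrix.
#' @param min_mappable Mappability threshold for a window to count
#'   (default 0.5).
#' @return Symmetric numeric matrix with chromosome names as dimnames.
#' @export
chrom_pair_means <- function(cm, min_mappable = 0.5) {
  bins <- cm$bins
  chroms <- unique(bins$chrom)
  ok <- bins$mappable_fraction >= min_mappable
  M <- as.matrix(cm$counts)
  out <- matrix(NA_real_, length(chroms), length(chroms),
                dimnames = list(chroms, chroms))
  idx <- lapply(chroms, function(cn) which(bins$chrom == cn & ok))
  for (a in seq_along(chroms)) for (b in seq_len(a)) {
    ia <- idx[[a]]; ib <- idx[[b]]
    if (length(ia) && length(ib)) {
      block <- M[ia, ib, drop = FALSE]
      if (a == b) {
        v <- mean(block[upper.tri(block, diag = TRUE)])
      } else v <- mean(block)
      out[a, b] <- out[b, a] <- v
    }
  }
  out
}

#' Export / import a contact matrix as triplet TSV
#'
#' Upper-triangle triplets (`bin1`, `bin2`, `count`) with 0-based bin
#' indices; the bin table itself can be written with [bins_to_bed].
#'
#' @param cm A `contact_matrix`.
#' @param path Output file.
#' @export
write_matrix_triplets <- function(cm, path) {
  tu <- methods::as(Matrix::triu(methods::as(cm$counts, "generalMatrix")),
                    "TsparseMatrix")
  ord <- order(tu@i, tu@j)
  utils::write.table(
    data.frame(bin1 = tu@i[ord], bin2 = tu@j[ord], count = tu@x[ord]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_triplets
#' @param bins Bin table matching the stored indices.
#' @export
read_matrix_triplets <- function(path, bins) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  m <- nrow(bins)
  counts <- Matrix::sparseMatrix(i = df$bin1 + 1L, j = df$bin2 + 1L,
                                 x = df$count, dims = c(m, m),
                                 symmetric = TRUE)
  structure(list(counts = counts, bins = bins), class = "contact_matrix")
}
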