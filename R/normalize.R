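#' Deduplicate a contact matrix onto homolog beads
#'
#' Converts the observed m x m locus-level counts into an n x n bead-level
#' matrix in which homologous copies of two-copy regions are separated.
#' Counts are split equally over the "eligible" bead pairs of each locus
#' pair, and counts between different homologs are set to zero, encoding the
#' assumption that homologous chromosomes interact in identical ways and do
#' not interact with each other:
#'
#' * haploid-haploid: the single bead pair keeps the full count;
#' * haploid-diploid: each of the two bead pairs gets half;
#' * diploid-diploid: the two same-copy pairs (A-A, B-B) get half each,
#'   inter-homolog pairs (A-B, B-A) get zero.
#'
#' @param cm A `contact_matrix` ([bin_contacts]) or bare matrix.
#' @param beadmap A [build_bead_map] for the same bins.
#' @return Sparse symmetric n x n bead-level matrix.
#' @export
deduplicate <- function(cm, beadmap) {
  M <- if (inherits(cm, "contact_matrix")) cm$counts else cm
  stopifnot(nrow(M) == beadmap$m)
  tu <- methods::as(Matrix::triu(methods::as(M, "generalMatrix")),
                    "TsparseMatrix")
  bol <- beads_of_locus(beadmap)
  ii <- jj <- xx <- vector("list", length(tu@x))
  for (t in seq_along(tu@x)) {
    k <- tu@i[t] + 1L; l <- tu@j[t] + 1L
    bk <- bol[[k]]; bl <- bol[[l]]
    pairs <- expand.grid(i = bk, j = bl)
    same <- beadmap$copy[pairs$i] == beadmap$copy[pairs$j]
    eligible <- if (length(bk) == 2L && length(bl) == 2L) same
                else rep(TRUE, nrow(pairs))
    pairs <- pairs[eligible, , drop = FALSE]
    if (k == l) pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
    ii[[t]] <- pmin(pairs$i, pairs$j)
    jj[[t]] <- pmax(pairs$i, pairs$j)
    xx[[t]] <- rep(tu@x[t] / nrow(pairs), nrow(pairs))
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(beadmap$n, beadmap$n), symmetric = TRUE)
}

#' Re-sum homolog beads back to loci
#'
#' Inverse aggregation of [deduplicate]: each locus-pair entry is the sum
#' over the corresponding bead pairs.  `resum_homologs(deduplicate(M))`
#' restores `M` exactly.  After bead-level iterative correction, two-copy
#' loci end up with exactly twice the coverage of single-copy loci.
#'
#' @param beadmat n x n bead-level matrix.
#' @param beadmap The matching [build_bead_map].
#' @return Sparse symmetric m x m locus-level matrix.
#' @export
resum_homologs <- function(beadmat, beadmap) {
  P <- Matrix::sparseMatrix(i = seq_len(beadmap$n), j = beadmap$phi, x = 1,
                            dims = c(beadmap$n, beadmap$m))
  out <- Matrix::t(P) %*% methods::as(beadmat, "generalMatrix") %*% P
  Matrix::forceSymmetric(out)
}

#' Rank-based sparsity prefilter
#'
#' Ranks loci by the fraction of zero entries among their intrachromosomal
#' contacts (entries within their own chromosome, diagonal included) and
#' flags the top `floor(fraction * m)` for removal; these are the loci with
#' the worst signal-to-noise (typically low-mappability regions).  Ties are
#' broken by locus index.  Loci on chromosomes with fewer than 2 bins are
#' exempt.
#'
#' @param mat m x m matrix (locus level).
#' @param chrom Chromosome name per locus (length m).
#' @param fraction Fraction of loci to remove, `0 <= fraction < 1`
#'   (default 0.10).
#' @return Logical vector, TRUE = retained.
#' @export
sparsity_filter <- function(mat, chrom, fraction = 0.10) {
  stopifnot(fraction >= 0, fraction < 1)
  m <- nrow(mat)
  M <- as.matrix(mat)
  zero_frac <- rep(NA_real_, m)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    if (length(idx) < 2L) next
    block <- M[idx, idx, drop = FALSE]
    zero_frac[idx] <- rowMeans(block == 0)
  }
  n_drop <- floor(fraction * m)
  retained <- rep(TRUE, m)
  cand <- which(!is.na(zero_frac))
  cand <- cand[order(-zero_frac[cand], cand)]
  retained[utils::head(cand, n_drop)] <- FALSE
  retained
}

#' Iterative correction (ICE) under the equal-visibility hypothesis
#'
#' Assumes the observed count for a pair of loci is the true contact
#' frequency multiplied by the product of per-locus biases, and iteratively
#' rescales rows/columns until coverage (row sums over retained loci) is
#' uniform.  The estimated bias vector `beta` is normalized to unit geometric
#' mean over retained loci; `normalized = raw / (beta %o% beta)`.
#'
#' @param mat Symmetric non-negative matrix (bead or locus level).
#' @param retained Logical mask of loci to include (default all); filtered
#'   rows/columns are zeroed in the output and get `NA` bias.
#' @param tol Convergence tolerance on the maximum relative coverage
#'   deviation (default 1e-5).
#' @param max_iter Maximum iterations (default 300); non-convergence returns
#'   with `converged = FALSE` and a warning.
#' @return List: `bias` (length-m, NA where filtered), `normalized` (sparse
#'   symmetric matrix), `converged`, `iterations`.
#' @export
ice <- function(mat, retained = NULL, tol = 1e-5, max_iter = 300L) {
  M <- methods::as(if (inherits(mat, "contact_matrix")) mat$counts else mat,
                   "generalMatrix")
  m <- nrow(M)
  if (is.null(retained)) retained <- rep(TRUE, m)
  if (any(M@x < 0)) stop("negative counts")
  W <- M
  if (any(!retained)) {
    W[!retained, ] <- 0
    W[, !retained] <- 0
  }
  beta <- rep(1, m)
  converged <- FALSE
  it <- 0L
  active <- retained & (Matrix::rowSums(W) > 0)
  for (it in seq_len(max_iter)) {
    cov <- Matrix::rowSums(W)
    s <- cov / mean(cov[active])
    s[!active | s == 0] <- 1
    Dinv <- Matrix::Diagonal(x = 1 / s)
    W <- Dinv %*% W %*% Dinv
    beta <- beta * s
    if (max(abs(s[active] - 1)) <= tol) { converged <- TRUE; break }
  }
  if (!converged) warning("ICE did not converge in ", max_iter, " iterations")
  g <- exp(mean(log(beta[active])))
  beta <- beta / g
  W <- W * g^2
  beta[!retained] <- NA_real_
  list(bias = beta, normalized = Matrix::forceSymmetric(W),
       converged = converged, iterations = it)
}

#' Full copy-number-aware normalization
#'
#' Pipeline: sparsity-filter loci, deduplicate counts onto homolog beads,
#' run [ice] at the bead level (the mask expanded to beads), and re-sum
#' homologs back to loci.  In the result, two-copy loci have exactly twice
#' the coverage of single-copy loci (all bead coverages are equalized, and
#' two-copy loci own two beads).
#'
#' @param cm A `contact_matrix`.
#' @param beadmap [build_bead_map] matching the bins.
#' @param fraction Sparsity-filter fraction (default 0.10).
#' @param tol,max_iter Passed to [ice].
#' @return List: `normalized` (`contact_matrix` at locus level), `bias`
#'   (per bead), `retained` (per locus), `bead_normalized` (n x n),
#'   `converged`.
#' @export
normalize_contacts <- function(cm, beadmap, fraction = 0.10, tol = 1e-5,
                               max_iter = 300L) {
  retained <- sparsity_filter(cm$counts, cm$bins$chrom, fraction)
  bead <- deduplicate(cm, beadmap)
  bead_retained <- retained[beadmap$phi]
  res <- ice(bead, bead_retained, tol, max_iter)
  loc <- resum_homologs(res$normalized, beadmap)
  structure(list(
    normalized = structure(list(counts = loc, bins = cm$bins),
                           class = "contact_matrix"),
    bias = res$bias, retained = retained,
    bead_normalized = res$normalized, converged = res$converged),
    class = "normalization_result")
}
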