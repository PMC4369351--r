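#' Configuration for 3D structure inference
#'
#' @param alpha Power-law exponent relating the Poisson mean to inter-bead
#'   distance (`mean = d^alpha`); must be negative.  Default -3.
#' @param dmax_quantile Quantile of expected adjacent-bead distances used as
#'   the distance upper bound (default 0.97).
#' @param mu_grid Step of the grid search over count-apportionment fractions
#'   (default 0.01; must divide 1).
#' @param mu_box Lower/upper bounds on each apportionment fraction in
#'   multi-bead groups (default `c(0.3, 0.7)`), keeping both homolog copies
#'   in play.
#' @param restarts Number of random restarts of the alternating optimization
#'   (default 10).
#' @param top_frac Fraction of restarts kept as the reported ensemble
#'   (default 0.1, i.e. "top 10%"; at least one model is always kept).
#' @param max_outer Maximum alternating iterations per restart (default 50).
#' @param rel_tol Relative objective-change convergence threshold
#'   (default 1e-6).
#' @param penalty Weight of the smooth hinge penalty enforcing
#'   `d <= d_max` (default 100; raised automatically if the final structure
#'   violates the bound by more than 1%).
#' @param max_inner Maximum L-BFGS iterations per structure step
#'   (default 200).
#' @param seed Base random seed; restart r uses `seed + r - 1`.
#' @return List of class `model_config`.
#' @export
model_config <- function(alpha = -3, dmax_quantile = 0.97, mu_grid = 0.01,
                         mu_box = c(0.3, 0.7), restarts = 10L,
                         top_frac = 0.1, max_outer = 50L, rel_tol = 1e-6,
                         penalty = 100, max_inner = 200L, seed = 1L) {
  stopifnot(alpha < 0, dmax_quantile > 0, dmax_quantile < 1,
            mu_grid > 0, abs(round(1 / mu_grid) - 1 / mu_grid) < 1e-9,
            mu_box[1] >= 0, mu_box[2] <= 1, mu_box[1] <= mu_box[2],
            restarts >= 1)
  structure(list(alpha = alpha, dmax_quantile = dmax_quantile,
                 mu_grid = mu_grid, mu_box = mu_box,
                 restarts = as.integer(restarts), top_frac = top_frac,
                 max_outer = as.integer(max_outer), rel_tol = rel_tol,
                 penalty = penalty, max_inner = as.integer(max_inner),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Bead-pair groups carrying the observed contact counts
#'
#' Expands the locus-level count matrix into the set `D` of bead pairs with
#' non-zero observed counts.  For each locus pair (k, l) with count
#' `c_kl > 0`, the eligible bead pairs follow the homolog model of
#' [deduplicate]: the single pair for haploid-haploid, both pairs for
#' haploid-diploid, and the two same-copy pairs for diploid-diploid.  Each
#' locus pair forms one constraint group over which the apportionment
#' fractions `mu` must sum to one.  Groups whose two loci both lie in
#' two-copy regions are flagged `boxed`: their same-copy apportionments are
#' additionally bounded to `mu_box` (both homolog configurations must carry
#' a substantial share, since homologous chromosomes are assumed to
#' interact similarly).  Diagonal (k = k) counts are excluded: a bead's
#' distance to itself carries no geometric information.
#'
#' @param counts Locus-level matrix (`contact_matrix` or bare m x m matrix).
#' @param beadmap [build_bead_map].
#' @param retained Optional logical mask of usable loci.
#' @return data.frame with columns `i`, `j` (bead indices), `k`, `l`
#'   (locus indices), `c` (locus-pair count), `group` (group id), `boxed`
#'   (TRUE when the group has more than one bead pair).
#' @export
contact_groups <- function(counts, beadmap, retained = NULL) {
  M <- if (inherits(counts, "contact_matrix")) counts$counts else counts
  stopifnot(nrow(M) == beadmap$m)
  tu <- methods::as(Matrix::triu(methods::as(M, "TsparseMatrix"), k = 1),
                    "TsparseMatrix")
  bol <- beads_of_locus(beadmap)
  rows <- list()
  gid <- 0L
  for (t in seq_along(tu@x)) {
    if (tu@x[t] <= 0) next
    k <- tu@i[t] + 1L; l <- tu@j[t] + 1L
    if (!is.null(retained) && (!retained[k] || !retained[l])) next
    bk <- bol[[k]]; bl <- bol[[l]]
    pairs <- expand.grid(i = bk, j = bl)
    if (length(bk) == 2L && length(bl) == 2L)
      pairs <- pairs[beadmap$copy[pairs$i] == beadmap$copy[pairs$j], ,
                     drop = FALSE]
    gid <- gid + 1L
    rows[[gid]] <- data.frame(i = pairs$i, j = pairs$j, k = k, l = l,
                              c = tu@x[t], group = gid,
                              boxed = length(bk) == 2L && length(bl) == 2L)
  }
  if (!gid)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      l = integer(), c = numeric(), group = integer(),
                      boxed = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.pair_dist <- function(X, groups) {
  dx <- X[groups$i, , drop = FALSE] - X[groups$j, , drop = FALSE]
  sqrt(rowSums(dx^2))
}

#' Adjacent bead pairs along each chromosome copy
#'
#' Consecutive beads of the same chromosome and homolog copy form the
#' polymer chain; the `d_max` bound of the structure model is enforced on
#' these chain distances (the quantity `d_max` is estimated from).
#'
#' @param beadmap [build_bead_map].
#' @param bins Bin table.
#' @return Two-column integer matrix of bead index pairs.
#' @export
adjacent_bead_pairs <- function(beadmap, bins) {
  ord <- order(beadmap$copy, beadmap$phi)
  b <- ord
  k <- beadmap$phi[b]
  same <- beadmap$copy[b[-length(b)]] == beadmap$copy[b[-1]] &
    bins$chrom[k[-length(k)]] == bins$chrom[k[-1]] &
    k[-1] == k[-length(k)] + 1L
  cbind(i = b[-length(b)][same], j = b[-1][same])
}

#' Poisson log-likelihood of a structure and count apportionment
#'
#' For each bead pair (i, j) in the non-zero count set `D`, with apportioned
#' count `w = mu_ij * c_kl` and distance `d_ij`, the contribution is
#' `w * alpha * log(d) - d^alpha - log Gamma(w + 1)` — the log density of a
#' Poisson with mean `d^alpha` evaluated at the (real-valued) count `w`,
#' with the factorial relaxed to the Gamma function.
#'
#' @param X n x 3 coordinate matrix.
#' @param mu Apportionment fractions along the rows of `groups`.
#' @param groups [contact_groups] output.
#' @param alpha Negative decay exponent (default -3).
#' @return Scalar log-likelihood.  Coincident beads (zero distance) within
#'   `D` are an error.
#' @export
log_likelihood <- function(X, mu, groups, alpha = -3) {
  if (!nrow(groups)) return(0)
  d <- .pair_dist(X, groups)
  if (any(d == 0)) stop("coincident beads with non-zero contact count")
  w <- mu * groups$c
  sum(w * alpha * log(d) - d^alpha - lgamma(w + 1))
}

.hinge_penalty <- function(d, dmax, penalty) {
  v <- pmax(0, d - dmax)
  penalty * sum(v^2)
}

#' Distance upper bound from adjacent-bead counts
#'
#' Computes the expected distance `c^(-1/3)` for every pair of adjacent loci
#' on single-copy chromosome stretches with a positive count, and returns
#' the requested quantile (linear interpolation, [stats::quantile] type 7).
#' Larger counts give smaller expected distances; the high quantile excludes
#' outlier distances arising from near-zero normalized counts.
#'
#' @param counts Locus-level matrix (`contact_matrix` or bare matrix).
#' @param beadmap [build_bead_map].
#' @param bins Bin table (adjacency = consecutive bins on one chromosome).
#' @param q Quantile (default 0.97).
#' @return `d_max` (scalar).
#' @export
estimate_dmax <- function(counts, beadmap, bins, q = 0.97) {
  M <- if (inherits(counts, "contact_matrix")) counts$counts else counts
  m <- nrow(bins)
  k <- seq_len(m - 1)
  adj <- which(bins$chrom[k] == bins$chrom[k + 1] &
                 beadmap$copy_number[k] == 1L &
                 beadmap$copy_number[k + 1] == 1L)
  cc <- M[cbind(adj, adj + 1L)]
  cc <- cc[cc > 0]
  if (!length(cc)) stop("no positive adjacent-bead counts on haploid stretches")
  stats::quantile(cc^(-1 / 3), q, names = FALSE, type = 7)
}

.mu_lattice <- function(size, step, box) {
  # all vectors on the step-lattice inside [box] summing to 1
  vals <- seq(box[1], box[2], by = step)
  if (size == 1L) return(matrix(1, 1, 1))
  grids <- rev(expand.grid(rep(list(vals), size - 1L)))
  last <- 1 - rowSums(grids)
  ok <- last >= box[1] - 1e-9 & last <= box[2] + 1e-9
  out <- cbind(as.matrix(grids), last)[ok, , drop = FALSE]
  colnames(out) <- NULL
  out
}

#' Re-estimate count apportionment by constrained grid search
#'
#' With the structure fixed, the likelihood separates over locus-pair
#' groups; within each group the apportionment fractions are optimized
#' exhaustively on a lattice with step `mu_grid`, subject to summing to one
#' and (for diploid-diploid `boxed` groups) the `mu_box` bounds.
#' Single-pair groups are forced to `mu = 1`.
#'
#' @param X n x 3 coordinates.
#' @param groups [contact_groups] output.
#' @param config [model_config].
#' @return Numeric vector of fractions along the rows of `groups`.
#' @export
mu_step <- function(X, groups, config = model_config()) {
  mu <- rep(1, nrow(groups))
  if (!nrow(groups)) return(mu)
  d <- .pair_dist(X, groups)
  logd <- log(d)
  for (g in unique(groups$group[duplicated(groups$group)])) {
    rows <- which(groups$group == g)
    box <- if (groups$boxed[rows[1]]) config$mu_box else c(0, 1)
    lat <- .mu_lattice(length(rows), config$mu_grid, box)
    cc <- groups$c[rows[1]]
    # objective: sum_r w * alpha * log d_r - lgamma(w + 1), w = mu * c
    obj <- lat %*% (cc * config$alpha * logd[rows]) -
      rowSums(lgamma(lat * cc + 1))
    mu[rows] <- lat[which.max(obj), ]
  }
  mu
}

#' Optimize bead coordinates for fixed apportionment
#'
#' Maximizes the Poisson log-likelihood over `X` by quasi-Newton ascent
#' (L-BFGS-B) with an analytic gradient.  The `d <= d_max` bound on chain
#' (adjacent-bead) distances is enforced through a smooth quadratic hinge
#' penalty; if the returned structure violates the bound by more than 1% of
#' `d_max`, the penalty weight is raised tenfold and the ascent repeated
#' (up to three times).
#'
#' @param X_init n x 3 starting coordinates.
#' @param mu Apportionment fractions along `groups`.
#' @param groups [contact_groups] output.
#' @param dmax Chain-distance upper bound ([estimate_dmax]).
#' @param config [model_config].
#' @param adj Adjacent bead pairs ([adjacent_bead_pairs]); the pairs the
#'   `d_max` bound applies to.
#' @param escalate Raise the penalty weight on violation (default TRUE).
#'   The alternating optimizer disables this so that every iteration
#'   ascends one fixed objective.
#' @return List: `X`, `loglik` (unpenalized), `penalized` (objective
#'   including the hinge term), `feasible`.
#' @export
structure_step <- function(X_init, mu, groups, dmax,
                           config = model_config(), adj = NULL,
                           escalate = TRUE) {
  n <- nrow(X_init)
  alpha <- config$alpha
  w <- mu * groups$c
  ii <- groups$i; jj <- groups$j
  if (is.null(adj)) adj <- cbind(integer(0), integer(0))
  ai <- adj[, 1]; aj <- adj[, 2]
  lam <- config$penalty
  eval_fn <- function(par, lam) {
    X <- matrix(par, n, 3)
    dx <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
    d <- pmax(sqrt(rowSums(dx^2)), 1e-9)
    f <- sum(w * alpha * log(d) - d^alpha)
    if (length(ai)) {
      da <- sqrt(rowSums((X[ai, , drop = FALSE] -
                            X[aj, , drop = FALSE])^2))
      f <- f - lam * sum(pmax(0, da - dmax)^2)
    }
    -f
  }
  eval_gr <- function(par, lam) {
    X <- matrix(par, n, 3)
    dx <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
    d <- pmax(sqrt(rowSums(dx^2)), 1e-9)
    coef <- w * alpha / d - alpha * d^(alpha - 1)
    contrib <- dx * (coef / d)
    gi <- c(ii, jj)
    gc_ <- rbind(contrib, -contrib)
    if (length(ai)) {
      dxa <- X[ai, , drop = FALSE] - X[aj, , drop = FALSE]
      da <- pmax(sqrt(rowSums(dxa^2)), 1e-9)
      pcoef <- -2 * lam * pmax(0, da - dmax)
      pc <- dxa * (pcoef / da)
      gi <- c(gi, ai, aj)
      gc_ <- rbind(gc_, pc, -pc)
    }
    G <- rowsum(gc_, gi)
    full <- matrix(0, n, 3)
    full[as.integer(rownames(G)), ] <- G
    -as.vector(full)
  }
  par <- as.vector(X_init)
  feasible <- TRUE
  for (attempt in seq_len(if (escalate) 3L else 1L)) {
    opt <- stats::optim(par, eval_fn, eval_gr, lam = lam,
                        method = "L-BFGS-B",
                        control = list(maxit = config$max_inner))
    par <- opt$par
    X <- matrix(par, n, 3)
    da <- if (length(ai)) sqrt(rowSums((X[ai, , drop = FALSE] -
                                          X[aj, , drop = FALSE])^2))
          else numeric(0)
    feasible <- !length(da) || max(da) <= dmax * 1.01
    if (feasible) break
    lam <- lam * 10
  }
  X <- matrix(par, n, 3)
  da <- if (length(ai)) sqrt(rowSums((X[ai, , drop = FALSE] -
                                        X[aj, , drop = FALSE])^2))
        else numeric(0)
  ll <- log_likelihood(X, mu, groups, alpha)
  list(X = X, loglik = ll,
       penalized = ll - .hinge_penalty(da, dmax, config$penalty),
       feasible = feasible)
}

#' Infer 3D genome structures by alternating optimization
#'
#' Jointly infers bead coordinates `X` and homolog count apportionments `mu`
#' maximizing the Poisson log-likelihood, by alternating (1) coordinate
#' ascent on `X` ([structure_step]) and (2) exact per-group grid search on
#' `mu` ([mu_step]).  Both steps are ascent steps, so the penalized
#' objective is non-decreasing across iterations.  The non-convex problem
#' is restarted from `config$restarts` random initializations (coordinates
#' drawn from an isotropic Gaussian scaled to the `d_max` ball;
#' apportionments uniform within each group); models are returned sorted by
#' log-likelihood, the first `ceiling(top_frac * restarts)` forming the
#' reported ensemble.
#'
#' @param counts Locus-level contact matrix (`contact_matrix` or bare
#'   matrix); typically the normalized matrix.
#' @param beadmap [build_bead_map].
#' @param bins Bin table (for adjacency in [estimate_dmax]).
#' @param config [model_config].
#' @param retained Optional per-locus mask.
#' @param dmax Override the estimated distance bound.
#' @return List of class `structure_ensemble`: models sorted by decreasing
#'   log-likelihood, each a list with `X` (n x 3), `mu` (the `groups` table
#'   plus a `mu` column), `loglik`, `penalized`, `converged`, `feasible`,
#'   `trace` (penalized objective per outer iteration) and `seed`.
#'   Attributes: `dmax`, `top_k`, `config`.
#' @export
infer_structure <- function(counts, beadmap, bins,
                            config = model_config(), retained = NULL,
                            dmax = NULL) {
  groups <- contact_groups(counts, beadmap, retained)
  if (!nrow(groups)) stop("no usable contact counts")
  if (is.null(dmax)) dmax <- estimate_dmax(counts, beadmap, bins,
                                           config$dmax_quantile)
  adj <- adjacent_bead_pairs(beadmap, bins)
  n <- beadmap$n
  models <- lapply(seq_len(config$restarts), function(r) {
    seed_r <- config$seed + r - 1L
    .with_seed(seed_r, {
      X <- matrix(stats::rnorm(n * 3, sd = dmax / 2), n, 3)
      mu <- stats::ave(rep(1, nrow(groups)), groups$group,
                       FUN = function(v) rep(1 / length(v), length(v)))
      trace <- numeric(0)
      prev <- -Inf
      converged <- FALSE
      st <- NULL
      for (iter in seq_len(config$max_outer)) {
        st <- structure_step(X, mu, groups, dmax, config, adj,
                             escalate = FALSE)
        X <- st$X
        mu <- mu_step(X, groups, config)
        da <- sqrt(rowSums((X[adj[, 1], , drop = FALSE] -
                              X[adj[, 2], , drop = FALSE])^2))
        cur <- log_likelihood(X, mu, groups, config$alpha) -
          .hinge_penalty(da, dmax, config$penalty)
        trace <- c(trace, cur)
        if (is.finite(prev) &&
            abs(cur - prev) <= config$rel_tol * max(1, abs(cur))) {
          converged <- TRUE
          break
        }
        prev <- cur
      }
      list(X = X, mu = cbind(groups, mu = mu),
           loglik = log_likelihood(X, mu, groups, config$alpha),
           penalized = trace[length(trace)], converged = converged,
           feasible = st$feasible, trace = trace, seed = seed_r)
    })
  })
  ord <- order(-vapply(models, `[[`, numeric(1), "loglik"))
  models <- models[ord]
  structure(models, class = "structure_ensemble", dmax = dmax,
            top_k = max(1L, ceiling(config$top_frac * config$restarts)),
            config = config)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  ll <- vapply(x, `[[`, numeric(1), "loglik")
  cat("structure_ensemble:", length(x), "models; best log-likelihood",
      format(max(ll)), "; top", attr(x, "top_k"), "retained\n")
  invisible(x)
}

#' RMSD between two structures after optimal superposition
#'
#' Centers both coordinate sets and finds the orthogonal transform (rotation,
#' optionally with reflection) minimizing the root-mean-square deviation
#' (Kabsch/Procrustes via SVD).  Distance-based likelihoods are invariant to
#' rigid motions and reflections, so reflection is allowed by default.
#'
#' @param X,Y n x 3 coordinate matrices (matched beads).
#' @param allow_reflection Permit an improper rotation (default TRUE).
#' @return RMSD after superposition.
#' @export
structure_rmsd <- function(X, Y, allow_reflection = TRUE) {
  stopifnot(all(dim(X) == dim(Y)))
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Xc) %*% Yc)
  R <- s$u %*% t(s$v)
  if (!allow_reflection && det(R) < 0) {
    u <- s$u
    u[, 3] <- -u[, 3]
    R <- u %*% t(s$v)
  }
  sqrt(mean(rowSums((Xc %*% R - Yc)^2)))
}

#' Diameter of a structure
#'
#' Largest inter-bead distance; used to express RMSD as a fraction of size.
#'
#' @param X n x 3 coordinates.
#' @return Scalar diameter.
#' @export
structure_diameter <- function(X) max(stats::dist(X))

#' Export a structure as TSV (and a PDB-like file for viewers)
#'
#' @param model One element of an [infer_structure] ensemble.
#' @param beadmap,bins The bead map and bin table the model was built on.
#' @param path Output TSV path (`bead`, `chrom`, `bin_start`, `copy`,
#'   `x`, `y`, `z`).
#' @param pdb Optional path for a minimal PDB-format trace (one CA atom per
#'   bead, chains by chromosome+copy).
#' @export
write_structure <- function(model, beadmap, bins, path, pdb = NULL) {
  X <- model$X
  loci <- beadmap$phi
  df <- data.frame(bead = seq_len(beadmap$n), chrom = bins$chrom[loci],
                   bin_start = bins$start[loci], copy = beadmap$copy,
                   x = X[, 1], y = X[, 2], z = X[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!is.null(pdb)) {
    sc <- 10 / max(1e-9, structure_diameter(X))   # viewer-friendly units
    lines <- sprintf(
      "ATOM  %5d  CA  BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      df$bead %% 100000, df$bead %% 10000,
      X[, 1] * sc, X[, 2] * sc, X[, 3] * sc)
    writeLines(c(lines, "END"), pdb)
  }
  invisible(path)
}
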