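test_that("the Poisson log term matches hand evaluation and a grid oracle", {
  # two haploid beads, c = 1, mu = 1, d = 1: term = 0 - 1 - log(Gamma(2)) = -1
  lay <- genome_layout(c(a = 2e6))
  bins <- make_bins(lay, 1e6)
  bm <- build_bead_map(bins, lay)
  M <- matrix(c(0, 1, 1, 0), 2, 2)
  gr <- contact_groups(M, bm)
  X <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(log_likelihood(X, rep(1, nrow(gr)), gr), -1)
  # zero-count pairs contribute nothing: adding an empty locus changes nothing
  lay3 <- genome_layout(c(a = 3e6))
  bins3 <- make_bins(lay3, 1e6)
  bm3 <- build_bead_map(bins3, lay3)
  M3 <- matrix(0, 3, 3); M3[1, 2] <- M3[2, 1] <- 1
  gr3 <- contact_groups(M3, bm3)
  X3 <- rbind(X, c(5, 5, 5))
  expect_equal(log_likelihood(X3, rep(1, nrow(gr3)), gr3), -1)
  # coincident beads in D are an error
  expect_error(log_likelihood(rbind(c(0, 0, 0), c(0, 0, 0)),
                              rep(1, nrow(gr)), gr), "coincident")
  # 1-D grid oracle: the per-pair term w*a*log(d) - d^a peaks at d = w^(1/a)
  w <- 4; a <- -3
  dgrid <- seq(0.2, 3, by = 1e-4)
  term <- w * a * log(dgrid) - dgrid^a
  expect_equal(dgrid[which.max(term)], w^(1 / a), tolerance = 1e-3)
  got <- vapply(c(0.5, w^(1 / a), 2), function(d)
    log_likelihood(rbind(c(0, 0, 0), c(d, 0, 0)), rep(1, nrow(gr)) * 1,
                   within(gr, c <- w), alpha = a), numeric(1))
  expect_gt(got[2], got[1])
  expect_gt(got[2], got[3])
})

test_that("likelihood is invariant under rigid motions and reflection", {
  fix <- planted_structure_fixture()
  cm <- simulate_counts_from_structure(fix$X, fix$beadmap, fix$bins,
                                       seed = 2)
  gr <- contact_groups(cm, fix$beadmap)
  mu <- mu_step(fix$X, gr)
  l0 <- log_likelihood(fix$X, mu, gr)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Xr <- sweep(fix$X %*% R, 2, c(3, -1, 2), "+")
  expect_equal(log_likelihood(Xr, mu, gr), l0, tolerance = 1e-9)
  Xm <- fix$X %*% diag(c(-1, 1, 1))
  expect_equal(log_likelihood(Xm, mu, gr), l0, tolerance = 1e-9)
})

test_that("d_max estimation uses the 97% quantile of adjacent c^(-1/3)", {
  lay <- genome_layout(c(a = 5e6))
  bins <- make_bins(lay, 1e6)
  bm <- build_bead_map(bins, lay)
  M <- matrix(0, 5, 5)
  for (k in 1:4) M[k, k + 1] <- M[k + 1, k] <- 8
  expect_equal(estimate_dmax(M, bm, bins), 8^(-1 / 3))
  # counts {1, 8} -> candidate distances {1, 0.5}; hand-computed type-7
  # interpolation at 0.97: 0.5 + 0.97 * (1 - 0.5)
  M2 <- matrix(0, 5, 5)
  M2[1, 2] <- M2[2, 1] <- 1
  M2[2, 3] <- M2[3, 2] <- 8
  expect_equal(estimate_dmax(M2, bm, bins), 0.985)
  # monotone: larger counts, smaller bound
  M3 <- M; M3[cbind(1:4, 2:5)] <- 64; M3[cbind(2:5, 1:4)] <- 64
  expect_lt(estimate_dmax(M3, bm, bins), estimate_dmax(M, bm, bins))
  # diploid loci are excluded from the adjacent-pair pool
  layd <- genome_layout(c(a = 5e6),
                        data.frame(chrom = "a", start = 3e6, end = 5e6,
                                   copy_number = 2))
  bmd <- build_bead_map(bins, layd)
  M4 <- M; M4[4, 5] <- M4[5, 4] <- 1e6
  expect_equal(estimate_dmax(M4, bmd, bins), estimate_dmax(M, bmd, bins))
})

test_that("mu grid search matches an exhaustive lattice oracle", {
  fix <- planted_structure_fixture()
  cm <- simulate_counts_from_structure(fix$X, fix$beadmap, fix$bins,
                                       seed = 4)
  gr <- contact_groups(cm, fix$beadmap)
  cfg <- model_config()
  set.seed(27)
  X <- fix$X + matrix(stats::rnorm(nrow(fix$X) * 3, 0, 0.05), ncol = 3)
  mu <- mu_step(X, gr, cfg)
  # group sums are exactly 1; box respected on diploid-diploid groups
  sums <- tapply(mu, gr$group, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(mu[gr$boxed] >= 0.3 - 1e-9 & mu[gr$boxed] <= 0.7 + 1e-9))
  # single-pair groups forced to 1
  single <- names(which(table(gr$group) == 1))
  expect_true(all(mu[gr$group %in% single] == 1))
  # oracle: brute-force over the 0.01 lattice, objective computed directly
  d <- sqrt(rowSums((X[gr$i, ] - X[gr$j, ])^2))
  for (g in sample(unique(gr$group[duplicated(gr$group)]), 10)) {
    rows <- which(gr$group == g)
    lo <- if (gr$boxed[rows[1]]) 0.3 else 0
    hi <- 1 - lo
    cand <- seq(lo, hi, by = 0.01)
    objs <- vapply(cand, function(m1) {
      m <- c(m1, 1 - m1)
      sum(m * gr$c[rows] * -3 * log(d[rows]) -
            lgamma(m * gr$c[rows] + 1))
    }, numeric(1))
    best <- cand[which.max(objs)]
    expect_equal(mu[rows][1], best, tolerance = 1e-9)
  }
})

test_that("a haploid-diploid group with one far copy pushes mu to its edge", {
  lay <- genome_layout(c(a = 1e6, b = 1e6),
                       data.frame(chrom = "b", start = 0, end = 1e6,
                                  copy_number = 2))
  bins <- make_bins(lay, 1e6)
  bm <- build_bead_map(bins, lay)
  M <- matrix(0, 2, 2); M[1, 2] <- M[2, 1] <- 20
  gr <- contact_groups(M, bm)
  expect_equal(nrow(gr), 2)          # haploid bead vs both copies
  expect_false(any(gr$boxed))
  # copy A at distance 0.4 (Poisson mean 15.6), copy B far away
  X <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(3, 0, 0))
  mu <- mu_step(X, gr)
  expect_equal(sum(mu), 1)
  expect_gte(mu[1], 0.95)
  # symmetric copies: equal split
  Xs <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(-0.4, 0, 0))
  expect_equal(mu_step(Xs, gr), c(0.5, 0.5))
})

test_that("structure step ascends and respects the chain bound", {
  fix <- planted_structure_fixture()
  cm <- simulate_counts_from_structure(fix$X, fix$beadmap, fix$bins,
                                       seed = 6)
  gr <- contact_groups(cm, fix$beadmap)
  adj <- adjacent_bead_pairs(fix$beadmap, fix$bins)
  expect_equal(nrow(adj), 19 + 4 + 4)   # chain links per chromosome copy
  cfg <- model_config(seed = 5)
  set.seed(28)
  X0 <- matrix(stats::rnorm(fix$beadmap$n * 3, 0, 0.3), ncol = 3)
  mu <- mu_step(X0, gr, cfg)
  dmax <- estimate_dmax(cm, fix$beadmap, fix$bins)
  before <- log_likelihood(X0, mu, gr)
  st <- structure_step(X0, mu, gr, dmax, cfg, adj)
  expect_gt(st$loglik, before)
})

test_that("three beads on a line are recovered from noise-free counts", {
  lay <- genome_layout(c(a = 3e6))
  bins <- make_bins(lay, 1e6)
  bm <- build_bead_map(bins, lay)
  d12 <- 0.2; d23 <- 0.25; d13 <- d12 + d23
  M <- matrix(0, 3, 3)
  M[1, 2] <- M[2, 1] <- round(d12^-3)
  M[2, 3] <- M[3, 2] <- round(d23^-3)
  M[1, 3] <- M[3, 1] <- round(d13^-3)
  cfg <- model_config(restarts = 3, seed = 9, max_outer = 30)
  ens <- infer_structure(M, bm, bins, cfg, dmax = 1)
  Xb <- ens[[1]]$X
  expect_equal(stats::dist(Xb)[1], M[1, 2]^(-1 / 3), tolerance = 0.01)
  expect_equal(stats::dist(Xb)[3], M[2, 3]^(-1 / 3), tolerance = 0.01)
  expect_equal(stats::dist(Xb)[2], M[1, 3]^(-1 / 3), tolerance = 0.01)
})

test_that("alternating optimization is monotone and seed-deterministic", {
  fix <- planted_structure_fixture()
  cm <- simulate_counts_from_structure(fix$X, fix$beadmap, fix$bins,
                                       seed = 7)
  cfg <- model_config(restarts = 2, seed = 11, max_outer = 12)
  ens1 <- infer_structure(cm, fix$beadmap, fix$bins, cfg)
  for (mod in ens1) {
    tr <- mod$trace
    expect_true(all(diff(tr) >= -1e-6 * pmax(1, abs(tr[-length(tr)]))))
  }
  ens2 <- infer_structure(cm, fix$beadmap, fix$bins, cfg)
  expect_identical(lapply(ens1, `[[`, "X"), lapply(ens2, `[[`, "X"))
  expect_identical(vapply(ens1, `[[`, numeric(1), "loglik"),
                   vapply(ens2, `[[`, numeric(1), "loglik"))
})

test_that("inferred distances correlate with a planted structure", {
  fix <- planted_structure_fixture()
  cm <- simulate_counts_from_structure(fix$X, fix$beadmap, fix$bins,
                                       seed = 5)
  cfg <- model_config(restarts = 4, seed = 2, max_outer = 30)
  ens <- infer_structure(cm, fix$beadmap, fix$bins, cfg)
  best <- ens[[1]]
  sp <- stats::cor(as.vector(stats::dist(fix$X)),
                   as.vector(stats::dist(best$X)), method = "spearman")
  expect_gt(sp, 0.95)
  expect_equal(attr(ens, "top_k"), 1)
})

test_that("all-haploid inference degenerates to fixed unit apportionment", {
  lay <- genome_layout(c(a = 4e6))
  bins <- make_bins(lay, 1e6)
  bm <- build_bead_map(bins, lay)
  set.seed(30)
  X <- matrix(stats::rnorm(12, 0, 0.3), 4, 3)
  cm <- simulate_counts_from_structure(X, bm, bins, seed = 12)
  gr <- contact_groups(cm, bm)
  expect_true(all(table(gr$group) == 1))
  expect_true(all(mu_step(X, gr) == 1))
})

test_that("superposition RMSD is zero for rigid copies, positive otherwise", {
  set.seed(31)
  X <- matrix(stats::rnorm(60), 20, 3)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- sweep(X %*% R, 2, c(1, 2, 3), "+")
  expect_lt(structure_rmsd(X, Y), 1e-8)
  expect_lt(structure_rmsd(X, Y %*% diag(c(-1, 1, 1))), 1e-8)
  expect_gt(structure_rmsd(X, Y + matrix(stats::rnorm(60, 0, 0.5), 20, 3)),
            0.1)
})
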