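test_that("expected fractions under an equal split match the closed form", {
  chrom <- rep(paste0("t", 1:4), each = 10)
  labels <- rep(rep(c("open", "closed"), each = 5), 4)
  ef3 <- expected_fractions(labels, chrom, 3)
  expect_equal(unname(ef3[c("all_open", "all_closed", "mixed")]),
               c(0.125, 0.125, 0.75))
  ef2 <- expected_fractions(labels, chrom, 2)
  expect_equal(unname(ef2[c("all_open", "all_closed", "mixed")]),
               c(0.25, 0.25, 0.50))
  # all bins open
  expect_equal(unname(expected_fractions(rep("open", 40), chrom, 2)[
    "all_open"]), 1)
  expect_equal(sum(ef3), 1, tolerance = 1e-9)
})

test_that("expected fractions equal brute-force enumeration on small genomes", {
  set.seed(23)
  for (rep in 1:6) {
    nchr <- sample(3:5, 1)
    chrom <- rep(paste0("c", seq_len(nchr)),
                 times = sample(4:12, nchr, TRUE))
    labels <- sample(c("open", "closed", NA), length(chrom), TRUE,
                     prob = c(0.45, 0.45, 0.1))
    if (length(chrom) > 60) next
    for (arity in 2:3) {
      ok <- tryCatch(expected_fractions(labels, chrom, arity),
                     error = function(e) NULL)
      if (is.null(ok)) next
      expect_equal(unname(ok[c("all_open", "all_closed", "mixed")]),
                   unname(oracle_fractions(labels, chrom, arity)),
                   tolerance = 1e-12)
    }
  }
})

test_that("observed fractions match expectation under uniform sampling", {
  set.seed(24)
  lay <- genome_layout(c(u = 10e6, v = 10e6, w = 10e6, x = 10e6))
  bins <- make_bins(lay, 1e6)
  labels <- rep(rep(c("open", "closed"), each = 5), 4)
  # uniform interchromosomal triples over three distinct chromosomes
  n <- 6000
  rows <- lapply(seq_len(n), function(i) {
    chrs <- sample(unique(bins$chrom), 3)
    b <- vapply(chrs, function(cn) sample(which(bins$chrom == cn), 1), 1L)
    ord <- order(bins$chrom[b], bins$start[b])
    b <- b[ord]
    data.frame(read_id = paste0("r", i), arity = 3L, class = "P-F",
               span = "inter", signature = NA_character_,
               chr1 = bins$chrom[b[1]], pos1 = bins$start[b[1]] + 10,
               strand1 = "+", prov1 = "1:left",
               chr2 = bins$chrom[b[2]], pos2 = bins$start[b[2]] + 10,
               strand2 = "+", prov2 = "1:right",
               chr3 = bins$chrom[b[3]], pos3 = bins$start[b[3]] + 10,
               strand3 = "+", prov3 = "2:whole")
  })
  contacts <- do.call(rbind, rows)
  obs <- observed_fractions(contacts, labels, bins$chrom, bins, 3)
  exp_ <- expected_fractions(labels, bins$chrom, 3)
  for (g in c("all_open", "all_closed", "mixed"))
    expect_lt(abs(obs[[g]] - exp_[[g]]), 0.03)  # ~4 MC sd
  expect_equal(sum(obs), 1, tolerance = 1e-9)
})

test_that("contacts drawn only among open bins give all-open = 100%", {
  lay <- genome_layout(c(u = 4e6, v = 4e6))
  bins <- make_bins(lay, 1e6)
  labels <- rep(c("open", "open", "closed", "closed"), 2)
  cc <- enumerate_contacts(end_F("u", 0.5e6), end_F("v", 1.5e6), "r1")
  obs <- observed_fractions(cc, labels, bins$chrom, bins, 2)
  expect_equal(obs[["all_open"]], 1)
})

test_that("DHS median split is deterministic and rank-invariant", {
  counts <- c(10, 3, 7, 2, 9, 1, 5, 4, 8, 6)
  lab <- dhs_classes(counts)
  expect_equal(sum(lab == "high"), 5)
  expect_equal(lab[counts > 5], rep("high", 5))
  expect_equal(dhs_classes(counts * 2), lab)
  expect_equal(sum(suppressWarnings(dhs_classes(rep(0, 100))) == "high"),
               50)
  expect_warning(dhs_classes(rep(1, 10)), "equal")
})

test_that("within-domain fraction applies the exclusion rules", {
  domains <- data.frame(chrom = "c1",
                        start = c(0, 50e4), end = c(50e4, 120e4))
  tri <- function(p1, p2, p3, id)
    data.frame(read_id = id, arity = 3L, class = "P-F", span = "intra",
               signature = NA, chr1 = "c1", pos1 = p1, strand1 = "+",
               prov1 = "1:left", chr2 = "c1", pos2 = p2, strand2 = "+",
               prov2 = "1:right", chr3 = "c1", pos3 = p3, strand3 = "+",
               prov3 = "2:whole")
  contacts <- rbind(
    tri(10e4, 20e4, 45e4, "in_domain"),       # all in domain 1
    tri(10e4, 30e4, 80e4, "spans_boundary"),  # crosses into domain 2
    tri(10e4, 10.5e4, 45e4, "same_window"),   # two loci in one 40 kb window
    tri(10e4, 10.9e4, 11.8e4, "short_range")) # span < 20 kb
  fr <- within_domain_fraction(contacts, domains)
  expect_equal(attr(fr, "n_eligible"), 2)
  expect_equal(attr(fr, "n_within"), 1)
  expect_equal(as.numeric(fr), 0.5)
})

test_that("domain shuffling preserves per-arm length multisets", {
  set.seed(25)
  arms <- data.frame(chrom = c("c1", "c1"), start = c(0, 5e6),
                     end = c(5e6, 11e6))
  domains <- data.frame(chrom = "c1",
                        start = c(0.2e6, 1.4e6, 3.1e6, 5.5e6, 8.0e6),
                        end   = c(1.0e6, 2.9e6, 4.0e6, 7.5e6, 9.9e6))
  for (rep in 1:10) {
    sh <- shuffle_domains(domains, arms)
    expect_equal(nrow(sh), nrow(domains))
    for (a in 1:2) {
      in_arm <- function(d) d$start >= arms$start[a] & d$start < arms$end[a]
      expect_equal(sort(sh$end[in_arm(sh)] - sh$start[in_arm(sh)]),
                   sort(domains$end[in_arm(domains)] -
                          domains$start[in_arm(domains)]))
      expect_true(all(sh$start[in_arm(sh)] >= arms$start[a]))
      expect_true(all(sh$end[in_arm(sh)] <= arms$end[a]))
    }
  }
})

test_that("shuffle null: invariant cover gives z ~ 0, planted signal large z", {
  # equal-length domains tiling the arm completely: every shuffle is the
  # same cover, so the fraction is unchanged and z is defined as 0
  arms <- data.frame(chrom = "c1", start = 0, end = 4e6)
  tiling <- data.frame(chrom = "c1", start = c(0, 1e6, 2e6, 3e6),
                       end = c(1e6, 2e6, 3e6, 4e6))
  tri <- function(p1, p2, p3, id)
    data.frame(read_id = id, arity = 3L, class = "P-F", span = "intra",
               signature = NA, chr1 = "c1", pos1 = p1, strand1 = "+",
               prov1 = "1:left", chr2 = "c1", pos2 = p2, strand2 = "+",
               prov2 = "1:right", chr3 = "c1", pos3 = p3, strand3 = "+",
               prov3 = "2:whole")
  contacts <- rbind(tri(0.1e6, 0.5e6, 0.9e6, "a"),
                    tri(1.1e6, 1.6e6, 2.4e6, "b"),
                    tri(2.05e6, 2.5e6, 2.95e6, "c"))
  null1 <- shuffle_null(contacts, tiling, arms, replicates = 20, seed = 7)
  expect_equal(null1$z, 0)
  expect_equal(null1$sd, 0)

  # triples planted inside narrow true domains stand far above the null
  set.seed(26)
  arms2 <- data.frame(chrom = "c1", start = 0, end = 50e6)
  dom2 <- data.frame(chrom = "c1", start = seq(0, 45e6, by = 5e6) + 2e6,
                     end = seq(0, 45e6, by = 5e6) + 2.5e6)
  planted <- do.call(rbind, lapply(1:60, function(i) {
    d <- dom2[sample(nrow(dom2), 1), ]
    p <- sort(stats::runif(3, d$start, d$end))
    while (max(p) - min(p) < 2e4 ||
           anyDuplicated(floor(p / 4e4)) > 0)
      p <- sort(stats::runif(3, d$start, d$end))
    tri(p[1], p[2], p[3], paste0("p", i))
  }))
  null2 <- shuffle_null(planted, dom2, arms2, replicates = 40, seed = 8)
  expect_equal(null2$observed, 1)
  expect_gt(null2$z, 5)
  # determinism under a fixed seed
  null2b <- shuffle_null(planted, dom2, arms2, replicates = 40, seed = 8)
  expect_identical(null2$replicates, null2b$replicates)
})

test_that("boundary overlap counts coinciding or adjacent boundaries", {
  a <- data.frame(chrom = "c1", start = c(1e6, 3e6), end = c(2e6, 4e6))
  expect_equal(boundary_overlap(a, a), 100)
  b_far <- data.frame(chrom = "c1", start = 5e6, end = 6e6)
  expect_equal(boundary_overlap(a, b_far), 0)
  # boundaries sharing one edge (adjacent intervals) overlap
  b_adj <- data.frame(chrom = "c1", start = 2e6, end = 3e6)
  expect_equal(boundary_overlap(b_adj, a), 100)
  # tolerance widens matching to binned boundaries: the 1.04/3.04 Mb edges
  # match a's 1 Mb and 3 Mb boundaries, the 2 Mb and 4 Mb ones stay unmatched
  b_near <- data.frame(chrom = "c1", start = 1.04e6, end = 3.04e6)
  expect_equal(boundary_overlap(a, b_near, tol = 4e4), 50)
  expect_equal(boundary_overlap(b_near, a, tol = 4e4), 100)
})
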