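test_that("end classification follows the two-phase decision tree", {
  whole <- data.frame(qname = "r", end = 1L, fragment = "whole",
                      chrom = "c1", pos = 10, strand = "+", mapq = 60L,
                      nm = 0L, unique = TRUE)
  frag <- function(side, chrom, pos)
    data.frame(qname = "r", end = 1L, fragment = side, chrom = chrom,
               pos = pos, strand = "+", mapq = 60L, nm = 0L, unique = TRUE)
  expect_equal(classify_end(whole, NULL, NA)$status, "F")
  expect_equal(classify_end(NULL, rbind(frag("left", "c1", 5),
                                        frag("right", "c2", 9)), 1)$status,
               "P2")
  expect_equal(classify_end(NULL, frag("left", "c1", 5), 1)$status, "P1")
  expect_equal(classify_end(NULL, NULL, 0)$status, "none")
  expect_equal(classify_end(NULL, frag("left", "c1", 5), 2)$status, "none")
  expect_error(classify_end(NULL, rbind(frag("left", "c1", 5),
                                        frag("left", "c1", 7)), 1))
})

test_that("contact enumeration yields every subset of mapped loci", {
  eF <- end_F("c1", 100)
  eF2 <- end_F("c2", 5e6, "-")
  eP <- end_P2("c3", 1e6, "+", "c4", 2e6, "+")
  ePb <- end_P2("c5", 3e6, "-", "c6", 4e6, "+")

  cc <- enumerate_contacts(eF, eF2, "r1")
  expect_equal(nrow(cc), 1)
  expect_equal(cc$class, "F-F")

  cc <- enumerate_contacts(eP, eF2, "r2")
  expect_equal(sum(cc$arity == 2), 3)
  expect_equal(sum(cc$arity == 3), 1)
  expect_true(all(cc$class == "P-F"))

  cc <- enumerate_contacts(eP, ePb, "r3")
  expect_equal(sum(cc$arity == 2), 6)
  expect_equal(sum(cc$arity == 3), 4)
  expect_equal(sum(cc$arity == 4), 1)
  expect_true(all(cc$class == "P-P"))

  expect_equal(nrow(enumerate_contacts(eF, end_none(), "r4")), 0)
})

test_that("enumeration counts equal choose(|L|, k) for random end configs", {
  set.seed(11)
  for (rep in 1:15) {
    n1 <- sample(0:2, 1); n2 <- sample(0:2, 1)
    mk <- function(n, eidx) {
      if (n == 0) return(end_none())
      loci <- do.call(rbind, lapply(seq_len(n), function(i)
        data.frame(chrom = paste0("c", sample(6, 1)),
                   pos = sample(1e7, 1), strand = sample(c("+", "-"), 1),
                   fragment = if (n == 1) "whole"
                              else c("left", "right")[i])))
      make_end(if (n == 1) sample(c("F", "P1"), 1) else "P2", loci)
    }
    cc <- enumerate_contacts(mk(n1, 1), mk(n2, 2), "r")
    L <- n1 + n2
    for (k in 2:4)
      expect_equal(sum(cc$arity == k),
                   if (L >= k) choose(L, k) else 0)
    expect_true(sum(cc$arity == 2) %in% c(0, 1, 3, 6))
    expect_true(sum(cc$arity == 3) %in% c(0, 1, 4))
    expect_true(sum(cc$arity == 4) %in% c(0, 1))
  }
})

test_that("span classes separate intra, inter and mixed contacts", {
  eP <- end_P2("c1", 1e6, "+", "c1", 9e6, "+")
  cc <- enumerate_contacts(eP, end_F("c1", 5e6), "r")
  expect_true(all(cc$span == "intra"))
  cc2 <- enumerate_contacts(eP, end_F("c2", 5e6), "r")
  tri <- cc2[cc2$arity == 3, ]
  expect_equal(tri$span, "mixed")
  cc3 <- enumerate_contacts(end_P2("c1", 1e6, "+", "c2", 2e6, "+"),
                            end_F("c3", 5e6), "r")
  expect_equal(cc3$span[cc3$arity == 3], "inter")
})

test_that("orientation signatures concatenate per-end strand signs", {
  expect_equal(orientation_signature(end_F("c1", 1, "+"),
                                     end_F("c1", 2, "+")), "+/+")
  expect_equal(orientation_signature(
    end_P2("c1", 1, "+", "c1", 2, "+"), end_F("c1", 3, "-")), "++/-")
  expect_equal(orientation_signature(
    end_P2("c1", 1, "+", "c1", 2, "-"), end_F("c1", 3, "+")), "+-/+")
})

test_that("religation-free chimeric doubles beyond 1 kb have ~uniform signs", {
  g <- simulate_genome(c(chrS1 = 2e5), seed = 41)
  cfg <- sim_config(n_reads = 260, seed = 41, intra_fraction = 1,
                    class_fractions = c(sonication = 0, two = 1, three = 0,
                                        four = 0))
  lib <- simulate_library(g, cfg)
  contacts <- call_contacts(lib$reads1, lib$reads2, g$genome,
                            enzyme_set("single"), min_dist = 1000)
  dbl <- contacts[contacts$arity == 2 & contacts$span == "intra" &
                    contacts$class == "F-F", ]
  sig <- table(factor(dbl$signature, c("+/+", "+/-", "-/+", "-/-")))
  expect_gte(sum(sig), 50)
  frac <- as.numeric(sig) / sum(sig)
  expect_true(all(frac > 0.10 & frac < 0.45))
})

test_that("distance filter drops close intrachromosomal loci only", {
  close_d <- enumerate_contacts(end_F("c1", 100), end_F("c1", 600, "-"),
                                "r")
  expect_equal(nrow(apply_distance_filter(close_d, 1000)), 0)
  expect_equal(nrow(apply_distance_filter(close_d, 0)), 1)
  inter3 <- enumerate_contacts(end_P2("c1", 1e6, "+", "c2", 2e6, "+"),
                               end_F("c3", 5e6), "r")
  expect_equal(nrow(apply_distance_filter(inter3, 2e4)), nrow(inter3))
  # a triple with one close pair is dropped even if the others are distant
  tri <- enumerate_contacts(end_P2("c1", 1e6, "+", "c1", 1.0005e6, "+"),
                            end_F("c2", 5e6), "r")
  kept <- apply_distance_filter(tri, 1000)
  expect_equal(sum(kept$arity == 3), 0)
  expect_equal(sum(kept$arity == 2), 2)
})

test_that("contact tables round-trip through TSV bit-exactly", {
  cc <- rbind(enumerate_contacts(end_P2("c1", 1e6, "+", "c2", 2e6, "-"),
                                 end_F("c3", 5e6), "r1"),
              enumerate_contacts(end_F("c1", 100), end_F("c2", 7e6, "-"),
                                 "r2"))
  f <- tempfile(fileext = ".tsv")
  write_contacts(cc, f)
  back <- read_contacts(f)
  expect_equal(back, cc, ignore_attr = TRUE)
  f2 <- tempfile()
  write_pairs(cc, f2)
  pairs <- utils::read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(pairs), sum(cc$arity == 2))
})

test_that("library summary tabulates arity-by-span categories", {
  cc <- rbind(enumerate_contacts(end_P2("c1", 1e6, "+", "c2", 2e6, "-"),
                                 end_F("c3", 5e6), "r1"),
              enumerate_contacts(end_F("c1", 100), end_F("c2", 7e6, "-"),
                                 "r2"))
  cs <- contact_summary(cc)
  expect_equal(nrow(cs), 9)
  expect_equal(sum(cs$count), nrow(cc))
  expect_equal(cs$count[cs$arity == 3 & cs$span == "inter"], 1)
})
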