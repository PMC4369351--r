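# Shared fixtures and independent oracles, all built in code.

# classified-end constructors
make_loci <- function(...) {
  do.call(rbind, lapply(list(...), function(v)
    data.frame(chrom = v[[1]], pos = as.numeric(v[[2]]), strand = v[[3]],
               fragment = v[[4]], stringsAsFactors = FALSE)))
}
make_end <- function(status, loci) list(status = status, loci = loci)
end_F <- function(chrom, pos, strand = "+")
  make_end("F", make_loci(list(chrom, pos, strand, "whole")))
end_P2 <- function(c1, p1, s1, c2, p2, s2)
  make_end("P2", make_loci(list(c1, p1, s1, "left"), list(c2, p2, s2, "right")))
end_none <- function()
  make_end("none", data.frame(chrom = character(), pos = numeric(),
                              strand = character(), fragment = character(),
                              stringsAsFactors = FALSE))

# brute-force motif-count oracle: slide over every substring
oracle_site_count <- function(read, enzymes) {
  n <- 0L
  for (e in enzymes) {
    pats <- unique(c(e$site, multiway3c::revcomp(e$site)))
    for (s in seq_len(nchar(read) - nchar(e$site) + 1)) {
      sub <- substr(read, s, s + nchar(e$site) - 1)
      if (sub %in% pats) n <- n + 1L
    }
  }
  n
}

# brute-force enumeration oracle for expected group fractions
oracle_fractions <- function(labels, chrom, arity) {
  ok <- !is.na(labels)
  labels <- labels[ok]; chrom <- chrom[ok]
  idx <- seq_along(labels)
  cmb <- utils::combn(idx, arity)
  tall <- c(all_open = 0, all_closed = 0, mixed = 0)
  total <- 0
  for (j in seq_len(ncol(cmb))) {
    s <- cmb[, j]
    if (length(unique(chrom[s])) != arity) next
    total <- total + 1
    labs <- labels[s]
    if (all(labs == "open")) tall["all_open"] <- tall["all_open"] + 1
    else if (all(labs == "closed")) tall["all_closed"] <- tall["all_closed"] + 1
    else tall["mixed"] <- tall["mixed"] + 1
  }
  tall / total
}

# independent enumeration of the contacts a truth table implies surviving a
# distance filter
oracle_contacts_from_truth <- function(truth, min_dist = 1000) {
  out <- character(0)
  for (r in seq_len(nrow(truth))) {
    L <- rbind(parse_truth_loci(truth$loci1[r]),
               parse_truth_loci(truth$loci2[r]))
    if (nrow(L) < 2) next
    for (k in 2:min(4, nrow(L))) {
      cmb <- utils::combn(nrow(L), k)
      for (j in seq_len(ncol(cmb))) {
        s <- L[cmb[, j], ]
        drop <- FALSE
        for (a in 1:(k - 1)) for (b in (a + 1):k)
          if (s$chrom[a] == s$chrom[b] &&
              abs(s$pos[a] - s$pos[b]) < min_dist) drop <- TRUE
        if (drop) next
        s <- s[order(s$chrom, s$pos), ]
        out <- c(out, paste(truth$read_id[r], k,
                            paste(s$chrom, s$pos, collapse = "|"),
                            sep = "#"))
      }
    }
  }
  sort(out)
}

contact_keys <- function(contacts) {
  sort(vapply(seq_len(nrow(contacts)), function(r) {
    k <- contacts$arity[r]
    paste(contacts$read_id[r], k,
          paste(unlist(contacts[r, paste0("chr", 1:k)]),
                unlist(contacts[r, paste0("pos", 1:k)]), collapse = "|"),
          sep = "#")
  }, ""))
}

# near-haploid toy: one haploid + one fully diploid chromosome
toy_diploid_layout <- function(hap_mb = 8, dip_mb = 4) {
  genome_layout(c(h1 = hap_mb * 1e6, d1 = dip_mb * 1e6),
                data.frame(chrom = "d1", start = 0, end = dip_mb * 1e6,
                           copy_number = 2))
}

# dense random symmetric count matrix
random_symmetric_counts <- function(m, seed = 1, lambda = 20) {
  set.seed(seed)
  M <- matrix(stats::rpois(m * m, lambda) + 1, m, m)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

as_cm <- function(M, bins) {
  structure(list(counts = Matrix::Matrix(M, sparse = TRUE), bins = bins),
            class = "contact_matrix")
}

# 30-bead planted-structure fixture: 20-bead haploid chromosome plus a
# 5-locus diploid chromosome (two translated copies), compact enough that
# unit-intensity Poisson counts are informative at every distance
planted_structure_fixture <- function(seed = 3) {
  set.seed(seed)
  lay <- genome_layout(c(g1 = 20e6, g2 = 5e6),
                       data.frame(chrom = "g2", start = 0, end = 5e6,
                                  copy_number = 2))
  bins <- make_bins(lay, 1e6)
  bm <- build_bead_map(bins, lay)
  walk <- function(n, start, step) {
    X <- matrix(0, n, 3); X[1, ] <- start
    for (i in 2:n) X[i, ] <- X[i - 1, ] + stats::rnorm(3, 0, step)
    X
  }
  XA <- walk(5, c(0.35, 0.2, 0), 0.07)
  XB <- sweep(XA, 2, c(-0.55, -0.35, 0.15), "+")
  Xstar <- rbind(walk(20, c(0, 0, 0), 0.07), XA, XB)
  list(layout = lay, bins = bins, beadmap = bm, X = Xstar)
}
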