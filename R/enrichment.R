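.sym_sums <- function(v) {
  s1 <- sum(v); s2 <- sum(v^2); s3 <- sum(v^3)
  c(e2 = (s1^2 - s2) / 2, e3 = (s1^3 - 3 * s1 * s2 + 2 * s3) / 6)
}

#' Expected compartment-group fractions by exact enumeration
#'
#' Enumerates (in closed form, via per-chromosome label counts) all
#' interchromosomal bin pairs (arity 2) or bin triples on three distinct
#' chromosomes (arity 3), and returns the fraction falling in each group:
#' all first-label ("all_open"), all second-label ("all_closed"), or mixed.
#' With exactly equal open/closed counts on every chromosome these fractions
#' are 25/25/50 for pairs and 12.5/12.5/75 for triples.
#'
#' @param labels Character vector of per-bin labels (two levels, e.g.
#'   "open"/"closed"; NA bins are excluded).  Callers should already have
#'   restricted bins to mappable ones.
#' @param chrom Chromosome per bin.
#' @param arity 2 or 3.
#' @param levels The two label values, in (all_open, all_closed) order.
#' @return Named numeric vector `c(all_open=, all_closed=, mixed=)` of
#'   fractions summing to 1; attribute `total` holds the tuple count.
#' @export
expected_fractions <- function(labels, chrom, arity = 2,
                               levels = c("open", "closed")) {
  stopifnot(arity %in% 2:3)
  ok <- !is.na(labels)
  labels <- labels[ok]; chrom <- chrom[ok]
  cs <- unique(chrom)
  n_c <- vapply(cs, function(x) sum(chrom == x), numeric(1))
  o_c <- vapply(cs, function(x) sum(chrom == x & labels == levels[1]),
                numeric(1))
  c_c <- vapply(cs, function(x) sum(chrom == x & labels == levels[2]),
                numeric(1))
  key <- if (arity == 2) "e2" else "e3"
  total <- .sym_sums(n_c)[[key]]
  all_open <- .sym_sums(o_c)[[key]]
  all_closed <- .sym_sums(c_c)[[key]]
  if (total <= 0) stop("no eligible tuples")
  out <- c(all_open = all_open, all_closed = all_closed,
           mixed = total - all_open - all_closed) / total
  attr(out, "total") <- total
  out
}

#' Observed compartment-group fractions of contacts
#'
#' Contact-weighted analogue of [expected_fractions]: among interchromosomal
#' doubles (arity 2) or triples linking three distinct chromosomes
#' (arity 3) whose loci all fall in labelled bins, the fraction whose labels
#' are all first-level, all second-level, or mixed.  The ratio
#' observed/expected per group is 1 under uniform sampling of eligible
#' tuples; a ratio > 1 is an enrichment.
#'
#' @param contacts Contact table.
#' @param labels,chrom Per-bin labels and chromosomes (aligned with `bins`).
#' @param bins Bin table used to map loci to bins.
#' @param arity 2 or 3.
#' @param levels Label values as in [expected_fractions].
#' @return Named fractions as in [expected_fractions]; attribute `total` is
#'   the number of contributing contacts.
#' @export
observed_fractions <- function(contacts, labels, chrom, bins, arity = 2,
                               levels = c("open", "closed")) {
  stopifnot(arity %in% 2:3)
  d <- contacts[contacts$arity == arity & contacts$span == "inter", ,
                drop = FALSE]
  tallies <- c(all_open = 0, all_closed = 0, mixed = 0)
  if (nrow(d)) {
    labmat <- sapply(seq_len(arity), function(i) {
      b <- assign_bins(d[[paste0("chr", i)]], d[[paste0("pos", i)]], bins)
      labels[b]
    })
    labmat <- matrix(labmat, ncol = arity)
    ok <- rowSums(is.na(labmat)) == 0
    labmat <- labmat[ok, , drop = FALSE]
    n_open <- rowSums(labmat == levels[1])
    tallies["all_open"] <- sum(n_open == arity)
    tallies["all_closed"] <- sum(rowSums(labmat == levels[2]) == arity)
    tallies["mixed"] <- nrow(labmat) - tallies["all_open"] -
      tallies["all_closed"]
  }
  total <- sum(tallies)
  if (total == 0) stop("no eligible contacts")
  out <- tallies / total
  attr(out, "total") <- total
  out
}

#' Label bins as high/low DNase hypersensitivity
#'
#' Sorts bins by decreasing DHS count and labels the top half "high", the
#' bottom half "low" (median split; `floor(n/2)` bins are "high").  Ties are
#' broken deterministically by bin index; a fully tied input still splits
#' deterministically, with a warning.
#'
#' @param dhs_count DHS peak count per bin.
#' @return Character vector "high"/"low".
#' @export
dhs_classes <- function(dhs_count) {
  n <- length(dhs_count)
  ord <- order(-dhs_count, seq_len(n))
  lab <- rep("low", n)
  lab[ord[seq_len(floor(n / 2))]] <- "high"
  if (length(unique(dhs_count)) == 1L)
    warning("all DHS counts equal; median split is arbitrary (by bin index)")
  lab
}

.domains_df <- function(domains) {
  if (inherits(domains, "GRanges"))
    domains <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(domains)),
      start = GenomicRanges::start(domains) - 1,
      end = GenomicRanges::end(domains), stringsAsFactors = FALSE)
  domains
}

#' Fraction of intrachromosomal triples within one topological domain
#'
#' Among intrachromosomal triples, excludes short-range ones (maximum
#' pairwise span < `min_span`) and those linking at least two loci within
#' the same `window`-bp window (both would trivially inflate the fraction),
#' then returns the fraction of the remainder whose three loci all lie
#' inside a single domain interval.
#'
#' @param contacts Contact table (arity-3 intra rows are used).
#' @param domains Domains as data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open) or [GenomicRanges::GRanges].
#' @param min_span Short-range exclusion threshold in bp (default 20 kb).
#' @param window Same-window exclusion size in bp (default 40 kb).
#' @return Fraction in `[0, 1]`; attributes `n_within` and `n_eligible`.
#' @export
within_domain_fraction <- function(contacts, domains, min_span = 2e4,
                                   window = 4e4) {
  domains <- .domains_df(domains)
  tr <- contacts[contacts$arity == 3L & contacts$span == "intra", ,
                 drop = FALSE]
  if (!nrow(tr)) stop("no intrachromosomal triples")
  pos <- as.matrix(tr[, c("pos1", "pos2", "pos3")])
  span <- apply(pos, 1, function(p) max(p) - min(p))
  same_win <- apply(floor(pos / window), 1,
                    function(w) anyDuplicated(w) > 0)
  eligible <- span >= min_span & !same_win
  tr <- tr[eligible, , drop = FALSE]
  pos <- pos[eligible, , drop = FALSE]
  if (!nrow(tr)) stop("no eligible triples after exclusions")
  within <- vapply(seq_len(nrow(tr)), function(r) {
    dd <- domains[domains$chrom == tr$chr1[r], , drop = FALSE]
    any(dd$start <= min(pos[r, ]) & max(pos[r, ]) < dd$end)
  }, logical(1))
  out <- mean(within)
  attr(out, "n_within") <- sum(within)
  attr(out, "n_eligible") <- nrow(tr)
  out
}

#' Shuffled-domain null for the within-domain fraction
#'
#' Generates `replicates` random domain decompositions that preserve, for
#' each chromosome arm, the multiset of domain lengths and of inter-domain
#' gap lengths (domains and gaps are re-laid in a random order from the arm
#' start), recomputes the within-domain triple fraction for each, and
#' reports the z-score of the observed fraction against this null.
#'
#' @param contacts Contact table.
#' @param domains Observed domains (data.frame or GRanges, 0-based
#'   half-open).
#' @param arms Chromosome-arm intervals (data.frame `chrom`, `start`,
#'   `end`); domains are assigned to the arm containing their start.
#' @param replicates Number of shuffles (default 100).
#' @param seed Random seed for reproducibility.
#' @param min_span,window Passed to [within_domain_fraction].
#' @return List: `observed`, `replicates` (vector of null fractions),
#'   `mean`, `sd`, `z` (0 when sd is 0 and observed equals the mean).
#' @export
shuffle_null <- function(contacts, domains, arms, replicates = 100L,
                         seed = 1L, min_span = 2e4, window = 4e4) {
  stopifnot(replicates > 1)
  domains <- .domains_df(domains)
  arms <- .domains_df(arms)
  obs <- within_domain_fraction(contacts, domains, min_span, window)
  rng <- .with_seed(seed, {
    vapply(seq_len(replicates), function(r) {
      shuf <- shuffle_domains(domains, arms)
      as.numeric(within_domain_fraction(contacts, shuf, min_span, window))
    }, numeric(1))
  })
  mu <- mean(rng); sdev <- stats::sd(rng)
  z <- if (sdev > 0) (as.numeric(obs) - mu) / sdev
       else if (isTRUE(all.equal(as.numeric(obs), mu))) 0
       else sign(as.numeric(obs) - mu) * Inf
  list(observed = as.numeric(obs), replicates = rng, mean = mu, sd = sdev,
       z = z)
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Randomly re-lay domains within chromosome arms
#'
#' One shuffle of the null in [shuffle_null]: per arm, the observed domain
#' intervals and the gaps between them are collected and re-laid
#' consecutively from the arm start in a uniformly random order.  The
#' per-arm multisets of domain lengths and of gap lengths (and hence the
#' covered fraction) are preserved exactly.
#'
#' @param domains data.frame of domains (0-based half-open).
#' @param arms data.frame of arm intervals.
#' @return data.frame of shuffled domains.
#' @export
shuffle_domains <- function(domains, arms) {
  domains <- .domains_df(domains)
  arms <- .domains_df(arms)
  out <- list()
  for (a in seq_len(nrow(arms))) {
    d <- domains[domains$chrom == arms$chrom[a] &
                   domains$start >= arms$start[a] &
                   domains$start < arms$end[a], , drop = FALSE]
    if (!nrow(d)) next
    d <- d[order(d$start), , drop = FALSE]
    edges <- c(arms$start[a], as.vector(rbind(d$start, d$end)), arms$end[a])
    lens <- diff(edges)
    types <- rep(c("gap", "domain"), length.out = length(lens))
    keep <- lens > 0 | types == "domain"
    lens <- lens[keep]; types <- types[keep]
    ord <- sample(length(lens))
    lens <- lens[ord]; types <- types[ord]
    ends <- arms$start[a] + cumsum(lens)
    starts <- ends - lens
    isd <- types == "domain"
    out[[length(out) + 1L]] <- data.frame(
      chrom = arms$chrom[a], start = starts[isd], end = ends[isd],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Percent of domain boundaries shared between two decompositions
#'
#' Boundaries are the start/end coordinates of each domain, treated as 1-bp
#' features; two boundaries are deemed overlapping if they coincide or are
#' adjacent (distance <= `tol` bp, default 1).  Returns the percentage of
#' `a`'s boundaries with an overlapping boundary in `b`.
#'
#' @param a,b Domain sets (data.frame or GRanges).
#' @param tol Maximum distance in bp to call two boundaries overlapping /
#'   adjacent (default 1; use the bin size for binned domain calls).
#' @return Percentage in `[0, 100]`.
#' @export
boundary_overlap <- function(a, b, tol = 1) {
  a <- .domains_df(a); b <- .domains_df(b)
  pa <- unique(data.frame(chrom = rep(a$chrom, 2), pos = c(a$start, a$end)))
  pb <- unique(data.frame(chrom = rep(b$chrom, 2), pos = c(b$start, b$end)))
  if (!nrow(pa)) return(NaN)
  hit <- vapply(seq_len(nrow(pa)), function(i) {
    cand <- pb$pos[pb$chrom == pa$chrom[i]]
    length(cand) > 0 && min(abs(cand - pa$pos[i])) <= tol
  }, logical(1))
  100 * mean(hit)
}
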