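#' Simulation configuration
#'
#' Defaults mirror the assayed library design: sonicated, ~250 bp
#' size-selected molecules sequenced 100 bp from each end, digestion with a
#' single 4-cutter (DpnII).  Molecule classes: plain sonication products
#' (no ligation junction), and 2-/3-/4-fragment ligation chimeras.
#' Sonication products dominate real libraries; the default mix keeps them
#' the largest class while producing enough multi-way molecules to exercise
#' every contact type.
#'
#' @param n_reads Number of read pairs.
#' @param read_length Read length per end (bp).
#' @param fragment_size Nominal sonication/size-selection length (bp).
#' @param class_fractions Named fractions (sonication, two, three, four)
#'   summing to 1.
#' @param intra_fraction Probability that a ligation partner fragment comes
#'   from the same chromosome.
#' @param enzymes Enzyme set name or list ([enzyme_set]).
#' @param flip_prob Probability that a ligated fragment is inserted
#'   reverse-complemented (palindromic sites religate in either
#'   orientation).
#' @param error_rate Per-base substitution rate applied to reads (default 0,
#'   error-free).
#' @param min_frag Minimum split-fragment length assumed recoverable
#'   (matches the mapping pipeline's default, 16 bp).
#' @param seed Random seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_reads = 200L, read_length = 100L,
                       fragment_size = 250L,
                       class_fractions = c(sonication = 0.40, two = 0.40,
                                           three = 0.15, four = 0.05),
                       intra_fraction = 0.5, enzymes = "single",
                       flip_prob = 0.5, error_rate = 0, min_frag = 16L,
                       seed = 1L) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-9,
            read_length <= fragment_size,
            all(c("sonication", "two", "three", "four") %in%
                  names(class_fractions)))
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 fragment_size = as.integer(fragment_size),
                 class_fractions = class_fractions,
                 intra_fraction = intra_fraction,
                 enzymes = enzyme_set(enzymes), flip_prob = flip_prob,
                 error_rate = error_rate, min_frag = as.integer(min_frag),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random genome
#'
#' Uniform base composition (so a 4-bp motif occurs at density ~4^-4 per
#' bp, giving restriction fragments of ~256 bp on average).  An optional
#' repeated segment copies part of the first chromosome elsewhere, to
#' exercise uniqueness filtering.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param ploidy_segments Optional ploidy table (see [genome_layout]).
#' @param seed Random seed.
#' @param repeat_bp If > 0, copy this many bp from the start of chromosome 1
#'   into the middle of the last chromosome.
#' @return List: `genome` ([Biostrings::DNAStringSet]), `layout`
#'   ([genome_layout]).
#' @export
simulate_genome <- function(chrom_lengths = c(chrS1 = 1e5, chrS2 = 1e5),
                            ploidy_segments = NULL, seed = 1L,
                            repeat_bp = 0L) {
  seqs <- .with_seed(seed, {
    lapply(chrom_lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
  })
  if (repeat_bp > 0 && length(seqs) > 1) {
    src <- substr(seqs[[1]], 1, repeat_bp)
    last <- length(seqs)
    mid <- floor(nchar(seqs[[last]]) / 2)
    seqs[[last]] <- paste0(substr(seqs[[last]], 1, mid), src,
                           substr(seqs[[last]], mid + repeat_bp + 1,
                                  nchar(seqs[[last]])))
  }
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(chrom_lengths)
  list(genome = genome,
       layout = genome_layout(stats::setNames(Biostrings::width(genome),
                                              names(genome)),
                              ploidy_segments))
}

# occurrence starts (0-based) of one enzyme's site per chromosome
.site_index <- function(genome_chr, enz) {
  lapply(genome_chr, function(s) {
    h <- scan_sites(s, list(enz))
    h$start
  })
}

# --- piece samplers -------------------------------------------------------
# A "piece" is an oriented genomic segment used to assemble a ligation
# molecule.  In oriented sequence space, interior pieces start AND end with
# a full recognition site; the first piece ends with one; the last starts
# with one.  Consecutive pieces overlap by the shared site (w bp).

.piece <- function(chrom, gs, ge, strand) {
  list(chrom = chrom, gs = gs, ge = ge, strand = strand, M = ge - gs)
}

# occurrences with genomic clearance: no other occurrence start within
# `clear` bp on the required side
.sample_terminal_piece <- function(chrom, occ, len_chr, L, strand, w,
                                   role = c("first", "last")) {
  role <- match.arg(role)
  s <- occ[[chrom]]
  if (!length(s)) return(NULL)
  prev_gap <- c(Inf, diff(s))
  next_gap <- c(diff(s), Inf)
  # "site at segment end" = genomic segment [s+w-L, s+w), clearance on left
  # "site at segment start" = [s, s+L), clearance on right
  end_ok <- s + w - L >= 0 & prev_gap > L - w
  start_ok <- s + L <= len_chr[chrom] & next_gap > L - w
  want_end <- (role == "first") == (strand == "+")
  ok <- if (want_end) end_ok else start_ok
  if (!any(ok)) return(NULL)
  sh <- s[sample(which(ok), 1L)]
  if (want_end) .piece(chrom, sh + w - L, sh + w, strand)
  else .piece(chrom, sh, sh + L, strand)
}

.sample_interior_piece <- function(chrom, occ, Lmin, Lmax, strand, w) {
  s <- occ[[chrom]]
  if (length(s) < 2) return(NULL)
  len <- diff(s) + w
  ok <- which(len >= Lmin & len <= Lmax)
  if (!length(ok)) return(NULL)
  r <- ok[sample(length(ok), 1L)]
  .piece(chrom, s[r], s[r + 1] + w, strand)
}

.oriented_seq <- function(piece, genome_chr) {
  seg <- substr(genome_chr[[piece$chrom]], piece$gs + 1, piece$ge)
  if (piece$strand == "-") revcomp(seg) else seg
}

# 5' genomic coordinate of a read fragment covering molecule interval
# [a, b) inside a piece starting at molecule offset `off`
.map_interval <- function(piece, off, a, b, read_end) {
  if (read_end == 1L) {
    if (piece$strand == "+")
      list(chrom = piece$chrom, pos = piece$gs + (a - off), strand = "+")
    else
      list(chrom = piece$chrom, pos = piece$ge - 1 - (a - off), strand = "-")
  } else {
    if (piece$strand == "+")
      list(chrom = piece$chrom, pos = piece$gs + (b - 1 - off), strand = "-")
    else
      list(chrom = piece$chrom, pos = piece$ge - 1 - (b - 1 - off),
           strand = "+")
  }
}

# expected end status/loci from molecule geometry (independent of the
# sequence-level mapping pipeline)
.truth_end <- function(pieces, offs, Tlen, read_end, read_length, w,
                       min_frag) {
  ws <- if (read_end == 1L) 0 else Tlen - read_length
  we <- ws + read_length
  none <- list(status = "none",
               loci = data.frame(chrom = character(), pos = numeric(),
                                 strand = character(),
                                 fragment = character(),
                                 stringsAsFactors = FALSE))
  k <- length(pieces)
  within <- which(vapply(seq_len(k), function(t)
    ws >= offs[t] && we <= offs[t] + pieces[[t]]$M, logical(1)))
  if (length(within)) {
    mp <- .map_interval(pieces[[within[1]]], offs[within[1]], ws, we,
                        read_end)
    return(list(status = "F",
                loci = data.frame(chrom = mp$chrom, pos = mp$pos,
                                  strand = mp$strand, fragment = "whole",
                                  stringsAsFactors = FALSE)))
  }
  if (k < 2) return(none)
  jin <- which(vapply(2:k, function(j)
    offs[j] >= ws && offs[j] + w <= we, logical(1))) + 1L
  if (length(jin) != 1L) return(none)
  j <- jin
  if (read_end == 1L) {
    iv <- list(left = c(ws, offs[j] + w, j - 1L), right = c(offs[j], we, j))
  } else {
    iv <- list(left = c(offs[j], we, j), right = c(ws, offs[j] + w, j - 1L))
  }
  loci <- list()
  for (side in names(iv)) {
    a <- iv[[side]][1]; b <- iv[[side]][2]; t <- iv[[side]][3]
    if (b - a < min_frag) next
    if (a < offs[t] || b > offs[t] + pieces[[t]]$M) next   # geometry breach
    mp <- .map_interval(pieces[[t]], offs[t], a, b, read_end)
    loci[[side]] <- data.frame(chrom = mp$chrom, pos = mp$pos,
                               strand = mp$strand, fragment = side,
                               stringsAsFactors = FALSE)
  }
  if (!length(loci)) return(none)
  list(status = if (length(loci) == 2L) "P2" else "P1",
       loci = do.call(rbind, loci))
}

.serialize_loci <- function(loci) {
  if (!nrow(loci)) return("")
  paste(sprintf("%s:%d:%s:%s", loci$chrom, as.integer(loci$pos),
                loci$strand, loci$fragment), collapse = ";")
}

#' Parse the locus strings of a simulated truth table
#'
#' @param s Serialized locus string from [simulate_library] truth
#'   (`"chrom:pos:strand:fragment"` entries joined by `;`).
#' @return data.frame with `chrom`, `pos`, `strand`, `fragment`.
#' @export
parse_truth_loci <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(chrom = character(), pos = numeric(),
                      strand = character(), fragment = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p)
    data.frame(chrom = p[1], pos = as.numeric(p[2]), strand = p[3],
               fragment = p[4], stringsAsFactors = FALSE)))
}

#' Simulate a proximity-ligation paired-end library with ground truth
#'
#' Assembles molecules by concatenating restriction fragments at cleavage
#' sites of a randomly chosen enzyme from the configured set (ligation
#' classes), or by excising plain genomic spans (sonication), then reads
#' `read_length` bp from each molecule end (end 2 reverse-complemented).
#' Ligated fragments are oriented randomly; because the bundled recognition
#' sites are palindromic, every junction carries exactly one reconstituted
#' recognition site, exactly as religation chemistry produces.
#'
#' Fragment lengths are drawn so that junctions fall either inside a read
#' (producing partially mapped, "P", ends) or between the reads (fully
#' mapped, "F", ends), uniformly for 2-fragment molecules; 3- and
#' 4-fragment molecules place one junction inside each relevant read.  The
#' returned truth table records, per read pair, the molecule class and the
#' end statuses/loci expected from the molecule geometry alone, which is
#' what a correct mapping pipeline should recover on error-free reads.
#'
#' @param genome [Biostrings::DNAStringSet] (or the list from
#'   [simulate_genome]).
#' @param config [sim_config].
#' @param X Optional n x 3 bead coordinates: ligation partners are then
#'   sampled with probability proportional to `d^-3` between bin beads.
#' @param beadmap,bins Required with `X`: the bead map and bin table the
#'   coordinates refer to.
#' @return List: `reads1`, `reads2` ([Biostrings::DNAStringSet], names
#'   `read<i>`), `truth` (data.frame: `read_id`, `class`, `enzyme`,
#'   `status1`, `status2`, `loci1`, `loci2`).
#' @export
simulate_library <- function(genome, config = sim_config(), X = NULL,
                             beadmap = NULL, bins = NULL) {
  if (is.list(genome) && !is.null(genome$genome)) genome <- genome$genome
  chr_names <- names(genome)
  genome_chr <- stats::setNames(as.character(genome), chr_names)
  len_chr <- stats::setNames(nchar(genome_chr), chr_names)
  enzymes <- config$enzymes
  occ_by_enz <- lapply(enzymes, function(e) .site_index(genome_chr, e))
  names(occ_by_enz) <- vapply(enzymes, `[[`, "", "name")
  no_sites <- vapply(occ_by_enz, function(o) sum(lengths(o)) == 0,
                     logical(1))
  if (any(no_sites))
    stop("enzyme with no sites in genome: ",
         paste(names(occ_by_enz)[no_sites], collapse = ", "))
  RL <- config$read_length
  FS <- config$fragment_size
  .with_seed(config$seed, {
    classes <- sample(names(config$class_fractions), config$n_reads,
                      replace = TRUE, prob = config$class_fractions)
    pick_chrom <- function(prev_chrom, prev_pos) {
      if (!is.null(X) && !is.null(bins) && !is.null(prev_chrom)) {
        b0 <- assign_bins(prev_chrom, prev_pos, bins)
        bead0 <- which(beadmap$phi == b0 & beadmap$copy == "A")
        d <- sqrt(rowSums((X - matrix(X[bead0, ], nrow(X), 3,
                                      byrow = TRUE))^2))
        wgt <- ifelse(d > 0, d^-3, 0)
        wgt <- wgt[beadmap$copy[seq_len(nrow(X))] == "A"]
        b <- sample(beadmap$m, 1L, prob = wgt)
        return(list(chrom = bins$chrom[b], pos = bins$start[b]))
      }
      if (!is.null(prev_chrom) &&
          stats::runif(1) < config$intra_fraction)
        list(chrom = prev_chrom, pos = NULL)
      else list(chrom = sample(chr_names, 1L), pos = NULL)
    }
    rand_strand <- function()
      if (stats::runif(1) < config$flip_prob) "-" else "+"
    reads1 <- reads2 <- character(config$n_reads)
    truth <- vector("list", config$n_reads)
    for (i in seq_len(config$n_reads)) {
      cls <- classes[i]
      if (cls == "sonication") {
        cn <- sample(chr_names, 1L)
        gs <- sample.int(len_chr[cn] - FS, 1L) - 1L
        pieces <- list(.piece(cn, gs, gs + FS, rand_strand()))
        w <- 0L
      } else {
        k <- switch(cls, two = 2L, three = 3L, four = 4L)
        ei <- sample(length(enzymes), 1L)
        enz <- enzymes[[ei]]
        occ <- occ_by_enz[[ei]]
        w <- nchar(enz$site)
        pieces <- NULL
        for (try in 1:50) {          # resample until geometry fits
          pcs <- vector("list", k)
          c1 <- sample(chr_names, 1L)
          L1 <- if (k == 2L) sample(20:230, 1L)
                else if (k == 4L) sample(20:60, 1L) else sample(20:80, 1L)
          pcs[[1]] <- .sample_terminal_piece(c1, occ, len_chr, L1,
                                             rand_strand(), w, "first")
          if (is.null(pcs[[1]])) next
          prev <- pcs[[1]]
          fit <- TRUE
          for (t in seq_len(k)[-1]) {
            nx <- pick_chrom(prev$chrom, prev$gs)
            if (t < k) {
              pcs[[t]] <- .sample_interior_piece(nx$chrom, occ, RL, 2 * RL,
                                                 rand_strand(), w)
            } else {
              Lk <- if (k == 2L) FS - L1 + w
                    else if (k == 3L) sample(100:150, 1L)
                    else sample(20:80, 1L)
              pcs[[t]] <- .sample_terminal_piece(nx$chrom, occ, len_chr, Lk,
                                                 rand_strand(), w, "last")
            }
            if (is.null(pcs[[t]])) { fit <- FALSE; break }
            prev <- pcs[[t]]
          }
          if (fit) { pieces <- pcs; break }
        }
        if (is.null(pieces)) stop("could not assemble a ", cls,
                                  "-fragment molecule; genome too small?")
      }
      Ms <- vapply(pieces, `[[`, numeric(1), "M")
      offs <- cumsum(c(0, utils::head(Ms, -1) - w))
      Tlen <- sum(Ms) - (length(pieces) - 1L) * w
      seqs <- vapply(pieces, .oriented_seq, "", genome_chr = genome_chr)
      mol <- paste0(seqs[1],
                    paste(vapply(seqs[-1], substring, "", w + 1),
                          collapse = ""))
      r1 <- substr(mol, 1, RL)
      r2 <- revcomp(substr(mol, Tlen - RL + 1, Tlen))
      if (config$error_rate > 0) {
        r1 <- .mutate(r1, config$error_rate)
        r2 <- .mutate(r2, config$error_rate)
      }
      reads1[i] <- r1; reads2[i] <- r2
      t1 <- .truth_end(pieces, offs, Tlen, 1L, RL, w, config$min_frag)
      t2 <- .truth_end(pieces, offs, Tlen, 2L, RL, w, config$min_frag)
      truth[[i]] <- data.frame(
        read_id = sprintf("read%05d", i), class = cls,
        enzyme = if (cls == "sonication") NA_character_
                 else enzymes[[ei]]$name,
        status1 = t1$status, status2 = t2$status,
        loci1 = .serialize_loci(t1$loci), loci2 = .serialize_loci(t2$loci),
        stringsAsFactors = FALSE)
    }
    reads1 <- Biostrings::DNAStringSet(reads1)
    reads2 <- Biostrings::DNAStringSet(reads2)
    names(reads1) <- names(reads2) <- sprintf("read%05d",
                                              seq_len(config$n_reads))
    list(reads1 = reads1, reads2 = reads2, truth = do.call(rbind, truth))
  })
}

.mutate <- function(seq, rate) {
  n <- nchar(seq)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(seq)
  ch <- strsplit(seq, "")[[1]]
  ch[hit] <- vapply(ch[hit], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(ch, collapse = "")
}

#' Draw a contact matrix from a 3D structure
#'
#' Generates locus-level counts under the inference model run forward: for
#' every locus pair, each eligible homolog bead pair (as in
#' [contact_groups]) contributes an independent Poisson count with mean
#' `scale * d^alpha`, and the bead-pair counts are summed per locus pair.
#'
#' @param X n x 3 bead coordinates.
#' @param beadmap [build_bead_map].
#' @param bins Bin table for the result.
#' @param alpha Decay exponent (default -3).
#' @param scale Multiplicative intensity (default 1; the inference model
#'   assumes 1).
#' @param seed Random seed.
#' @return A `contact_matrix`.
#' @export
simulate_counts_from_structure <- function(X, beadmap, bins, alpha = -3,
                                           scale = 1, seed = 1L) {
  m <- beadmap$m
  bol <- beads_of_locus(beadmap)
  .with_seed(seed, {
    ii <- jj <- xx <- list()
    for (k in seq_len(m - 1)) for (l in (k + 1):m) {
      bk <- bol[[k]]; bl <- bol[[l]]
      pairs <- expand.grid(i = bk, j = bl)
      if (length(bk) == 2L && length(bl) == 2L)
        pairs <- pairs[beadmap$copy[pairs$i] == beadmap$copy[pairs$j], ,
                       drop = FALSE]
      d <- sqrt(rowSums((X[pairs$i, , drop = FALSE] -
                           X[pairs$j, , drop = FALSE])^2))
      cnt <- sum(stats::rpois(length(d), scale * d^alpha))
      if (cnt > 0) {
        ii[[length(ii) + 1L]] <- k
        jj[[length(jj) + 1L]] <- l
        xx[[length(xx) + 1L]] <- cnt
      }
    }
    counts <- Matrix::sparseMatrix(
      i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
      x = as.numeric(unlist(xx)), dims = c(m, m), symmetric = TRUE)
    structure(list(counts = counts, bins = bins), class = "contact_matrix")
  })
}

#' Write reads as FASTQ
#'
#' Constant quality "I" per base (error-free simulation).
#'
#' @param reads [Biostrings::DNAStringSet].
#' @param path Output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  q <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(wd)
    paste(rep("I", wd), collapse = ""), ""))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q)
  invisible(path)
}
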