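#' Read a pipeline layout/config file
#'
#' YAML with keys: `chromosomes` (name: length), optional `ploidy_segments`
#' (list of chrom/start/end/copy_number), optional `enzymes` (preset name or
#' list).
#'
#' @param path YAML file.
#' @return [genome_layout]; attribute `enzymes` carries the enzyme set name
#'   if present.
#' @export
read_layout_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chromosomes)) stop("config missing field: chromosomes")
  seg <- NULL
  if (!is.null(cfg$ploidy_segments))
    seg <- do.call(rbind, lapply(cfg$ploidy_segments, as.data.frame))
  layout <- genome_layout(unlist(cfg$chromosomes), seg)
  attr(layout, "enzymes") <- cfg$enzymes
  layout
}

.manifest <- function(out_dir, stage, params, contacts = NULL) {
  man <- list(stage = stage, params = params,
              time = format(Sys.time(), tz = "UTC"))
  if (!is.null(contacts)) {
    cs <- contact_summary(contacts)
    man$contact_counts <- stats::setNames(
      as.list(cs$count), paste0(c("doubles", "triples", "quadruples")[
        cs$arity - 1], "_", cs$span))
  }
  jsonlite::write_json(man, file.path(out_dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package's functions, with versioned text
#' outputs and a machine-readable manifest per stage (parameters, seed, and
#' contact counts per arity and chromosomal span, so filter attrition is
#' auditable).  Stages:
#'
#' * `simulate`: write a simulated genome (FASTA), library (paired FASTQ)
#'   and truth table.  Params: `chrom_lengths`, `n_reads`, `seed`, ...
#'   (passed to [sim_config]).
#' * `call-contacts`: two-phase mapping with the built-in exact aligner.
#'   Params: `fastq1`, `fastq2`, `genome`, `enzymes`, `min_dist`.
#' * `bin`: bin doubles.  Params: `contacts`, `chrom_sizes`, `resolution`.
#' * `normalize`: copy-number-aware ICE.  Params: `matrix`, `bins_bed`
#'   (from `bin`), `layout` (YAML), `fraction`.
#' * `compartments`: per-chromosome eigendecomposition, GC-oriented when a
#'   genome FASTA is supplied.  Params: `matrix`, `bins_bed`, `genome`.
#' * `model3d`: 3D inference.  Params: `matrix`, `bins_bed`, `layout`,
#'   `restarts`, `seed`.
#'
#' @param stage Stage name (above).
#' @param params Named list of stage parameters.
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_stage <- function(stage, params = list(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  get_par <- function(name, default = NULL) {
    if (!is.null(params[[name]])) return(params[[name]])
    if (is.null(default)) stop("missing required config field: ", name)
    default
  }
  switch(stage,
    "simulate" = {
      lens <- unlist(get_par("chrom_lengths",
                             c(chrS1 = 1e5, chrS2 = 1e5)))
      seed <- get_par("seed", 1L)
      g <- simulate_genome(lens, seed = seed)
      cfg <- sim_config(n_reads = get_par("n_reads", 200L),
                        enzymes = get_par("enzymes", "single"),
                        seed = seed)
      lib <- simulate_library(g, cfg)
      Biostrings::writeXStringSet(g$genome, file.path(out_dir, "genome.fa"))
      write_fastq(lib$reads1, file.path(out_dir, "reads_1.fastq"))
      write_fastq(lib$reads2, file.path(out_dir, "reads_2.fastq"))
      utils::write.table(lib$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      .manifest(out_dir, stage, list(seed = seed, n_reads = cfg$n_reads,
                                     chromosomes = as.list(lens)))
    },
    "call-contacts" = {
      contacts <- call_contacts(get_par("fastq1"), get_par("fastq2"),
                                get_par("genome"),
                                enzyme_set(get_par("enzymes", "single")),
                                min_dist = get_par("min_dist", 1000))
      write_contacts(contacts, file.path(out_dir, "contacts.tsv"))
      write_pairs(contacts, file.path(out_dir, "pairs.tsv"))
      .manifest(out_dir, stage,
                list(min_dist = get_par("min_dist", 1000)), contacts)
    },
    "bin" = {
      layout <- genome_layout(read_chrom_sizes(get_par("chrom_sizes")))
      bins <- make_bins(layout, get_par("resolution", 1e6))
      contacts <- read_contacts(get_par("contacts"))
      cm <- bin_contacts(contacts, bins)
      write_matrix_triplets(cm, file.path(out_dir, "matrix.tsv"))
      bins_to_bed(bins, file.path(out_dir, "bins.bed"))
      .manifest(out_dir, stage,
                list(resolution = get_par("resolution", 1e6),
                     bins = nrow(bins), mass = contact_mass(cm)), contacts)
    },
    "normalize" = {
      layout <- read_layout_config(get_par("layout"))
      bins <- make_bins(layout, get_par("resolution", 1e6))
      cm <- read_matrix_triplets(get_par("matrix"), bins)
      bm <- build_bead_map(bins, layout)
      res <- normalize_contacts(cm, bm,
                                fraction = get_par("fraction", 0.10))
      write_matrix_triplets(res$normalized,
                            file.path(out_dir, "normalized.tsv"))
      utils::write.table(
        data.frame(bead = seq_along(res$bias), bias = res$bias),
        file.path(out_dir, "bias.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      bins_to_bed(bins[res$retained, ], file.path(out_dir, "retained.bed"))
      .manifest(out_dir, stage,
                list(fraction = get_par("fraction", 0.10),
                     converged = res$converged,
                     retained = sum(res$retained)))
    },
    "compartments" = {
      layout <- read_layout_config(get_par("layout"))
      bins <- make_bins(layout, get_par("resolution", 1e6))
      if (!is.null(params$genome))
        bins <- annotate_gc(bins,
                            Biostrings::readDNAStringSet(params$genome))
      cm <- read_matrix_triplets(get_par("matrix"), bins)
      track <- call_compartments(cm)
      track_to_bed(track, file.path(out_dir, "compartments.bed"))
      .manifest(out_dir, stage,
                list(resolution = get_par("resolution", 1e6),
                     labelled = sum(!is.na(track$label))))
    },
    "model3d" = {
      layout <- read_layout_config(get_par("layout"))
      bins <- make_bins(layout, get_par("resolution", 1e6))
      cm <- read_matrix_triplets(get_par("matrix"), bins)
      bm <- build_bead_map(bins, layout)
      cfg <- model_config(restarts = get_par("restarts", 10L),
                          seed = get_par("seed", 1L))
      ens <- infer_structure(cm, bm, bins, cfg)
      write_structure(ens[[1]], bm, bins,
                      file.path(out_dir, "structure.tsv"),
                      pdb = file.path(out_dir, "structure.pdb"))
      .manifest(out_dir, stage,
                list(restarts = cfg$restarts, seed = cfg$seed,
                     loglik = ens[[1]]$loglik, dmax = attr(ens, "dmax")))
    },
    stop("unknown stage: ", stage)
  )
}
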