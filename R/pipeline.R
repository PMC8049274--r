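# Pipeline orchestration: configuration, the in-memory end-to-end run, and
# the run-directory entry point used by the command-line wrapper.

#' Binning pipeline configuration
#'
#' All thresholds of the pipeline with their standard defaults: 400 bp
#' minimum contig length, ambiguity runs of 50 bp split, seed hits must
#' cover 2/3 of the seed on contigs with at least 4-fold coverage, seed
#' similarity uses 8-mers, discriminating k-mers are 12 residues with a
#' 10-hit minimum, rescue matches are 50 bp, and the high-quality cutoffs
#' are contamination <= 10, fine consistency >= 87, completeness >= 80.
#'
#' @param min_contig_len Minimum contig length in bp.
#' @param max_ambig_run Ambiguity-run split length in bp.
#' @param min_seed_cov Minimum seed coverage fraction of a seed hit.
#' @param min_contig_cov Minimum fold coverage of a seed-bearing contig.
#' @param seed_sim_k Seed-similarity k-mer length (residues).
#' @param disc_k Discriminating k-mer length (residues).
#' @param min_disc_hits Minimum discriminating k-mers for assignment.
#' @param rescue_k Rescue match length (bp).
#' @param contamination_max,fine_min,completeness_min High-quality cutoffs.
#' @param min_role_kmer_frac Minimum k-mer fraction for a role occurrence.
#' @param seed_policy A [seed_length_policy()].
#' @param default_coverage Coverage for contigs without a header token.
#' @param annotator,predictor Plugin names (`"kmer"` role projection and the
#'   `"baseline"` single-copy predictor are built in).
#' @param seed RNG seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return A `binning_config` list.
#' @export
binning_config <- function(min_contig_len = 400, max_ambig_run = 50,
                           min_seed_cov = 2 / 3, min_contig_cov = 4.0,
                           seed_sim_k = 8, disc_k = 12, min_disc_hits = 10,
                           rescue_k = 50, contamination_max = 10,
                           fine_min = 87, completeness_min = 80,
                           min_role_kmer_frac = 0.5,
                           seed_policy = seed_length_policy(),
                           default_coverage = 50,
                           annotator = "kmer", predictor = "baseline",
                           seed = 1) {
  cfg <- list(
    min_contig_len = min_contig_len, max_ambig_run = max_ambig_run,
    min_seed_cov = min_seed_cov, min_contig_cov = min_contig_cov,
    seed_sim_k = seed_sim_k, disc_k = disc_k, min_disc_hits = min_disc_hits,
    rescue_k = rescue_k, contamination_max = contamination_max,
    fine_min = fine_min, completeness_min = completeness_min,
    min_role_kmer_frac = min_role_kmer_frac, seed_policy = seed_policy,
    default_coverage = default_coverage,
    annotator = annotator, predictor = predictor, seed = seed
  )
  num <- cfg[c(
    "min_contig_len", "max_ambig_run", "min_seed_cov", "min_contig_cov",
    "seed_sim_k", "disc_k", "min_disc_hits", "rescue_k",
    "contamination_max", "fine_min", "completeness_min", "min_role_kmer_frac"
  )]
  if (any(unlist(num) <= 0)) abort("all pipeline thresholds must be positive")
  cfg$annotator_fn <- switch(annotator,
    kmer = annotate_bin,
    abort(paste0("unknown annotator plugin: ", annotator))
  )
  cfg$predictor_fn <- switch(predictor,
    baseline = baseline_predictor,
    abort(paste0("unknown predictor plugin: ", predictor))
  )
  structure(cfg, class = "binning_config")
}

stage_log <- function(log, stage, detail) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", stage, ": ", detail)
  inform(line)
  c(log, line)
}

#' Run the supervised binning pipeline in memory
#'
#' Executes quality control, seed-hit search, bin initialization, reference
#' assignment, same-species merging, discriminating-index construction,
#' contig assignment, rescue, annotation, quality evaluation and
#' contamination-triggered pruning, and returns everything as one
#' `binning_result`.
#'
#' @param contigs Contig tibble (from [read_contigs()]) or path to a FASTA
#'   file.
#' @param ref_db A `ref_db` or path to a reference-database directory.
#' @param config A [binning_config()].
#' @return A `binning_result`: list with `contigs` (QC-passing), `bins`,
#'   `assignments`, `metrics`, `occurrences`, `problematic`, `ref_db`,
#'   `config`, stage `log` and input counts.
#' @export
bin_metagenome <- function(contigs, ref_db, config = binning_config()) {
  if (is.character(ref_db)) ref_db <- load_reference_db_dir(ref_db)
  input_file <- NULL
  if (is.character(contigs)) {
    input_file <- contigs
    contigs <- read_contigs(contigs, default_coverage = config$default_coverage)
  }
  log <- character(0)
  n_in <- nrow(contigs)
  log <- stage_log(log, "input", paste0(n_in, " contigs"))
  clean <- clean_contigs(contigs,
    min_len = config$min_contig_len, max_ambig_run = config$max_ambig_run
  )
  log <- stage_log(log, "qc", paste0(nrow(clean), " contigs pass quality control"))

  hits <- find_seed_hits(clean, ref_db,
    min_seed_cov = config$min_seed_cov,
    min_contig_cov = config$min_contig_cov, min_len = config$min_contig_len
  )
  log <- stage_log(log, "seed-hits", paste0(nrow(hits), " retained seed hits"))
  bins <- init_bins(hits)
  log <- stage_log(log, "init-bins", paste0(nrow(bins), " provisional bins"))
  bins <- assign_reference(bins, ref_db, k = config$seed_sim_k)
  bins <- merge_bins(bins)
  log <- stage_log(log, "merge", paste0(nrow(bins), " bins after same-species merge"))

  if (nrow(bins) > 0L) {
    index <- build_discriminating_index(bins, ref_db, k = config$disc_k)
    log <- stage_log(
      log, "disc-index",
      paste0(nrow(index$map), " discriminating ", config$disc_k, "-mers")
    )
    assignments <- assign_contigs(clean, index, bins,
      min_hits = config$min_disc_hits
    )
    log <- stage_log(
      log, "kmer-assign",
      paste0(sum(!is.na(assignments$bin_id)), " contigs binned")
    )
    rescue_index <- build_rescue_index(clean, assignments, k = config$rescue_k)
    before <- sum(!is.na(assignments$bin_id))
    assignments <- rescue_contigs(clean, assignments, rescue_index)
    log <- stage_log(
      log, "rescue",
      paste0(sum(!is.na(assignments$bin_id)) - before, " contigs rescued")
    )
  } else {
    assignments <- unbinned_assignment(clean$contig_id, "no-hits")
    if (nrow(clean) == 0L) {
      assignments <- unbinned_assignment(character(0), character(0))
    }
  }

  ev <- evaluate_bins(bins, assignments, clean, ref_db, config)
  assignments <- ev$assignments
  n_good <- sum(ev$metrics$verdict == "good")
  log <- stage_log(
    log, "evaluate",
    paste0(nrow(ev$metrics), " bins evaluated, ", n_good, " high-quality")
  )

  structure(
    list(
      contigs = clean, bins = bins, assignments = assignments,
      metrics = ev$metrics, occurrences = ev$occurrences,
      problematic = ev$problematic, ref_db = ref_db, config = config,
      log = log, input_file = input_file,
      n_contigs_in = n_in, n_contigs_qc = nrow(clean)
    ),
    class = "binning_result"
  )
}

#' @export
print.binning_result <- function(x, ...) {
  cat(
    "<binning_result> ", x$n_contigs_qc, " QC-passing contigs, ",
    nrow(x$metrics), " bins (", sum(x$metrics$verdict == "good"),
    " high-quality), ", sum(!is.na(x$assignments$bin_id)),
    " contigs binned\n",
    sep = ""
  )
  invisible(x)
}

config_json <- function(config) {
  cfg <- unclass(config)
  cfg$annotator_fn <- NULL
  cfg$predictor_fn <- NULL
  cfg$seed_policy <- list(
    Bacteria = cfg$seed_policy$Bacteria, Archaea = cfg$seed_policy$Archaea
  )
  cfg
}

#' Run the binning pipeline and write a run directory
#'
#' Wraps [bin_metagenome()]: runs the full pipeline and writes the binning
#' report (HTML + JSON), per-bin and unbinned FASTA files, the assignment
#' table, the fully resolved configuration (`config.json`) and a `run.log`
#' with per-stage counts.
#'
#' @param contigs_path Contigs FASTA path (or contig tibble).
#' @param ref_db Reference-database directory (or `ref_db` object).
#' @param out_dir Run directory to create.
#' @param config A [binning_config()].
#' @return The `binning_result`, invisibly.
#' @export
run_pipeline <- function(contigs_path, ref_db, out_dir,
                         config = binning_config()) {
  if (is.character(contigs_path) && !file.exists(contigs_path)) {
    abort(paste0("contigs file not readable: ", contigs_path), class = "seedbin_input_error")
  }
  if (is.character(ref_db) && !dir.exists(ref_db)) {
    abort(paste0("reference database directory not readable: ", ref_db),
      class = "seedbin_input_error"
    )
  }
  result <- bin_metagenome(contigs_path, ref_db, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  render_report(result, out_dir)
  jsonlite::write_json(config_json(config), file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(result)
}
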