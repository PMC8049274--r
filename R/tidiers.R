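# broom-style accessors and plots for binning results.

#' Tidy a binning result into per-bin quality metrics
#'
#' @param x A `binning_result`.
#' @param ... Unused.
#' @return A tibble with one row per bin: quality metrics, contig
#'   statistics, verdict and failing metrics (comma-separated).
#' @method tidy binning_result
#' @export
tidy.binning_result <- function(x, ...) {
  m <- x$metrics
  if (nrow(m) == 0L) {
    return(tibble(
      bin_id = character(0), species_id = character(0),
      reference = character(0), seed_similarity = numeric(0),
      completeness = numeric(0), contamination = numeric(0),
      fine_consistency = numeric(0), coarse_consistency = numeric(0),
      seed_count = integer(0), seed_length_ok = logical(0),
      contig_count = integer(0), dna_size = numeric(0), n50 = numeric(0),
      mean_coverage = numeric(0), score = numeric(0),
      verdict = character(0), failing = character(0)
    ))
  }
  tibble(
    bin_id = m$bin_id,
    species_id = m$species_id,
    reference = map_chr(m$reference_genome_ids, paste, collapse = ","),
    seed_similarity = m$ref_similarity,
    completeness = m$completeness,
    contamination = m$contamination,
    fine_consistency = m$fine_consistency,
    coarse_consistency = m$coarse_consistency,
    seed_count = m$seed_count,
    seed_length_ok = m$seed_length_ok,
    contig_count = m$contig_count,
    dna_size = m$dna_size,
    n50 = m$n50,
    mean_coverage = m$mean_coverage,
    score = m$score,
    verdict = m$verdict,
    failing = map_chr(m$failing, paste, collapse = ",")
  )
}

#' One-row summary of a binning run
#'
#' @param x A `binning_result`.
#' @param ... Unused.
#' @return A one-row tibble: contig counts at each stage, bin counts and
#'   the fraction of QC-passing contigs binned.
#' @method glance binning_result
#' @export
glance.binning_result <- function(x, ...) {
  a <- x$assignments
  tibble(
    n_contigs_in = x$n_contigs_in,
    n_contigs_qc = x$n_contigs_qc,
    n_bins = nrow(x$metrics),
    n_good_bins = sum(x$metrics$verdict == "good"),
    n_binned = sum(!is.na(a$bin_id)),
    n_seed = sum(a$stage == "seed", na.rm = TRUE),
    n_kmer = sum(a$stage == "kmer", na.rm = TRUE),
    n_rescued = sum(a$stage == "rescue", na.rm = TRUE),
    frac_binned = if (nrow(a)) sum(!is.na(a$bin_id)) / nrow(a) else 0
  )
}

#' Plot bin quality: completeness vs contamination
#'
#' Scatter of the per-bin quality metrics with the high-quality cutoffs
#' drawn as dashed lines; high-quality bins are coloured.
#'
#' @param object A `binning_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binning_result
#' @export
autoplot.binning_result <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(
    x = .data$completeness, y = .data$contamination,
    colour = .data$verdict, size = .data$dna_size
  )) +
    geom_point(alpha = 0.8) +
    geom_vline(xintercept = object$config$completeness_min, linetype = "dashed") +
    geom_hline(yintercept = object$config$contamination_max, linetype = "dashed") +
    scale_colour_manual(values = c(good = "#2e7d32", poor = "#c62828")) +
    labs(
      x = "Completeness (%)", y = "Contamination (%)",
      colour = "Verdict", size = "DNA size (bp)",
      title = "Bin quality",
      subtitle = "Dashed lines: high-quality cutoffs"
    ) +
    theme_minimal()
}

#' Plot binned fraction per assignment stage
#'
#' @param result A `binning_result`.
#' @return A ggplot object.
#' @export
plot_assignment_stages <- function(result) {
  a <- result$assignments |>
    mutate(stage = if_else(is.na(.data$bin_id), "unbinned", .data$stage)) |>
    count(.data$stage)
  ggplot(a, aes(x = .data$stage, y = .data$n, fill = .data$stage)) +
    ggplot2::geom_col(show.legend = FALSE) +
    labs(x = "Assignment stage", y = "Contigs", title = "Contig assignment by stage") +
    theme_minimal()
}
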