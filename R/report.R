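# Binning report: structured HTML, machine-readable JSON with identical
# numbers, per-bin FASTA files, per-bin problematic-role pages and an
# unbinned FASTA. Failing metrics are flagged in both HTML and JSON.

fmt4 <- function(x) formatC(round(x, 4), format = "fg", digits = 15)

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

metric_cell <- function(value, name, failing) {
  cls <- if (name %in% failing) " class=\"fail\"" else ""
  paste0("<td", cls, ">", value, "</td>")
}

bin_table_html <- function(metrics, ref_names) {
  if (nrow(metrics) == 0L) {
    return("<p>No bins in this section.</p>")
  }
  header <- paste0(
    "<tr><th>Score</th><th>Bin</th><th>Organism</th><th>Reference</th>",
    "<th>Coarse consistency</th><th>Fine consistency</th>",
    "<th>Completeness</th><th>Contamination</th><th>Good seed</th>",
    "<th>Contigs</th><th>DNA size (bp)</th><th>N50</th>",
    "<th>Mean coverage</th><th>Roles report</th></tr>"
  )
  rows <- map_chr(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    failing <- m$failing[[1]]
    refs <- paste(m$reference_genome_ids[[1]], collapse = ", ")
    organism <- paste0(ref_names[m$reference_genome_ids[[1]][1]], " clonal population")
    seed_ok <- m$seed_count == 1L && m$seed_length_ok
    paste0(
      "<tr>",
      "<td>", fmt4(m$score), "</td>",
      "<td>", html_escape(m$bin_id), "</td>",
      "<td>", html_escape(organism), "</td>",
      "<td>", html_escape(refs), "</td>",
      "<td>", fmt4(m$coarse_consistency), "</td>",
      metric_cell(fmt4(m$fine_consistency), "fine_consistency", failing),
      metric_cell(fmt4(m$completeness), "completeness", failing),
      metric_cell(fmt4(m$contamination), "contamination", failing),
      metric_cell(if (seed_ok) "yes" else "no", "seed", failing),
      "<td>", m$contig_count, "</td>",
      "<td>", m$dna_size, "</td>",
      "<td>", m$n50, "</td>",
      "<td>", fmt4(m$mean_coverage), "</td>",
      "<td><a href=\"bins/", m$bin_id, ".roles.html\">roles</a></td>",
      "</tr>"
    )
  })
  paste0("<table>", header, paste0(rows, collapse = ""), "</table>")
}

report_css <- paste0(
  "<style>body{font-family:sans-serif;margin:2em}",
  "table{border-collapse:collapse}",
  "td,th{border:1px solid #999;padding:4px 8px}",
  "td.fail{background:#ffeb3b}</style>"
)

roles_report_html <- function(bin_id, prob) {
  rows <- if (nrow(prob) == 0L) {
    "<p>No problematic roles: every predictable role matches its expected count.</p>"
  } else {
    paste0(
      "<table><tr><th>Role</th><th>Observed</th><th>Expected</th>",
      "<th>Universal</th><th>In reference</th></tr>",
      paste0(map_chr(seq_len(nrow(prob)), function(i) {
        paste0(
          "<tr><td>", html_escape(prob$role_id[i]), "</td><td>",
          prob$observed[i], "</td><td>", prob$expected[i], "</td><td>",
          ifelse(prob$universal[i], "yes", "no"), "</td><td>",
          ifelse(prob$in_reference[i], "yes", "no"), "</td></tr>"
        )
      }), collapse = ""),
      "</table>"
    )
  }
  paste0(
    "<!DOCTYPE html><html><head><title>Problematic roles: ", bin_id,
    "</title>", report_css, "</head><body><h1>Problematic roles for ",
    html_escape(bin_id), "</h1>", rows, "</body></html>"
  )
}

report_json_payload <- function(result) {
  metrics <- result$metrics
  ref_names <- stats::setNames(result$ref_db$genomes$name, result$ref_db$genomes$genome_id)
  bins <- map(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    list(
      bin_id = m$bin_id,
      organism = paste0(ref_names[m$reference_genome_ids[[1]][1]], " clonal population"),
      reference_genome_ids = as.list(m$reference_genome_ids[[1]]),
      species_id = m$species_id,
      domain = m$domain,
      seed_similarity = round(m$ref_similarity, 4),
      score = round(m$score, 4),
      coarse_consistency = round(m$coarse_consistency, 4),
      fine_consistency = round(m$fine_consistency, 4),
      completeness = round(m$completeness, 4),
      contamination = round(m$contamination, 4),
      seed_count = m$seed_count,
      seed_length_ok = m$seed_length_ok,
      contig_count = m$contig_count,
      dna_size = m$dna_size,
      n50 = m$n50,
      mean_coverage = round(m$mean_coverage, 4),
      verdict = m$verdict,
      failing = as.list(m$failing[[1]])
    )
  })
  n_good <- sum(metrics$verdict == "good")
  list(
    input = list(
      contigs_file = result$input_file %||% NA,
      contigs_in = result$n_contigs_in,
      contigs_after_qc = result$n_contigs_qc
    ),
    totals = list(
      bins = nrow(metrics), good = n_good, poor = nrow(metrics) - n_good,
      binned_contigs = sum(!is.na(result$assignments$bin_id)),
      unbinned_contigs = sum(is.na(result$assignments$bin_id))
    ),
    bins = bins
  )
}

#' Render the binning report
#'
#' Writes `BinningReport.html` (high-quality bins and other bins in separate
#' sections, failing metric cells highlighted), `report.json` with the same
#' numbers (rounded to 4 decimals in both formats), one problematic-role
#' HTML per bin, per-bin FASTA files and `unbinned.fasta`, plus
#' `assignments.tsv`. A run with zero bins still produces a report saying
#' so.
#'
#' @param result A `binning_result` from [bin_metagenome()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(result, out_dir) {
  dir.create(file.path(out_dir, "bins"), showWarnings = FALSE, recursive = TRUE)
  metrics <- result$metrics
  ref_names <- stats::setNames(result$ref_db$genomes$name, result$ref_db$genomes$genome_id)
  good <- metrics |> filter(.data$verdict == "good")
  poor <- metrics |> filter(.data$verdict == "poor")
  html <- paste0(
    "<!DOCTYPE html><html><head><title>Binning report</title>", report_css,
    "</head><body><h1>Metagenome binning report</h1>",
    "<p>Input: ", html_escape(result$input_file %||% "(in-memory contigs)"),
    " &mdash; ", result$n_contigs_in, " contigs submitted, ",
    result$n_contigs_qc, " after quality control.</p>",
    "<p>Total bins: ", nrow(metrics), " (", nrow(good), " high-quality, ",
    nrow(poor), " other).</p>",
    "<h2>High-quality bins</h2>", bin_table_html(good, ref_names),
    "<h2>Other bins</h2>", bin_table_html(poor, ref_names),
    "</body></html>"
  )
  writeLines(html, file.path(out_dir, "BinningReport.html"))
  jsonlite::write_json(
    report_json_payload(result), file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  for (bid in metrics$bin_id) {
    prob <- result$problematic[[bid]] %||%
      tibble(
        role_id = character(0), observed = integer(0), expected = integer(0),
        universal = logical(0), in_reference = logical(0)
      )
    writeLines(
      roles_report_html(bid, prob),
      file.path(out_dir, "bins", paste0(bid, ".roles.html"))
    )
  }
  write_bin_fastas(result, out_dir)
  a <- result$assignments
  a_out <- tibble(
    contig_id = a$contig_id,
    bin_id = if_else(is.na(a$bin_id), "UNBINNED", a$bin_id),
    stage = a$stage, best_count = a$best_count,
    runner_up_count = a$runner_up_count,
    reason = if_else(is.na(a$reason), "", a$reason)
  )
  utils::write.table(a_out, file.path(out_dir, "assignments.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(out_dir)
}

#' Write per-bin FASTA files and the unbinned FASTA
#'
#' One FASTA per bin (headers carry the contig id and its bin id) plus
#' `unbinned.fasta`. The union of all outputs equals the QC-passing contig
#' set exactly; a contig assigned to two bins is an invariant breach and a
#' hard error.
#'
#' @param result A `binning_result`.
#' @param out_dir Output directory (FASTAs go to `out_dir/bins/` and
#'   `out_dir/unbinned.fasta`).
#' @return `out_dir`, invisibly.
#' @export
write_bin_fastas <- function(result, out_dir) {
  dir.create(file.path(out_dir, "bins"), showWarnings = FALSE, recursive = TRUE)
  a <- result$assignments
  if (anyDuplicated(a$contig_id)) {
    abort("invariant breach: a contig appears in more than one assignment row")
  }
  contigs <- result$contigs
  for (bid in result$metrics$bin_id) {
    member <- a$contig_id[!is.na(a$bin_id) & a$bin_id == bid]
    ct <- contigs[match(member, contigs$contig_id), ]
    write_contigs(ct, file.path(out_dir, "bins", paste0(bid, ".fasta")),
      headers = paste(ct$contig_id, paste0("bin_id=", bid))
    )
  }
  unb <- a$contig_id[is.na(a$bin_id)]
  ct <- contigs[match(unb, contigs$contig_id), ]
  write_contigs(ct, file.path(out_dir, "unbinned.fasta"))
  invisible(out_dir)
}

#' Structurally validate a binning report JSON
#'
#' Checks a parsed `report.json` against the shipped schema
#' (`inst/schema/report.schema.json`): required top-level and per-bin keys
#' and their primitive types.
#'
#' @param report Parsed JSON (e.g. `jsonlite::read_json(path)`).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report_json <- function(report) {
  need_top <- c("input", "totals", "bins")
  miss <- setdiff(need_top, names(report))
  if (length(miss)) abort(paste0("report missing keys: ", paste(miss, collapse = ", ")))
  need_tot <- c("bins", "good", "poor", "binned_contigs", "unbinned_contigs")
  miss <- setdiff(need_tot, names(report$totals))
  if (length(miss)) abort(paste0("report totals missing: ", paste(miss, collapse = ", ")))
  need_bin <- c(
    "bin_id", "organism", "reference_genome_ids", "score",
    "coarse_consistency", "fine_consistency", "completeness",
    "contamination", "seed_count", "seed_length_ok", "contig_count",
    "dna_size", "n50", "mean_coverage", "verdict", "failing"
  )
  for (b in report$bins) {
    miss <- setdiff(need_bin, names(b))
    if (length(miss)) {
      abort(paste0("bin entry missing: ", paste(miss, collapse = ", ")))
    }
    if (!b$verdict %in% c("good", "poor")) abort("verdict must be good/poor")
    for (k in c("completeness", "contamination", "fine_consistency")) {
      if (!is.numeric(b[[k]]) || b[[k]] < 0 || b[[k]] > 100) {
        abort(paste0(k, " must be a percentage in [0, 100]"))
      }
    }
  }
  invisible(TRUE)
}
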