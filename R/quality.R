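# Bin quality: k-mer role projection onto bins (a lightweight annotator
# contract), the completeness / contamination / consistency metrics,
# high-quality classification, problematic-role accounting and the
# contamination-triggered pruning step.

#' Project reference roles onto a bin's contigs
#'
#' A lightweight annotator: for each reference protein carrying a
#' non-hypothetical role, the bin's contigs are scanned in six-frame protein
#' k-mer space. An occurrence of the role is emitted on a contig when the
#' fraction of that protein's distinct k-mers found on the contig is at
#' least `min_kmer_frac`; the similarity of the occurrence is that fraction.
#' Overlapping candidate occurrences of the same role on one contig (e.g.
#' from two reference genomes of a merged bin) collapse to the best.
#'
#' This is a pluggable contract: any function mapping (bin, contigs, ref_db)
#' to the same occurrence table can stand in for it.
#'
#' @param bin One-row bin tibble (or list) with `bin_id` and
#'   `reference_genome_ids`.
#' @param contigs Tibble of the bin's member contigs.
#' @param ref_db A `ref_db`.
#' @param min_kmer_frac Minimum fraction of a protein's k-mers required
#'   (default 0.5).
#' @param k Protein k-mer length (default 12).
#' @return Occurrence tibble: `bin_id`, `contig_id`, `role_id`, `start`,
#'   `end` (0-based half-open), `strand`, `similarity`, `good` (`NA` until
#'   [mark_good_occurrences()]).
#' @export
annotate_bin <- function(bin, contigs, ref_db, min_kmer_frac = 0.5, k = 12) {
  refs <- unlist(bin$reference_genome_ids)
  bin_id <- bin$bin_id[[1]]
  empty <- tibble(
    bin_id = character(0), contig_id = character(0), role_id = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    similarity = numeric(0), good = logical(0)
  )
  prot <- ref_db$proteins |>
    filter(
      .data$genome_id %in% refs, .data$role_id != "hypothetical",
      nchar(.data$aa) >= k
    )
  if (nrow(prot) == 0L || nrow(contigs) == 0L) return(empty)
  pk <- lapply(prot$aa, aa_kmer_set, k = k)
  prot_long <- tibble(
    pidx = rep(seq_len(nrow(prot)), lengths(pk)),
    role_id = rep(prot$role_id, lengths(pk)),
    kmer = unlist(pk, use.names = FALSE)
  )
  ck <- lapply(contigs$seq, six_frame_kmer_table, k = k)
  contig_long <- bind_rows(ck, .id = "ci") |>
    mutate(contig_id = contigs$contig_id[as.integer(.data$ci)]) |>
    select(-"ci")
  if (nrow(contig_long) == 0L) return(empty)
  j <- inner_join(prot_long, contig_long, by = "kmer",
    relationship = "many-to-many"
  )
  if (nrow(j) == 0L) return(empty)
  cand <- j |>
    group_by(.data$pidx, .data$role_id, .data$contig_id) |>
    summarise(
      n_hit = n_distinct(.data$kmer),
      start = min(.data$start), end = max(.data$end),
      strand = names(sort(table(.data$strand), decreasing = TRUE))[1],
      .groups = "drop"
    ) |>
    mutate(similarity = .data$n_hit / lengths(pk)[.data$pidx]) |>
    filter(.data$similarity >= min_kmer_frac)
  if (nrow(cand) == 0L) return(empty)
  # collapse overlapping occurrences of the same role on the same contig
  occ <- cand |>
    arrange(
      .data$role_id, .data$contig_id, desc(.data$similarity),
      .data$start, .data$end
    ) |>
    group_by(.data$role_id, .data$contig_id) |>
    group_modify(function(g, key) {
      keep <- logical(nrow(g))
      for (i in seq_len(nrow(g))) {
        keep[i] <- !any(keep & g$start < g$end[i] & g$end > g$start[i])
      }
      g[keep, , drop = FALSE]
    }) |>
    ungroup()
  occ |>
    mutate(bin_id = bin_id, good = NA) |>
    select(
      "bin_id", "contig_id", "role_id", "start", "end", "strand",
      "similarity", "good"
    ) |>
    arrange(.data$contig_id, .data$start)
}

#' Observed role counts of a bin
#'
#' @param occurrences Occurrence tibble from [annotate_bin()].
#' @return Tibble `role_id`, `n`.
#' @export
role_counts <- function(occurrences) {
  occurrences |> count(.data$role_id, name = "n")
}

count_of <- function(role_counts, roles) {
  n <- role_counts$n[match(roles, role_counts$role_id)]
  replace_na(n, 0L)
}

#' Completeness: percentage of marker roles observed at least once
#'
#' @param role_counts Tibble `role_id`, `n` (observed counts).
#' @param marker_roles Character vector of single-copy universal marker role
#'   ids expected in the bin's domain.
#' @return Percent in `[0, 100]`.
#' @export
completeness <- function(role_counts, marker_roles) {
  if (length(marker_roles) == 0L) abort("completeness is undefined for an empty marker set")
  100 * mean(count_of(role_counts, marker_roles) >= 1L)
}

#' Contamination: percentage of marker roles observed more than once
#'
#' @inheritParams completeness
#' @return Percent in `[0, 100]`.
#' @export
contamination <- function(role_counts, marker_roles) {
  if (length(marker_roles) == 0L) abort("contamination is undefined for an empty marker set")
  100 * mean(count_of(role_counts, marker_roles) > 1L)
}

#' Fine consistency: percentage of predictable roles with exactly the
#' expected count
#'
#' Roles absent from the observation count as observed 0.
#'
#' @param observed_counts Tibble `role_id`, `n`.
#' @param prediction Tibble `role_id`, `expected` (the predictable set).
#' @return Percent in `[0, 100]`.
#' @export
fine_consistency <- function(observed_counts, prediction) {
  if (nrow(prediction) == 0L) abort("fine consistency is undefined for an empty predictable set")
  obs <- count_of(observed_counts, prediction$role_id)
  100 * mean(obs == prediction$expected)
}

#' Coarse consistency: presence/absence agreement with the prediction
#'
#' @inheritParams fine_consistency
#' @return Percent in `[0, 100]`.
#' @export
coarse_consistency <- function(observed_counts, prediction) {
  if (nrow(prediction) == 0L) abort("coarse consistency is undefined for an empty predictable set")
  obs <- count_of(observed_counts, prediction$role_id)
  100 * mean((obs > 0L) == (prediction$expected > 0L))
}

#' Baseline copy-number predictor
#'
#' The trivial multiplicity predictor: every universal marker role of the
#' bin's domain is expected exactly once, and the predictable set equals the
#' marker set. The predictor contract accepts any function mapping
#' (`ref_db`, `domain`) to a tibble `role_id`, `expected`; a trained
#' copy-number model can drop in.
#'
#' @param ref_db A `ref_db`.
#' @param domain `"Bacteria"` or `"Archaea"`.
#' @return Tibble `role_id`, `expected`.
#' @export
baseline_predictor <- function(ref_db, domain = c("Bacteria", "Archaea")) {
  domain <- match.arg(domain)
  mk <- marker_roles(ref_db, domain)
  if (length(mk) == 0L) abort(paste0("no marker roles for domain ", domain))
  tibble(role_id = mk, expected = 1L)
}

#' Check the seed gene of a bin
#'
#' Counts occurrences of the seed role in the bin's annotation; the check
#' passes iff there is exactly one occurrence and its translated length (in
#' residues, from the occurrence footprint) lies within the domain's policy
#' range, boundaries inclusive.
#'
#' @param occurrences Occurrence tibble of the bin.
#' @param domain `"Bacteria"` or `"Archaea"`.
#' @param seed_role_id Seed role id.
#' @param policy A [seed_length_policy()].
#' @return List with `seed_count` and `seed_length_ok`.
#' @export
check_seed_gene <- function(occurrences, domain, seed_role_id,
                            policy = seed_length_policy()) {
  occ <- occurrences |> filter(.data$role_id == seed_role_id)
  cnt <- nrow(occ)
  ok <- FALSE
  if (cnt == 1L) {
    aa_len <- (occ$end - occ$start) %/% 3L
    r <- policy[[domain]]
    ok <- aa_len >= r[1] && aa_len <= r[2]
  }
  list(seed_count = cnt, seed_length_ok = ok)
}

#' Classify a bin as high-quality or not
#'
#' A bin is high-quality (verdict `good`) iff contamination <=
#' `contamination_max`, fine consistency >= `fine_min`, completeness >=
#' `completeness_min` (all boundaries inclusive) and the seed-gene check
#' passes (exactly one seed gene of appropriate length).
#'
#' @param completeness,contamination,fine_consistency Percentages.
#' @param seed_count,seed_length_ok Seed check results.
#' @param contamination_max,fine_min,completeness_min Cutoffs (defaults 10,
#'   87, 80).
#' @return List with `verdict` (`"good"`/`"poor"`) and `failing` (character
#'   vector of violated cutoffs).
#' @export
classify_bin_quality <- function(completeness, contamination, fine_consistency,
                                 seed_count, seed_length_ok,
                                 contamination_max = 10, fine_min = 87,
                                 completeness_min = 80) {
  failing <- character(0)
  if (contamination > contamination_max) failing <- c(failing, "contamination")
  if (fine_consistency < fine_min) failing <- c(failing, "fine_consistency")
  if (completeness < completeness_min) failing <- c(failing, "completeness")
  if (seed_count != 1L || !seed_length_ok) failing <- c(failing, "seed")
  list(verdict = if (length(failing)) "poor" else "good", failing = failing)
}

#' Contig statistics of a bin
#'
#' N50 is the largest length L such that contigs of length >= L total at
#' least half the bin's DNA size; mean coverage is length-weighted.
#'
#' @param contigs Tibble of the bin's member contigs (`length`, `coverage`).
#' @return List with `contig_count`, `dna_size`, `n50`, `mean_coverage`.
#' @export
bin_stats <- function(contigs) {
  if (nrow(contigs) == 0L) abort("bin_stats is undefined for an empty bin")
  len <- sort(contigs$length, decreasing = TRUE)
  cs <- cumsum(len)
  n50 <- len[which(cs >= sum(len) / 2)[1]]
  list(
    contig_count = nrow(contigs),
    dna_size = sum(contigs$length),
    n50 = n50,
    mean_coverage = sum(contigs$length * contigs$coverage) / sum(contigs$length)
  )
}

#' Mark good occurrences of each role
#'
#' For each predictable role with expected count e and m observed
#' occurrences, the top `min(e, m)` occurrences by similarity are marked
#' good; the remainder are potential contamination. Ties are broken
#' deterministically by (similarity desc, contig id, interval start). Roles
#' outside the predictable set have all occurrences marked good (no evidence
#' against them).
#'
#' @param occurrences Occurrence tibble.
#' @param prediction Tibble `role_id`, `expected`.
#' @return The occurrence tibble with the `good` flag set.
#' @export
mark_good_occurrences <- function(occurrences, prediction) {
  if (nrow(occurrences) == 0L) return(occurrences)
  exp_of <- stats::setNames(prediction$expected, prediction$role_id)
  occurrences |>
    arrange(
      .data$role_id, desc(.data$similarity), .data$contig_id, .data$start
    ) |>
    group_by(.data$role_id) |>
    mutate(
      good = if (is.na(exp_of[.data$role_id[1]])) {
        TRUE
      } else {
        row_number() <= exp_of[.data$role_id[1]]
      }
    ) |>
    ungroup() |>
    arrange(.data$contig_id, .data$start)
}

#' Prune contaminated bins
#'
#' When a bin's contamination exceeds the threshold, every member contig
#' whose occurrences are all not-good (and which has at least one
#' occurrence) is discarded. Contigs with zero detected occurrences are
#' retained, and seed-bearing contigs are never removed. Below the
#' threshold the bin is unchanged.
#'
#' @param member_contig_ids Character vector of the bin's member contigs.
#' @param seed_contig_ids Seed-bearing contigs of the bin (never removed).
#' @param occurrences Occurrence tibble with `good` flags
#'   ([mark_good_occurrences()]).
#' @param contamination The bin's contamination percentage.
#' @param contamination_threshold Pruning trigger (default 10, strict
#'   inequality: pruning happens only above it).
#' @return List with `keep` and `removed` contig-id vectors.
#' @export
postprocess_bin <- function(member_contig_ids, seed_contig_ids, occurrences,
                            contamination, contamination_threshold = 10) {
  if (contamination <= contamination_threshold) {
    return(list(keep = member_contig_ids, removed = character(0)))
  }
  per_contig <- occurrences |>
    group_by(.data$contig_id) |>
    summarise(any_good = any(.data$good), .groups = "drop")
  bad <- per_contig$contig_id[!per_contig$any_good]
  removed <- setdiff(intersect(bad, member_contig_ids), seed_contig_ids)
  list(keep = setdiff(member_contig_ids, removed), removed = removed)
}

#' Problematic-role report rows
#'
#' One row per predictable role whose observed count differs from its
#' expected count, with flags for universality (membership in the marker
#' set) and presence in the bin's reference genome(s).
#'
#' @param observed_counts Tibble `role_id`, `n`.
#' @param prediction Tibble `role_id`, `expected`.
#' @param marker_role_ids Marker roles of the bin's domain.
#' @param reference_role_ids Roles present in the bin's reference genome(s).
#' @return Tibble `role_id`, `observed`, `expected`, `universal`,
#'   `in_reference`.
#' @export
problematic_roles <- function(observed_counts, prediction, marker_role_ids,
                              reference_role_ids) {
  obs <- count_of(observed_counts, prediction$role_id)
  bad <- obs != prediction$expected
  tibble(
    role_id = prediction$role_id[bad],
    observed = obs[bad],
    expected = prediction$expected[bad],
    universal = prediction$role_id[bad] %in% marker_role_ids,
    in_reference = prediction$role_id[bad] %in% reference_role_ids
  ) |>
    arrange(.data$role_id)
}

empty_bin_metrics <- function() {
  tibble(
    bin_id = character(0), reference_genome_ids = list(),
    species_id = character(0), domain = character(0),
    ref_similarity = numeric(0),
    completeness = numeric(0), contamination = numeric(0),
    fine_consistency = numeric(0), coarse_consistency = numeric(0),
    seed_count = integer(0), seed_length_ok = logical(0),
    contig_count = integer(0), dna_size = numeric(0), n50 = numeric(0),
    mean_coverage = numeric(0), verdict = character(0), failing = list(),
    score = numeric(0), pruned_contigs = list()
  )
}

# Evaluate all bins of a binning run: annotate, compute metrics, prune
# contaminated bins once, recompute, classify. Returns metrics, marked
# occurrences, problematic-role tables and the (possibly pruned) assignments.
evaluate_bins <- function(bins, assignments, contigs, ref_db, config) {
  if (nrow(bins) == 0L) {
    return(list(
      metrics = empty_bin_metrics(), occurrences = tibble(),
      problematic = list(), assignments = assignments
    ))
  }
  metrics_rows <- list()
  occ_all <- list()
  prob_all <- list()
  annotator <- config$annotator_fn %||% annotate_bin
  predictor <- config$predictor_fn %||% baseline_predictor
  domains <- stats::setNames(ref_db$genomes$domain, ref_db$genomes$genome_id)
  for (i in seq_len(nrow(bins))) {
    bin <- bins[i, ]
    domain <- unname(domains[bin$reference_genome_ids[[1]][1]])
    members <- assignments$contig_id[
      !is.na(assignments$bin_id) & assignments$bin_id == bin$bin_id
    ]
    member_tbl <- contigs |> filter(.data$contig_id %in% members)
    occ <- annotator(bin, member_tbl, ref_db,
      min_kmer_frac = config$min_role_kmer_frac, k = config$disc_k
    )
    pred <- predictor(ref_db, domain)
    mk <- marker_roles(ref_db, domain)
    counts <- role_counts(occ)
    cont <- contamination(counts, mk)
    occ <- mark_good_occurrences(occ, pred)
    pruned <- character(0)
    if (cont > config$contamination_max) {
      pp <- postprocess_bin(
        members, unlist(bin$contig_ids), occ, cont,
        contamination_threshold = config$contamination_max
      )
      pruned <- pp$removed
      if (length(pruned)) {
        members <- pp$keep
        member_tbl <- contigs |> filter(.data$contig_id %in% members)
        occ <- occ |> filter(!(.data$contig_id %in% pruned))
        counts <- role_counts(occ)
        cont <- contamination(counts, mk)
        occ <- mark_good_occurrences(occ, pred)
        assignments$bin_id[assignments$contig_id %in% pruned] <- NA_character_
        assignments$stage[assignments$contig_id %in% pruned] <- "none"
        assignments$reason[assignments$contig_id %in% pruned] <- "pruned"
      }
    }
    compl <- completeness(counts, mk)
    fine <- fine_consistency(counts, pred)
    coarse <- coarse_consistency(counts, pred)
    seed_chk <- check_seed_gene(occ, domain, ref_db$seed_role_id,
      policy = config$seed_policy
    )
    stats_ <- bin_stats(member_tbl)
    cls <- classify_bin_quality(
      compl, cont, fine, seed_chk$seed_count, seed_chk$seed_length_ok,
      contamination_max = config$contamination_max,
      fine_min = config$fine_min, completeness_min = config$completeness_min
    )
    ref_roles <- ref_db$proteins |>
      filter(.data$genome_id %in% bin$reference_genome_ids[[1]]) |>
      pull("role_id") |>
      unique()
    prob_all[[bin$bin_id]] <- problematic_roles(counts, pred, mk, ref_roles)
    occ_all[[i]] <- occ
    metrics_rows[[i]] <- tibble(
      bin_id = bin$bin_id,
      reference_genome_ids = list(bin$reference_genome_ids[[1]]),
      species_id = bin$species_id,
      domain = domain,
      ref_similarity = bin$ref_similarity,
      completeness = compl, contamination = cont,
      fine_consistency = fine, coarse_consistency = coarse,
      seed_count = seed_chk$seed_count,
      seed_length_ok = seed_chk$seed_length_ok,
      contig_count = stats_$contig_count, dna_size = stats_$dna_size,
      n50 = stats_$n50, mean_coverage = stats_$mean_coverage,
      verdict = cls$verdict, failing = list(cls$failing),
      score = mean(c(compl, fine, 100 - cont)),
      pruned_contigs = list(pruned)
    )
  }
  list(
    metrics = bind_rows(metrics_rows),
    occurrences = bind_rows(occ_all),
    problematic = prob_all,
    assignments = assignments
  )
}
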