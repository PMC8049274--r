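# Contig sorting: the sample-specific discriminating protein 12-mer index,
# assignment of contigs to bins by discriminating-hit counts, and rescue of
# unbinned contigs through exact canonical 50-mer DNA matches.

#' Build the discriminating protein k-mer index
#'
#' Enumerates the distinct protein k-mers (default 12 residues) of each bin's
#' reference proteomes; k-mers occurring in two or more bins' sets are
#' discarded, and the remainder map to their unique bin. The index is
#' sample-specific: which k-mers discriminate depends on which references
#' were pulled into the sample's bins. With a single bin every reference
#' k-mer is discriminating (valid degenerate case, with a warning).
#'
#' @param bins Bin tibble with assigned references ([merge_bins()]).
#' @param ref_db A `ref_db`.
#' @param k K-mer length in residues (default 12).
#' @return A `disc_index`: list with `k`, `map` (tibble `kmer`, `bin_id`) and
#'   `bin_kmer_counts` (per-bin totals and discriminating counts).
#' @export
build_discriminating_index <- function(bins, ref_db, k = 12) {
  if (nrow(bins) == 0L) abort("cannot build a discriminating index without bins")
  if (nrow(bins) == 1L) {
    warn("single bin: every reference k-mer is discriminating")
  }
  per_bin <- map(seq_len(nrow(bins)), function(i) {
    prot <- ref_db$proteins |>
      filter(.data$genome_id %in% bins$reference_genome_ids[[i]])
    tibble(
      bin_id = bins$bin_id[i],
      kmer = unique(unlist(lapply(prot$aa, aa_kmer_set, k = k), use.names = FALSE))
    )
  })
  long <- bind_rows(per_bin)
  shared <- unique(long$kmer[duplicated(long$kmer)])
  map_tbl <- long |> filter(!(.data$kmer %in% shared))
  counts <- long |>
    count(.data$bin_id, name = "n_total") |>
    left_join(count(map_tbl, .data$bin_id, name = "n_discriminating"), by = "bin_id") |>
    mutate(n_discriminating = replace_na(.data$n_discriminating, 0L))
  structure(list(k = k, map = map_tbl, bin_kmer_counts = counts),
    class = "disc_index"
  )
}

#' @export
print.disc_index <- function(x, ...) {
  cat(
    "<disc_index> k=", x$k, ", ", nrow(x$map), " discriminating k-mers over ",
    nrow(x$bin_kmer_counts), " bins\n",
    sep = ""
  )
  invisible(x)
}

unbinned_assignment <- function(contig_id, reason) {
  tibble(
    contig_id = contig_id, bin_id = NA_character_, stage = "none",
    best_count = 0L, runner_up_count = 0L, reason = reason
  )
}

#' Assign contigs to bins by discriminating k-mer counts
#'
#' For each contig the distinct discriminating k-mers (via
#' [six_frame_kmers()]) are counted per bin. The contig is assigned to the
#' argmax bin iff the maximum count is at least `min_hits` and the argmax is
#' unique; otherwise it stays unbinned with a reason (`below-threshold`,
#' `tie`, or `no-hits`). Seed-bearing contigs are pinned to their bins
#' (stage `seed`) and never reassigned.
#'
#' @param contigs QC-passed contig tibble.
#' @param index A `disc_index` from [build_discriminating_index()].
#' @param bins Bin tibble (pins its seed-bearing contigs).
#' @param min_hits Minimum discriminating k-mers for assignment (default 10).
#' @return An assignment tibble: `contig_id`, `bin_id` (`NA` when unbinned),
#'   `stage` (`seed`/`kmer`/`none`), `best_count`, `runner_up_count`,
#'   `reason`.
#' @export
assign_contigs <- function(contigs, index, bins, min_hits = 10) {
  seed_map <- tibble(
    contig_id = unlist(bins$contig_ids),
    bin_id = rep(bins$bin_id, lengths(bins$contig_ids))
  )
  out <- vector("list", nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[i]
    pin <- seed_map$bin_id[seed_map$contig_id == cid]
    if (length(pin)) {
      out[[i]] <- tibble(
        contig_id = cid, bin_id = pin[1], stage = "seed",
        best_count = NA_integer_, runner_up_count = NA_integer_,
        reason = NA_character_
      )
      next
    }
    km <- six_frame_kmers(contigs$seq[i], k = index$k)
    hit_bins <- index$map$bin_id[match(km, index$map$kmer)]
    hit_bins <- hit_bins[!is.na(hit_bins)]
    if (length(hit_bins) == 0L) {
      out[[i]] <- unbinned_assignment(cid, "no-hits")
      next
    }
    counts <- sort(table(hit_bins), decreasing = TRUE)
    best <- as.integer(counts[1])
    runner <- if (length(counts) > 1L) as.integer(counts[2]) else 0L
    if (best < min_hits) {
      out[[i]] <- tibble(
        contig_id = cid, bin_id = NA_character_, stage = "none",
        best_count = best, runner_up_count = runner, reason = "below-threshold"
      )
    } else if (runner == best) {
      out[[i]] <- tibble(
        contig_id = cid, bin_id = NA_character_, stage = "none",
        best_count = best, runner_up_count = runner, reason = "tie"
      )
    } else {
      out[[i]] <- tibble(
        contig_id = cid, bin_id = names(counts)[1], stage = "kmer",
        best_count = best, runner_up_count = runner, reason = NA_character_
      )
    }
  }
  bind_rows(out)
}

#' Build the rescue index of canonical DNA k-mers
#'
#' Collects the canonical DNA k-mers (default 50 bp; see
#' [dna_canonical_kmers()]) of every successfully binned contig and maps each
#' to its bin. K-mers seen in two or more bins are removed, so an index hit
#' is always unambiguous.
#'
#' @param contigs Contig tibble.
#' @param assignments Assignment tibble; rows with a non-`NA` `bin_id` are
#'   the binned contigs.
#' @param k K-mer length in bp (default 50).
#' @return A `rescue_index`: list with `k` and `map` (tibble `kmer`,
#'   `bin_id`).
#' @export
build_rescue_index <- function(contigs, assignments, k = 50) {
  binned <- assignments |> filter(!is.na(.data$bin_id))
  long <- binned |>
    inner_join(contigs[, c("contig_id", "seq")], by = "contig_id") |>
    group_by(.data$bin_id) |>
    summarise(
      kmer = list(unique(unlist(lapply(.data$seq, dna_canonical_kmers, k = k)))),
      .groups = "drop"
    ) |>
    unnest("kmer")
  shared <- unique(long$kmer[duplicated(long$kmer)])
  structure(
    list(k = k, map = long |> filter(!(.data$kmer %in% shared))),
    class = "rescue_index"
  )
}

#' Rescue unbinned contigs by exact DNA matches
#'
#' An unbinned contig is placed into bin B iff it contains at least one
#' canonical k-mer mapped to B and no canonical k-mer mapped to any other
#' bin; contigs hitting two or more bins stay unbinned. Rescue is a single
#' pass: rescued contigs do not seed further rescue.
#'
#' @param contigs Contig tibble.
#' @param assignments Assignment tibble from [assign_contigs()].
#' @param rescue_index A `rescue_index` from [build_rescue_index()].
#' @return The assignment tibble with rescued contigs moved to stage
#'   `rescue`.
#' @export
rescue_contigs <- function(contigs, assignments, rescue_index) {
  unb <- which(is.na(assignments$bin_id))
  if (length(unb) == 0L || nrow(rescue_index$map) == 0L) return(assignments)
  seqs <- contigs$seq[match(assignments$contig_id[unb], contigs$contig_id)]
  for (j in seq_along(unb)) {
    km <- dna_canonical_kmers(seqs[j], k = rescue_index$k)
    hit <- unique(rescue_index$map$bin_id[match(km, rescue_index$map$kmer)])
    hit <- hit[!is.na(hit)]
    if (length(hit) == 1L) {
      i <- unb[j]
      assignments$bin_id[i] <- hit
      assignments$stage[i] <- "rescue"
      assignments$reason[i] <- NA_character_
    }
  }
  assignments
}
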