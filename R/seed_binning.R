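# Bin initialization: locate seed-protein occurrences on the contigs,
# open one provisional bin per seed-bearing contig, assign the nearest
# reference genome by seed 8-mer Jaccard similarity, and merge bins whose
# references share a species.

empty_seed_hits <- function() {
  tibble(
    contig_id = character(0), seed_entry_id = character(0),
    seed_coverage_fraction = numeric(0), identity_fraction = numeric(0),
    start = integer(0), end = integer(0), strand = character(0),
    translated_seed = character(0)
  )
}

# map an aa interval [j1, j2] (1-based, inclusive, in frame coordinates)
# to 0-based half-open nt coordinates on the forward strand
frame_interval_to_nt <- function(j1, j2, strand, offset, L) {
  if (strand == "+") {
    start <- offset + 3L * (j1 - 1L)
    end <- offset + 3L * j2
  } else {
    end <- L - (offset + 3L * (j1 - 1L))
    start <- L - (offset + 3L * j2)
  }
  c(as.integer(start), as.integer(end))
}

#' Find seed-protein occurrences on contigs
#'
#' Searches the contigs for occurrences of the reference seed proteins by
#' translated local alignment: every reading frame sharing at least one
#' amino-acid 8-mer with a seed is aligned against it (Smith-Waterman via
#' `Biostrings::pairwiseAlignment`, BLOSUM62). A hit is retained only if the
#' aligned region covers at least `min_seed_cov` of the seed sequence, the
#' contig has at least `min_contig_cov` fold coverage, and the contig is at
#' least `min_len` bp long. Overlapping hits on one contig are reduced to the
#' best (highest identity) per locus.
#'
#' @param contigs QC-passed contig tibble.
#' @param ref_db A `ref_db` (its `seeds` table is the seed database).
#' @param min_seed_cov Minimum fraction of the seed covered by the alignment
#'   (default 2/3).
#' @param min_contig_cov Minimum contig fold coverage (default 4).
#' @param min_len Minimum contig length in bp (default 400).
#' @return A seed-hit tibble: `contig_id`, `seed_entry_id`,
#'   `seed_coverage_fraction`, `identity_fraction`, `start`, `end` (0-based
#'   half-open on the contig), `strand`, `translated_seed`.
#' @export
find_seed_hits <- function(contigs, ref_db, min_seed_cov = 2 / 3,
                           min_contig_cov = 4.0, min_len = 400) {
  seeds <- ref_db$seeds
  if (nrow(seeds) == 0L) abort("seed database is empty")
  cand <- contigs |>
    filter(.data$coverage >= min_contig_cov, .data$length >= min_len)
  if (nrow(cand) == 0L) {
    warn("no bins can be initialized: no contig passes the coverage/length filters")
    return(empty_seed_hits())
  }
  seed_k8 <- lapply(seeds$aa, aa_kmer_set, k = 8)
  rows <- list()
  for (ci in seq_len(nrow(cand))) {
    seq <- cand$seq[ci]
    L <- nchar(seq)
    tr <- six_frame_translations(seq)
    fr_k8 <- lapply(tr$aa, aa_kmer_set, k = 8)
    for (si in seq_len(nrow(seeds))) {
      frames <- which(map_lgl(fr_k8, function(x) any(x %in% seed_k8[[si]])))
      if (length(frames) == 0L) next
      seed_aa <- Biostrings::AAString(seeds$aa[si])
      for (f in frames) {
        aln <- Biostrings::pairwiseAlignment(
          pattern = seed_aa,
          subject = Biostrings::AAString(tr$aa[f]),
          type = "local", substitutionMatrix = blosum62(),
          gapOpening = 10, gapExtension = 0.5
        )
        p <- Biostrings::pattern(aln)
        cov_frac <- (Biostrings::end(p) - Biostrings::start(p) + 1L) /
          nchar(seeds$aa[si])
        if (cov_frac < min_seed_cov) next
        s <- Biostrings::subject(aln)
        nt <- frame_interval_to_nt(
          Biostrings::start(s), Biostrings::end(s),
          tr$strand[f], tr$offset[f], L
        )
        rows[[length(rows) + 1L]] <- tibble(
          contig_id = cand$contig_id[ci],
          seed_entry_id = seeds$genome_id[si],
          seed_coverage_fraction = cov_frac,
          identity_fraction = Biostrings::pid(aln, type = "PID1") / 100,
          start = nt[1], end = nt[2], strand = tr$strand[f],
          translated_seed = gsub("-", "", as.character(s), fixed = TRUE)
        )
      }
    }
  }
  hits <- bind_rows(rows)
  if (nrow(hits) == 0L) {
    warn("no bins can be initialized: no seed hit passes the filters")
    return(empty_seed_hits())
  }
  # best identity wins per overlapping locus of each contig
  hits <- hits |>
    arrange(
      .data$contig_id, desc(.data$identity_fraction),
      desc(.data$seed_coverage_fraction), .data$seed_entry_id, .data$start
    )
  kept <- hits |>
    group_by(.data$contig_id) |>
    group_modify(function(g, key) {
      keep <- logical(nrow(g))
      for (i in seq_len(nrow(g))) {
        overlaps <- any(keep & g$start < g$end[i] & g$end > g$start[i])
        keep[i] <- !overlaps
      }
      g[keep, , drop = FALSE]
    }) |>
    ungroup() |>
    arrange(.data$contig_id, .data$start)
  kept
}

#' Import seed hits from an external aligner's tabular output
#'
#' Reads a 12-column tab-separated hit table (the common tabular dialect:
#' query id, subject id, percent identity, alignment length, mismatches, gap
#' opens, query start, query end, subject start, subject end, e-value, bit
#' score; 1-based inclusive coordinates) produced by aligning contigs
#' (queries) against the seed DNA database, and applies the same retention
#' filters as [find_seed_hits()].
#'
#' @param path Tabular hit file.
#' @param contigs QC-passed contig tibble (for coverage/length filters).
#' @param ref_db A `ref_db` (seed lengths for the coverage fraction).
#' @inheritParams find_seed_hits
#' @return A seed-hit tibble (with `translated_seed` derived from the contig
#'   interval).
#' @export
read_seed_hits_blast <- function(path, contigs, ref_db, min_seed_cov = 2 / 3,
                                 min_contig_cov = 4.0, min_len = 400) {
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  tab <- utils::read.delim(path, header = FALSE, col.names = cols,
    colClasses = c(
      "character", "character", rep("numeric", 4),
      rep("integer", 4), "numeric", "numeric"
    )
  )
  seeds <- ref_db$seeds
  seed_aa_len <- stats::setNames(nchar(seeds$aa), seeds$genome_id)
  ct <- contigs |> select("contig_id", "seq", "length", "coverage")
  hits <- as_tibble(tab) |>
    inner_join(ct, by = c(qseqid = "contig_id")) |>
    mutate(
      # subject is seed DNA: convert aligned nt span to aa fraction
      seed_coverage_fraction =
        (abs(.data$send - .data$sstart) + 1) / (3 * seed_aa_len[.data$sseqid]),
      identity_fraction = .data$pident / 100,
      strand = if_else(.data$qend >= .data$qstart, "+", "-"),
      start = as.integer(pmin(.data$qstart, .data$qend) - 1L),
      end = as.integer(pmax(.data$qstart, .data$qend))
    ) |>
    filter(
      .data$seed_coverage_fraction >= min_seed_cov,
      .data$coverage >= min_contig_cov,
      .data$length >= min_len
    )
  if (nrow(hits) == 0L) return(empty_seed_hits())
  hits <- hits |>
    mutate(
      translated_seed = map_chr(seq_len(dplyr::n()), function(i) {
        sub <- substr(hits$seq[i], hits$start[i] + 1L, hits$end[i])
        if (hits$strand[i] == "-") sub <- revcomp_chr(sub)
        len <- nchar(sub) - nchar(sub) %% 3L
        if (len < 3L) return("")
        as.character(Biostrings::translate(
          Biostrings::DNAString(substr(sub, 1L, len)),
          genetic.code = genetic_code_11(), if.fuzzy.codon = "X",
          no.init.codon = TRUE
        ))
      }),
      contig_id = .data$qseqid, seed_entry_id = .data$sseqid
    ) |>
    select(
      "contig_id", "seed_entry_id", "seed_coverage_fraction",
      "identity_fraction", "start", "end", "strand", "translated_seed"
    ) |>
    arrange(
      .data$contig_id, desc(.data$identity_fraction),
      desc(.data$seed_coverage_fraction), .data$seed_entry_id, .data$start
    )
  hits |>
    group_by(.data$contig_id) |>
    group_modify(function(g, key) {
      keep <- logical(nrow(g))
      for (i in seq_len(nrow(g))) {
        keep[i] <- !any(keep & g$start < g$end[i] & g$end > g$start[i])
      }
      g[keep, , drop = FALSE]
    }) |>
    ungroup() |>
    arrange(.data$contig_id, .data$start)
}

empty_bins <- function() {
  tibble(
    bin_id = character(0), contig_ids = list(), seed_hits = list(),
    reference_genome_ids = list(), species_id = character(0),
    ref_similarity = numeric(0), usable = logical(0), merged_from = list()
  )
}

#' Initialize provisional bins from seed hits
#'
#' One bin per seed-bearing contig: a contig with multiple non-overlapping
#' seed hits yields a single bin holding all of them (a contig cannot belong
#' to two bins). Bin ids are minted deterministically in sorted contig-id
#' order.
#'
#' @param hits Seed-hit tibble from [find_seed_hits()].
#' @return A bin tibble: `bin_id`, `contig_ids` (list), `seed_hits` (list of
#'   tibbles), plus empty reference-assignment columns.
#' @export
init_bins <- function(hits) {
  if (nrow(hits) == 0L) return(empty_bins())
  ids <- sort(unique(hits$contig_id))
  width <- max(3L, nchar(length(ids)))
  tibble(
    bin_id = sprintf("bin_%0*d", width, seq_along(ids)),
    contig_ids = as.list(ids),
    seed_hits = map(ids, function(cid) hits |> filter(.data$contig_id == cid)),
    reference_genome_ids = vector("list", length(ids)),
    species_id = NA_character_,
    ref_similarity = NA_real_,
    usable = NA,
    merged_from = vector("list", length(ids))
  )
}

#' Assign the nearest reference genome to each bin
#'
#' Computes the 8-mer Jaccard similarity ([kmer_jaccard()]) between each
#' bin's translated seed (its best hit: highest identity, then coverage) and
#' every reference seed, and assigns the argmax genome and its species. Ties
#' are broken by the lexicographically smallest genome id. A bin whose best
#' similarity is 0 is flagged unusable ("no usable reference") and excluded
#' from downstream binning.
#'
#' @param bins Bin tibble from [init_bins()].
#' @param ref_db A `ref_db`.
#' @param k Seed-similarity k-mer length (default 8).
#' @return The bin tibble with `reference_genome_ids`, `species_id`,
#'   `ref_similarity` and `usable` filled in.
#' @export
assign_reference <- function(bins, ref_db, k = 8) {
  if (nrow(bins) == 0L) return(bins)
  seeds <- ref_db$seeds |> arrange(.data$genome_id)
  species <- stats::setNames(ref_db$genomes$species_id, ref_db$genomes$genome_id)
  for (i in seq_len(nrow(bins))) {
    sh <- bins$seed_hits[[i]] |>
      arrange(
        desc(.data$identity_fraction), desc(.data$seed_coverage_fraction),
        .data$start
      )
    query <- sh$translated_seed[1]
    sims <- vapply(seeds$aa, kmer_jaccard, numeric(1),
      seq_b = query, k = k, USE.NAMES = FALSE
    )
    best <- max(sims)
    if (best == 0) {
      warn(paste0("bin ", bins$bin_id[i], ": no usable reference (all similarities 0)"))
      bins$usable[i] <- FALSE
      next
    }
    g <- seeds$genome_id[sims == best][1] # seeds sorted: lexicographic tie-break
    bins$reference_genome_ids[[i]] <- g
    bins$species_id[i] <- unname(species[g])
    bins$ref_similarity[i] <- best
    bins$usable[i] <- TRUE
  }
  bins
}

#' Merge bins whose reference genomes share a species
#'
#' Bins are partitioned by assigned `species_id`; each merged bin unions
#' member contigs, seed hits and reference genome ids, keeps the
#' lexicographically smallest member bin id, and records merge provenance in
#' `merged_from`. Bins flagged unusable are dropped (with a message).
#'
#' @param bins Bin tibble after [assign_reference()].
#' @return The merged bin tibble, sorted by bin id.
#' @export
merge_bins <- function(bins) {
  if (nrow(bins) == 0L) return(bins)
  if (any(!bins$usable)) {
    inform(paste0(
      sum(!bins$usable), " bin(s) without a usable reference excluded from binning"
    ))
    bins <- bins |> filter(.data$usable)
  }
  if (nrow(bins) == 0L) return(bins)
  merged <- bins |>
    group_by(.data$species_id) |>
    group_modify(function(g, key) {
      g <- g |> arrange(.data$bin_id)
      tibble(
        bin_id = g$bin_id[1],
        contig_ids = list(unique(unlist(g$contig_ids))),
        seed_hits = list(bind_rows(g$seed_hits)),
        reference_genome_ids = list(sort(unique(unlist(g$reference_genome_ids)))),
        ref_similarity = max(g$ref_similarity),
        usable = TRUE,
        merged_from = list(if (nrow(g) > 1L) g$bin_id else character(0))
      )
    }) |>
    ungroup() |>
    select(
      "bin_id", "contig_ids", "seed_hits", "reference_genome_ids",
      "species_id", "ref_similarity", "usable", "merged_from"
    ) |>
    arrange(.data$bin_id)
  merged
}
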