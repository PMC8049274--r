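# Synthetic reference databases and metagenomic samples with ground truth:
# the test harness for the whole pipeline. Genomes are simulated
# gene-by-gene from a shared ancestral proteome, so translation, k-mer and
# marker logic are exercised exactly as on real data, with no downloads.

random_protein <- function(len) {
  alphabet <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Simulate a reference database
#'
#' Builds `n_genomes` bacterial genomes as sets of coding genes. One random
#' ancestral protein is drawn per role; each genome derives its copy by
#' substituting amino acids at rate `divergence` (uniform over the other 19
#' residues) and encoding the result with random synonymous codons
#' (translation table 11). The first `n_markers` roles form the universal
#' marker set, present exactly once per genome; role 1 is the seed role (a
#' pheS-like phenylalanyl-tRNA synthetase alpha chain) whose protein length
#' is drawn inside the bacterial seed-length policy range. Each genome is
#' its own species. Deterministic given `seed`.
#'
#' @param n_genomes Number of genomes (>= 2).
#' @param n_roles Number of roles (>= 25).
#' @param seed RNG seed (recorded in the manifest).
#' @param divergence Per-genome amino-acid substitution rate from the
#'   ancestral proteome (default 0.25; pairwise inter-genome divergence is
#'   then roughly 0.4).
#' @param n_markers Number of universal marker roles (default 20).
#' @param mean_protein_len Mean non-seed protein length in residues
#'   (default 300).
#' @return A `ref_db` with a `manifest` attribute (seed and parameters).
#' @export
simulate_reference_db <- function(n_genomes = 5, n_roles = 40, seed = 1,
                                  divergence = 0.25, n_markers = 20,
                                  mean_protein_len = 300) {
  stopifnot(n_genomes >= 2, n_roles >= 25, n_markers >= 2, n_markers <= n_roles)
  withr::with_seed(seed, {
    role_id <- sprintf("R%04d", seq_len(n_roles))
    role_name <- c(
      "Phenylalanyl-tRNA synthetase alpha chain (pheS)",
      paste0("synthetic role ", seq_len(n_roles - 1L))
    )
    is_marker <- seq_len(n_roles) <= n_markers
    roles <- tibble(
      role_id = role_id, role_name = role_name,
      is_marker_bacteria = is_marker, is_marker_archaea = is_marker
    )
    seed_len <- sample(250:360, 1L)
    other_len <- pmax(
      100L,
      as.integer(round(stats::rnorm(n_roles - 1L, mean_protein_len, 60)))
    )
    ancestral <- c(
      random_protein(seed_len),
      vapply(other_len, random_protein, character(1))
    )
    genomes <- tibble(
      genome_id = sprintf("G%03d", seq_len(n_genomes)),
      name = paste0("Synthabacter species ", seq_len(n_genomes)),
      species_id = sprintf("S%03d", seq_len(n_genomes)),
      species_name = paste0("Synthabacter species ", seq_len(n_genomes)),
      domain = "Bacteria"
    )
    prot_rows <- list()
    seed_rows <- list()
    for (g in seq_len(n_genomes)) {
      for (r in seq_len(n_roles)) {
        aa <- mutate_protein(ancestral[r], divergence)
        dna <- back_translate(aa)
        prot_rows[[length(prot_rows) + 1L]] <- tibble(
          protein_id = sprintf("%s_P%04d", genomes$genome_id[g], r),
          genome_id = genomes$genome_id[g],
          role_id = role_id[r], aa = aa, dna = dna
        )
        if (r == 1L) {
          seed_rows[[g]] <- tibble(
            genome_id = genomes$genome_id[g], aa = aa, dna = dna
          )
        }
      }
    }
    proteins <- bind_rows(prot_rows)
    db <- new_ref_db(
      genomes = genomes,
      proteins = proteins |> select("protein_id", "genome_id", "role_id", "aa"),
      seeds = bind_rows(seed_rows),
      roles = roles,
      seed_role_id = role_id[1]
    )
    # gene DNA is kept for sample simulation
    attr(db, "gene_dna") <- proteins |> select("protein_id", "genome_id", "role_id", "dna")
    attr(db, "manifest") <- list(
      generator = "simulate_reference_db", seed = seed,
      n_genomes = n_genomes, n_roles = n_roles, divergence = divergence,
      n_markers = n_markers, mean_protein_len = mean_protein_len
    )
    db
  })
}

#' Describe a synthetic community
#'
#' @param species Tibble with one row per community member: `genome_id`
#'   (reference it derives from), `divergence` (amino-acid substitution rate
#'   from that reference, in `[0, 1)`), `coverage` (fold coverage, > 0).
#' @param frag_mean,frag_sd,frag_min Fragment-length distribution: lengths
#'   are drawn from N(`frag_mean`, `frag_sd`) truncated below at `frag_min`
#'   bp (defaults 2000, 500, 1000).
#' @param decoy_fraction Fraction of contigs drawn from no reference
#'   (random DNA; default 0.05).
#' @param keep_seed_intact Keep the seed gene on a single fragment (default
#'   `TRUE`): breakpoints falling inside it are moved to its end, emulating
#'   assemblies in which the single-copy marker locus is contiguous.
#' @param seed RNG seed.
#' @return A `community_spec` list.
#' @export
community_spec <- function(species, frag_mean = 2000, frag_sd = 500,
                           frag_min = 1000, decoy_fraction = 0.05,
                           keep_seed_intact = TRUE, seed = 1) {
  species <- as_tibble(species)
  stopifnot(
    all(c("genome_id", "divergence", "coverage") %in% names(species)),
    all(species$divergence >= 0 & species$divergence < 1),
    all(species$coverage > 0),
    frag_min >= 1, decoy_fraction >= 0, decoy_fraction < 1
  )
  structure(
    list(
      species = species, frag_mean = frag_mean, frag_sd = frag_sd,
      frag_min = frag_min, decoy_fraction = decoy_fraction,
      keep_seed_intact = keep_seed_intact, seed = seed
    ),
    class = "community_spec"
  )
}

# substitute amino acids of a gene's DNA at codon level: untouched codons
# keep their reference DNA, so divergence 0 leaves the DNA identical
mutate_gene_dna <- function(dna, rate) {
  if (rate <= 0) return(dna)
  n_codon <- nchar(dna) %/% 3L
  hit <- which(stats::runif(n_codon) < rate)
  if (length(hit) == 0L) return(dna)
  codons <- substring(dna, 3L * (seq_len(n_codon) - 1L) + 1L, 3L * seq_len(n_codon))
  gc <- genetic_code_11()
  tab <- codons_by_aa()
  alphabet <- names(tab)
  for (i in hit) {
    aa_old <- unname(gc[codons[i]])
    if (is.na(aa_old) || aa_old == "*") next
    aa_new <- sample(setdiff(alphabet, aa_old), 1L)
    cs <- tab[[aa_new]]
    codons[i] <- cs[sample.int(length(cs), 1L)]
  }
  paste0(codons, collapse = "")
}

random_dna <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a metagenomic sample from a reference database
#'
#' For each community member, the genes of its reference genome (as simulated
#' by [simulate_reference_db()]) are concatenated into a genome, amino-acid
#' substitutions are applied at the member's `divergence` rate (codon-level:
#' untouched codons keep the reference DNA, so divergence 0 yields exact
#' substrings of the reference), and the genome is fragmented into contigs
#' with the spec's length distribution. Each fragment is reverse-complemented
#' with probability 1/2 and written with a SPAdes-style header embedding its
#' coverage. Decoy contigs of random DNA are added. The truth table covers
#' every emitted contig.
#'
#' @param ref_db A `ref_db` from [simulate_reference_db()].
#' @param spec A [community_spec()].
#' @return List with `contigs` (contig tibble) and `truth` (tibble
#'   `contig_id`, `genome_id`, `species_id`; decoys carry species
#'   `"DECOY"`), plus a `manifest` attribute.
#' @export
simulate_sample <- function(ref_db, spec) {
  gene_dna <- attr(ref_db, "gene_dna")
  if (is.null(gene_dna)) {
    abort("simulate_sample needs a ref_db produced by simulate_reference_db")
  }
  missing <- setdiff(spec$species$genome_id, ref_db$genomes$genome_id)
  if (length(missing)) {
    abort(paste0("community species not in ref_db: ", paste(missing, collapse = ", ")))
  }
  withr::with_seed(spec$seed, {
    contig_rows <- list()
    truth_rows <- list()
    node <- 0L
    for (s in seq_len(nrow(spec$species))) {
      gid <- spec$species$genome_id[s]
      div <- spec$species$divergence[s]
      cov <- spec$species$coverage[s]
      genes <- gene_dna |> filter(.data$genome_id == gid)
      seed_is_first <- genes$role_id == ref_db$seed_role_id
      genes <- bind_rows(genes[seed_is_first, ], genes[!seed_is_first, ])
      dna <- vapply(genes$dna, mutate_gene_dna, character(1),
        rate = div, USE.NAMES = FALSE
      )
      seed_start <- 1L
      seed_end <- nchar(dna[1]) # seed gene leads the genome
      genome <- paste0(dna, collapse = "")
      glen <- nchar(genome)
      # fragment sequentially; optionally keep the seed locus contiguous
      pos <- 1L
      while (pos <= glen) {
        flen <- max(
          spec$frag_min,
          as.integer(round(stats::rnorm(1, spec$frag_mean, spec$frag_sd)))
        )
        brk <- min(pos + flen - 1L, glen)
        if (spec$keep_seed_intact && brk >= seed_start && brk < seed_end &&
          pos <= seed_start) {
          brk <- seed_end
        }
        # avoid emitting a sub-minimum tail: absorb it into this fragment
        if (glen - brk < spec$frag_min) brk <- glen
        frag <- substr(genome, pos, brk)
        if (nchar(frag) >= spec$frag_min || brk == glen) {
          node <- node + 1L
          if (stats::runif(1) < 0.5) frag <- revcomp_chr(frag)
          cov_r <- round(cov, 1)
          id <- sprintf("NODE_%d_length_%d_cov_%s", node, nchar(frag), format(cov_r))
          contig_rows[[length(contig_rows) + 1L]] <- tibble(
            contig_id = id, seq = frag, length = nchar(frag), coverage = cov_r
          )
          truth_rows[[length(truth_rows) + 1L]] <- tibble(
            contig_id = id, genome_id = gid,
            species_id = ref_db$genomes$species_id[
              ref_db$genomes$genome_id == gid
            ]
          )
        }
        pos <- brk + 1L
      }
    }
    n_real <- length(contig_rows)
    n_decoy <- as.integer(round(spec$decoy_fraction * n_real))
    for (d in seq_len(n_decoy)) {
      flen <- max(
        spec$frag_min,
        as.integer(round(stats::rnorm(1, spec$frag_mean, spec$frag_sd)))
      )
      node <- node + 1L
      cov_r <- round(stats::runif(1, 5, 30), 1)
      id <- sprintf("NODE_%d_length_%d_cov_%s", node, flen, format(cov_r))
      contig_rows[[length(contig_rows) + 1L]] <- tibble(
        contig_id = id, seq = random_dna(flen), length = flen, coverage = cov_r
      )
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        contig_id = id, genome_id = NA_character_, species_id = "DECOY"
      )
    }
    contigs <- bind_rows(contig_rows)
    truth <- bind_rows(truth_rows)
    ord <- sample.int(nrow(contigs))
    contigs <- contigs[ord, ]
    truth <- truth[match(contigs$contig_id, truth$contig_id), ]
    out <- list(contigs = contigs, truth = truth)
    attr(out, "manifest") <- list(
      generator = "simulate_sample", seed = spec$seed,
      species = spec$species, frag_mean = spec$frag_mean,
      frag_sd = spec$frag_sd, frag_min = spec$frag_min,
      decoy_fraction = spec$decoy_fraction,
      keep_seed_intact = spec$keep_seed_intact
    )
    out
  })
}

#' Write a simulated sample to disk
#'
#' Emits `contigs.fasta` (SPAdes-style headers), `truth.tsv`, a `refdb/`
#' directory in the reference-database formats and a `manifest.json`.
#'
#' @param sample Output of [simulate_sample()].
#' @param ref_db The `ref_db` it was simulated from.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_sample <- function(sample, ref_db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contigs(sample$contigs, file.path(dir, "contigs.fasta"))
  utils::write.table(sample$truth, file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_reference_db(ref_db, file.path(dir, "refdb"))
  manifest <- attr(sample, "manifest")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Score binning results against ground truth
#'
#' A binned contig is correct iff its bin's assigned reference species equals
#' the truth species. Precision is correct / binned; recall is correct /
#' total non-decoy contigs. With zero binned contigs precision is reported
#' as 1 (no false positives) with `no_binned = TRUE`. Base-weighted variants
#' weight every contig by its length.
#'
#' @param assignments Assignment tibble of a binning run.
#' @param bins Bin tibble (maps `bin_id` to `species_id`).
#' @param truth Truth tibble from [simulate_sample()].
#' @param contigs Contig tibble (lengths for base weighting).
#' @return List with `overall` (one-row tibble: contig- and base-weighted
#'   precision/recall/F1) and `per_bin` (per-bin precision tibble).
#' @export
score_binning <- function(assignments, bins, truth, contigs) {
  if (!setequal(assignments$contig_id, truth$contig_id)) {
    abort("assignments and truth must cover the same contig ids")
  }
  bin_species <- tibble(bin_id = bins$bin_id, bin_species = bins$species_id)
  d <- assignments |>
    left_join(truth, by = "contig_id") |>
    left_join(bin_species, by = "bin_id") |>
    left_join(contigs[, c("contig_id", "length")], by = "contig_id") |>
    mutate(
      binned = !is.na(.data$bin_id),
      correct = .data$binned & !is.na(.data$bin_species) &
        .data$species_id == .data$bin_species,
      non_decoy = .data$species_id != "DECOY"
    )
  weighted <- function(w) {
    n_binned <- sum(w * d$binned)
    n_correct <- sum(w * d$correct)
    n_total <- sum(w * d$non_decoy)
    precision <- if (n_binned == 0) 1 else n_correct / n_binned
    recall <- if (n_total == 0) 0 else n_correct / n_total
    f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, f1 = f1)
  }
  cw <- unname(weighted(rep(1, nrow(d))))
  bw <- unname(weighted(d$length))
  overall <- tibble(
    precision = cw[1], recall = cw[2], f1 = cw[3],
    base_precision = bw[1], base_recall = bw[2], base_f1 = bw[3],
    n_binned = sum(d$binned), n_correct = sum(d$correct),
    n_non_decoy = sum(d$non_decoy),
    no_binned = sum(d$binned) == 0
  )
  per_bin <- d |>
    filter(.data$binned) |>
    group_by(.data$bin_id) |>
    summarise(
      n_contigs = dplyr::n(),
      n_correct = sum(.data$correct),
      precision = mean(.data$correct),
      base_precision = sum(.data$length * .data$correct) / sum(.data$length),
      .groups = "drop"
    )
  list(overall = overall, per_bin = per_bin)
}
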