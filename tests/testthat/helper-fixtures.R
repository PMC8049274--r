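# Shared fixtures, built in code. All randomness is scoped with withr.

aa_alphabet <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

rand_protein <- function(len) {
  paste0(sample(aa_alphabet, len, replace = TRUE), collapse = "")
}

rand_dna <- function(len) {
  paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# deterministic back-translation wrapper (uses package internals via exports:
# encode through simulate machinery is overkill; draw codons here)
codon_tab <- local({
  gc <- Biostrings::getGeneticCode("11")
  gc <- gc[gc != "*"]
  split(names(gc), unname(gc))
})

encode_dna <- function(aa) {
  letters <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste0(vapply(letters, function(a) {
    cs <- codon_tab[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE), collapse = "")
}

mutate_aa <- function(aa, rate) {
  letters <- strsplit(aa, "", fixed = TRUE)[[1]]
  hit <- runif(length(letters)) < rate
  letters[hit] <- vapply(letters[hit], function(a) {
    sample(setdiff(aa_alphabet, a), 1L)
  }, character(1), USE.NAMES = FALSE)
  paste0(letters, collapse = "")
}

# A small hand-built reference database: 3 bacterial genomes, 8 roles of
# which 5 are universal markers (the seed role R001 among them).
tiny_ref_db <- function(seed = 101, n_genomes = 3, divergence = 0.3) {
  withr::with_seed(seed, {
    n_roles <- 8L
    role_id <- sprintf("R%03d", seq_len(n_roles))
    roles <- tibble::tibble(
      role_id = role_id,
      role_name = c(
        "Phenylalanyl-tRNA synthetase alpha chain (pheS)",
        paste0("test role ", 2:n_roles)
      ),
      is_marker_bacteria = seq_len(n_roles) <= 5,
      is_marker_archaea = seq_len(n_roles) <= 5
    )
    lens <- c(300L, rep(150L, n_roles - 1L))
    ancestral <- vapply(lens, rand_protein, character(1))
    gids <- sprintf("G%d", seq_len(n_genomes))
    genomes <- tibble::tibble(
      genome_id = gids,
      name = paste0("Testibacter sp. ", seq_len(n_genomes)),
      species_id = sprintf("S%d", seq_len(n_genomes)),
      species_name = paste0("Testibacter sp. ", seq_len(n_genomes)),
      domain = "Bacteria"
    )
    prot <- list()
    seeds <- list()
    for (g in seq_len(n_genomes)) {
      for (r in seq_len(n_roles)) {
        aa <- mutate_aa(ancestral[r], divergence)
        dna <- encode_dna(aa)
        prot[[length(prot) + 1L]] <- tibble::tibble(
          protein_id = sprintf("%s_P%03d", gids[g], r),
          genome_id = gids[g], role_id = role_id[r], aa = aa, dna = dna
        )
        if (r == 1L) seeds[[g]] <- tibble::tibble(genome_id = gids[g], aa = aa, dna = dna)
      }
    }
    prot <- dplyr::bind_rows(prot)
    db <- structure(
      list(
        genomes = genomes,
        proteins = prot[, c("protein_id", "genome_id", "role_id", "aa")],
        seeds = dplyr::bind_rows(seeds),
        roles = roles,
        seed_role_id = "R001",
        seed_policy = seed_length_policy()
      ),
      class = "ref_db"
    )
    attr(db, "gene_dna") <- prot[, c("protein_id", "genome_id", "role_id", "dna")]
    db
  })
}

# DNA of every gene of one genome, seed first (a "perfect" single-contig bin)
genome_dna <- function(db, gid) {
  gd <- attr(db, "gene_dna")
  gd <- gd[gd$genome_id == gid, ]
  seed_first <- order(gd$role_id != db$seed_role_id, gd$role_id)
  paste0(gd$dna[seed_first], collapse = "")
}

# a one-row bins tibble as produced by init/assign/merge
manual_bin <- function(bin_id, contig_ids, ref_ids, species_id,
                       seed_hits = NULL, similarity = 1) {
  tibble::tibble(
    bin_id = bin_id,
    contig_ids = list(contig_ids),
    seed_hits = list(seed_hits %||% tibble::tibble()),
    reference_genome_ids = list(ref_ids),
    species_id = species_id,
    ref_similarity = similarity,
    usable = TRUE,
    merged_from = list(character(0))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force discriminating-index oracle: k-mers occurring in exactly one
# bin's reference proteome
brute_disc_index <- function(bin_proteomes, k = 12) {
  sets <- lapply(bin_proteomes, function(aas) {
    unique(unlist(lapply(aas, aa_kmer_set, k = k), use.names = FALSE))
  })
  long <- data.frame(
    bin_id = rep(names(sets), lengths(sets)),
    kmer = unlist(sets, use.names = FALSE)
  )
  tab <- table(long$kmer)
  long[long$kmer %in% names(tab)[tab == 1L], c("kmer", "bin_id")]
}

make_contigs <- function(seqs, coverage = 10, prefix = "ctg") {
  tibble::tibble(
    contig_id = sprintf("%s%03d", prefix, seq_along(seqs)),
    seq = seqs,
    length = nchar(seqs),
    coverage = coverage
  )
}
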