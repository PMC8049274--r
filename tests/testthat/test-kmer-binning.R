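# helper: a minimal ref_db-like object + bins for index construction
index_fixture <- function(proteomes) {
  # proteomes: named list bin_id -> character vector of protein aa
  prot <- tibble::tibble(
    protein_id = sprintf("P%03d", seq_along(unlist(proteomes))),
    genome_id = rep(names(proteomes), lengths(proteomes)),
    role_id = "R999",
    aa = unlist(proteomes, use.names = FALSE)
  )
  bins <- dplyr::bind_rows(lapply(names(proteomes), function(b) {
    manual_bin(b, paste0("seedctg_", b), b, paste0("sp_", b))
  }))
  list(bins = bins, ref_db = list(proteins = prot))
}

test_that("discriminating index equals the brute-force unique-k-mer oracle", {
  withr::with_seed(51, {
    shared <- rand_protein(60)
    proteomes <- list(
      binA = c(rand_protein(150), shared),
      binB = c(rand_protein(150), shared),
      binC = rand_protein(120)
    )
  })
  fx <- index_fixture(proteomes)
  idx <- build_discriminating_index(fx$bins, fx$ref_db, k = 12)
  oracle <- brute_disc_index(proteomes, k = 12)
  expect_setequal(
    paste(idx$map$kmer, idx$map$bin_id),
    paste(oracle$kmer, oracle$bin_id)
  )
  # no k-mer of the verbatim-shared protein survives
  expect_false(any(aa_kmer_set(shared, 12) %in% idx$map$kmer))
  # no k-mer maps to two bins
  expect_false(anyDuplicated(idx$map$kmer) > 0)
})

test_that("disjoint proteomes keep every k-mer; a single bin keeps all (with warning)", {
  withr::with_seed(52, {
    pa <- rand_protein(100)
    pb <- rand_protein(100)
  })
  fx <- index_fixture(list(binA = pa, binB = pb))
  idx <- build_discriminating_index(fx$bins, fx$ref_db, k = 12)
  if (length(intersect(aa_kmer_set(pa, 12), aa_kmer_set(pb, 12))) == 0) {
    expect_setequal(idx$map$kmer, c(aa_kmer_set(pa, 12), aa_kmer_set(pb, 12)))
  }
  fx1 <- index_fixture(list(binA = pa))
  expect_warning(idx1 <- build_discriminating_index(fx1$bins, fx1$ref_db, k = 12), "single bin")
  expect_setequal(idx1$map$kmer, aa_kmer_set(pa, 12))
})

test_that("contigs are assigned by discriminating-hit counts with threshold and tie rules", {
  withr::with_seed(53, {
    pa <- rand_protein(400)
    pb <- rand_protein(400)
    fx <- index_fixture(list(binA = pa, binB = pb))
    idx <- build_discriminating_index(fx$bins, fx$ref_db, k = 12)

    # contig encoding a 40-aa window of A's protein: ~29 distinct A k-mers
    ca <- encode_dna(substr(pa, 1, 40))
    # contig encoding a 20-aa window: 9 distinct k-mers -> below threshold 10
    cb <- encode_dna(substr(pb, 101, 120))
    # random contig: no discriminating hits
    cn <- rand_dna(600)
    contigs <- make_contigs(c(ca, cb, cn))
  })
  asg <- assign_contigs(contigs, idx, fx$bins, min_hits = 10)
  expect_equal(asg$bin_id[1], "binA")
  expect_equal(asg$stage[1], "kmer")
  expect_gte(asg$best_count[1], 10)
  expect_true(is.na(asg$bin_id[2]))
  expect_equal(asg$reason[2], "below-threshold")
  expect_equal(asg$best_count[2], 9)
  expect_true(is.na(asg$bin_id[3]))
  expect_equal(asg$reason[3], "no-hits")
})

test_that("a tie at the argmax leaves the contig unbinned", {
  withr::with_seed(54, {
    pa <- rand_protein(100)
    pb <- rand_protein(100)
    fx <- index_fixture(list(binA = pa, binB = pb))
    idx <- build_discriminating_index(fx$bins, fx$ref_db, k = 12)
    # encode 23 aa of each protein back to back: 12 distinct k-mers per bin
    tie_contig <- paste0(encode_dna(substr(pa, 1, 23)), encode_dna(substr(pb, 1, 23)))
    asg <- assign_contigs(make_contigs(tie_contig), idx, fx$bins, min_hits = 10)
    expect_true(is.na(asg$bin_id[1]))
    expect_equal(asg$reason[1], "tie")
    expect_equal(asg$best_count[1], asg$runner_up_count[1])
  })
})

test_that("seed-bearing contigs stay pinned and assignment is order-invariant", {
  withr::with_seed(55, {
    pa <- rand_protein(300)
    pb <- rand_protein(300)
    fx <- index_fixture(list(binA = pa, binB = pb))
    idx <- build_discriminating_index(fx$bins, fx$ref_db, k = 12)
    contigs <- make_contigs(c(
      encode_dna(substr(pa, 1, 50)), encode_dna(substr(pb, 1, 50)), rand_dna(400)
    ))
    # pretend contig 1 carries a seed of binB: the pin wins over the k-mer signal
    fx$bins$contig_ids[[2]] <- c("seedctg_binB", contigs$contig_id[1])
  })
  asg <- assign_contigs(contigs, idx, fx$bins, min_hits = 10)
  expect_equal(asg$bin_id[asg$contig_id == contigs$contig_id[1]], "binB")
  expect_equal(asg$stage[asg$contig_id == contigs$contig_id[1]], "seed")
  # permuting contig order permutes rows, not decisions
  perm <- c(3, 1, 2)
  asg2 <- assign_contigs(contigs[perm, ], idx, fx$bins, min_hits = 10)
  expect_equal(
    asg2[order(asg2$contig_id), ]$bin_id,
    asg[order(asg$contig_id), ]$bin_id
  )
})

test_that("rescue index excludes multi-bin k-mers and canonicalizes strands", {
  withr::with_seed(56, {
    shared60 <- rand_dna(60)
    cA <- paste0(rand_dna(200), shared60, rand_dna(200))
    cB <- paste0(rand_dna(200), shared60, rand_dna(200))
    cC <- rand_dna(300)
  })
  contigs <- make_contigs(c(cA, cB, cC))
  asg <- tibble::tibble(
    contig_id = contigs$contig_id, bin_id = c("binA", "binB", "binA"),
    stage = "kmer", best_count = 10L, runner_up_count = 0L, reason = NA_character_
  )
  ridx <- build_rescue_index(contigs, asg, k = 50)
  # the 50-mers of the shared 60 bp segment are absent
  expect_false(any(dna_canonical_kmers(shared60, 50) %in% ridx$map$kmer))
  # a single binned contig's k-mers are all present
  expect_true(all(dna_canonical_kmers(cC, 50) %in% ridx$map$kmer))
  # canonical form: the index never stores a k-mer and its reverse complement
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(ridx$map$kmer)))
  expect_false(any(rc %in% ridx$map$kmer & rc != ridx$map$kmer))
})

test_that("rescue assigns single-bin exact matches of >= 50 bp and nothing else", {
  withr::with_seed(57, {
    uniqA <- rand_dna(70)
    uniqB <- rand_dna(70)
    cA <- paste0(rand_dna(150), uniqA, rand_dna(150))
    cB <- paste0(rand_dna(150), uniqB, rand_dna(150))
    # unbinned contigs: 50 bp from A only; 49 bp from A; 50 bp from each of A and B
    uA <- paste0(rand_dna(400), substr(uniqA, 1, 50))
    u49 <- paste0(rand_dna(400), substr(uniqA, 1, 49))
    uAB <- paste0(rand_dna(200), substr(uniqA, 1, 50), rand_dna(100), substr(uniqB, 1, 50))
  })
  contigs <- make_contigs(c(cA, cB, uA, u49, uAB))
  asg <- dplyr::bind_rows(
    tibble::tibble(
      contig_id = contigs$contig_id[1:2], bin_id = c("binA", "binB"),
      stage = "kmer", best_count = 10L, runner_up_count = 0L, reason = NA_character_
    ),
    seedbin:::unbinned_assignment(contigs$contig_id[3:5], "below-threshold")
  )
  ridx <- build_rescue_index(contigs, asg, k = 50)
  out <- rescue_contigs(contigs, asg, ridx)
  expect_equal(out$bin_id[3], "binA")
  expect_equal(out$stage[3], "rescue")
  expect_true(is.na(out$bin_id[4])) # 49 bp is below the exact-match length
  expect_true(is.na(out$bin_id[5])) # hits two bins -> stays unbinned
  # brute-force check of the multi-bin case
  kmAB <- dna_canonical_kmers(contigs$seq[5], 50)
  hit_bins <- unique(ridx$map$bin_id[match(kmAB, ridx$map$kmer)])
  expect_setequal(hit_bins[!is.na(hit_bins)], c("binA", "binB"))
  # rescue only adds assignments, never removes
  expect_true(all(which(!is.na(asg$bin_id)) %in% which(!is.na(out$bin_id))))
})
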