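counts_tbl <- function(...) {
  x <- c(...)
  tibble::tibble(role_id = names(x), n = as.integer(x))
}

pred_tbl <- function(...) {
  x <- c(...)
  tibble::tibble(role_id = names(x), expected = as.integer(x))
}

test_that("completeness and contamination follow their marker-count definitions", {
  mk <- paste0("m", 1:5)
  rc <- counts_tbl(m1 = 1, m2 = 2, m3 = 0, m4 = 1, m5 = 1)
  expect_equal(completeness(rc, mk), 80)
  expect_equal(contamination(rc, mk), 20)
  expect_equal(completeness(counts_tbl(m1 = 1, m2 = 1, m3 = 1, m4 = 1, m5 = 1), mk), 100)
  expect_equal(contamination(counts_tbl(m1 = 1, m2 = 1, m3 = 1, m4 = 1, m5 = 1), mk), 0)
  expect_equal(completeness(tibble::tibble(role_id = character(0), n = integer(0)), mk), 0)
  expect_equal(contamination(counts_tbl(m1 = 2, m2 = 2, m3 = 2, m4 = 2, m5 = 2), mk), 100)
  expect_error(completeness(rc, character(0)), "empty marker set")
  expect_error(contamination(rc, character(0)), "empty marker set")
})

test_that("fine and coarse consistency compare observed to expected counts", {
  pred <- pred_tbl(r1 = 1, r2 = 1, r3 = 2, r4 = 1, r5 = 1, r6 = 1, r7 = 1, r8 = 1, r9 = 1, r10 = 1)
  obs_perfect <- counts_tbl(r1 = 1, r2 = 1, r3 = 2, r4 = 1, r5 = 1, r6 = 1, r7 = 1, r8 = 1, r9 = 1, r10 = 1)
  expect_equal(fine_consistency(obs_perfect, pred), 100)
  obs1 <- obs_perfect
  obs1$n[3] <- 1L # one mismatch out of 10 predictable roles
  expect_equal(fine_consistency(obs1, pred), 90)
  expect_equal(fine_consistency(tibble::tibble(role_id = character(0), n = integer(0)), pred), 0)
  # presence/absence: observed 2 where expected 1 still agrees coarsely
  expect_equal(coarse_consistency(counts_tbl(r1 = 2), pred_tbl(r1 = 1)), 100)
  expect_equal(coarse_consistency(counts_tbl(r1 = 0), pred_tbl(r1 = 1)), 0)
  expect_error(fine_consistency(obs1, pred_tbl()), "empty predictable")
})

test_that("fine consistency never exceeds coarse consistency", {
  withr::with_seed(61, {
    for (i in 1:50) {
      roles <- paste0("r", 1:8)
      pred <- tibble::tibble(role_id = roles, expected = sample(0:2, 8, TRUE))
      obs <- tibble::tibble(role_id = roles, n = sample(0:3, 8, TRUE))
      expect_lte(fine_consistency(obs, pred), coarse_consistency(obs, pred))
    }
  })
})

test_that("with the baseline predictor, fine consistency is the single-copy fraction", {
  db <- tiny_ref_db()
  pred <- baseline_predictor(db, "Bacteria")
  expect_equal(sort(pred$role_id), sort(marker_roles(db, "Bacteria")))
  expect_true(all(pred$expected == 1L))
  withr::with_seed(62, {
    for (i in 1:30) {
      mk <- pred$role_id
      obs <- tibble::tibble(role_id = mk, n = sample(0:3, length(mk), TRUE))
      fine <- fine_consistency(obs, pred)
      # identity over markers: fine = 100 - contamination - (100 - completeness)
      expect_equal(
        fine,
        100 - contamination(obs, mk) - (100 - completeness(obs, mk))
      )
      expect_equal(fine, 100 * mean(obs$n == 1L))
    }
  })
})

test_that("role projection finds planted genes with the right similarity", {
  db <- tiny_ref_db()
  gd <- attr(db, "gene_dna")
  gene <- gd[gd$genome_id == "G1" & gd$role_id == "R003", ]
  bin <- manual_bin("bin_001", "c1", "G1", "S1")
  withr::with_seed(63, {
    contig <- paste0(rand_dna(90), gene$dna, rand_dna(90))
    two_copies <- make_contigs(c(contig, paste0(rand_dna(30), gene$dna, rand_dna(30))))
  })
  occ <- annotate_bin(bin, make_contigs(contig), db)
  r3 <- occ[occ$role_id == "R003", ]
  expect_equal(nrow(r3), 1)
  expect_equal(r3$similarity, 1.0)
  # the same gene on two contigs gives two occurrences of the role
  occ2 <- annotate_bin(bin, two_copies, db)
  expect_equal(nrow(occ2[occ2$role_id == "R003", ]), 2)
})

test_that("heavily mutated genes below the k-mer fraction are not called", {
  db <- tiny_ref_db()
  prot <- db$proteins[db$proteins$genome_id == "G1" & db$proteins$role_id == "R004", ]
  withr::with_seed(64, {
    mut <- mutate_aa(prot$aa, 0.15)
    contig <- paste0(rand_dna(60), encode_dna(mut), rand_dna(60))
  })
  # oracle: fraction of the reference protein's 12-mers retained in the mutant
  frac <- length(intersect(aa_kmer_set(prot$aa, 12), aa_kmer_set(mut, 12))) /
    length(aa_kmer_set(prot$aa, 12))
  expect_lt(frac, 0.5)
  occ <- annotate_bin(manual_bin("b", "c1", "G1", "S1"), make_contigs(contig), db)
  expect_false("R004" %in% occ$role_id)
})

test_that("the seed-gene check enforces single copy and length policy", {
  occ1 <- tibble::tibble(
    bin_id = "b", contig_id = "c1", role_id = "R001",
    start = 0L, end = 900L, strand = "+", similarity = 1, good = NA
  )
  chk <- check_seed_gene(occ1, "Bacteria", "R001")
  expect_equal(chk$seed_count, 1)
  expect_true(chk$seed_length_ok) # 900 nt -> 300 aa, inside [209, 405]
  chk2 <- check_seed_gene(dplyr::bind_rows(occ1, occ1), "Bacteria", "R001")
  expect_equal(chk2$seed_count, 2)
  expect_false(chk2$seed_length_ok)
  occ_long <- occ1
  occ_long$end <- 3L * 406L # 406 aa: just above the bacterial range
  expect_false(check_seed_gene(occ_long, "Bacteria", "R001")$seed_length_ok)
  # the same length is acceptable for Archaea
  expect_true(check_seed_gene(occ_long, "Archaea", "R001")$seed_length_ok)
})

test_that("high-quality classification is inclusive at every boundary", {
  good <- classify_bin_quality(80.0, 10.0, 87.0, 1L, TRUE)
  expect_equal(good$verdict, "good")
  expect_length(good$failing, 0)
  poor <- classify_bin_quality(100, 10.1, 100, 1L, TRUE)
  expect_equal(poor$verdict, "poor")
  expect_equal(poor$failing, "contamination")
  seedless <- classify_bin_quality(100, 0, 100, 0L, FALSE)
  expect_equal(seedless$verdict, "poor")
  expect_equal(seedless$failing, "seed")
  multi <- classify_bin_quality(79.9, 10.1, 86.9, 2L, FALSE)
  expect_setequal(multi$failing, c("contamination", "fine_consistency", "completeness", "seed"))
})

test_that("bin statistics follow the N50 and length-weighted definitions", {
  ct <- tibble::tibble(
    contig_id = c("a", "b", "c"), length = c(10L, 10L, 30L), coverage = c(1, 1, 1)
  )
  st <- bin_stats(ct)
  expect_equal(st$n50, 30)
  expect_equal(st$dna_size, 50)
  expect_equal(st$contig_count, 3)
  single <- bin_stats(tibble::tibble(contig_id = "a", length = 1234L, coverage = 2))
  expect_equal(single$n50, 1234)
  wc <- bin_stats(tibble::tibble(
    contig_id = c("a", "b"), length = c(100L, 300L), coverage = c(10, 2)
  ))
  expect_equal(wc$mean_coverage, 4.0)
  expect_error(bin_stats(ct[0, ]), "empty bin")
})

test_that("good-occurrence marking keeps the top expected occurrences per role", {
  occ <- tibble::tibble(
    bin_id = "b", contig_id = c("c2", "c1"), role_id = "r1",
    start = c(0L, 0L), end = c(100L, 100L), strand = "+",
    similarity = c(0.9, 0.6), good = NA
  )
  m <- mark_good_occurrences(occ, pred_tbl(r1 = 1))
  expect_true(m$good[m$similarity == 0.9])
  expect_false(m$good[m$similarity == 0.6])
  # observed <= expected: all good
  m2 <- mark_good_occurrences(occ, pred_tbl(r1 = 2))
  expect_true(all(m2$good))
  # tie at equal similarity: lexicographically earlier contig wins
  occ_tie <- occ
  occ_tie$similarity <- c(0.8, 0.8)
  m3 <- mark_good_occurrences(occ_tie, pred_tbl(r1 = 1))
  expect_true(m3$good[m3$contig_id == "c1"])
  expect_false(m3$good[m3$contig_id == "c2"])
  # roles outside the predictable set: no evidence against them
  m4 <- mark_good_occurrences(occ, pred_tbl(other = 1))
  expect_true(all(m4$good))
})

test_that("postprocessing prunes only all-bad annotated contigs above the threshold", {
  occ <- tibble::tibble(
    bin_id = "b",
    contig_id = c("keep1", "keep1", "bad1", "mixed", "mixed"),
    role_id = c("r1", "r2", "r1", "r3", "r4"),
    start = 0L, end = 100L, strand = "+",
    similarity = c(0.9, 0.9, 0.5, 0.9, 0.4),
    good = c(TRUE, TRUE, FALSE, TRUE, FALSE)
  )
  members <- c("keep1", "bad1", "mixed", "noann", "seedctg")
  # below the threshold: unchanged
  pp <- postprocess_bin(members, "seedctg", occ, contamination = 8)
  expect_equal(pp$keep, members)
  # above: only 'bad1' (annotated, all not-good) goes; zero-occurrence and
  # seed contigs stay
  pp2 <- postprocess_bin(members, "seedctg", occ, contamination = 20)
  expect_equal(pp2$removed, "bad1")
  expect_setequal(pp2$keep, c("keep1", "mixed", "noann", "seedctg"))
  # a seed contig is never removed even if all its occurrences are bad
  occ_seed <- occ
  occ_seed$contig_id[occ_seed$contig_id == "bad1"] <- "seedctg"
  pp3 <- postprocess_bin(members, "seedctg", occ_seed, contamination = 20)
  expect_equal(pp3$removed, character(0))
})

test_that("pruning a planted duplicate marker reduces recomputed contamination", {
  db <- tiny_ref_db()
  gd <- attr(db, "gene_dna")
  g1 <- gd[gd$genome_id == "G1", ]
  # bin = full genome on one contig + a rogue contig carrying dup copies of
  # two markers (enough to push contamination over 10%: 2/5 markers doubled)
  withr::with_seed(65, {
    genome_ctg <- genome_dna(db, "G1")
    rogue <- paste0(
      rand_dna(50), g1$dna[g1$role_id == "R002"], rand_dna(20),
      g1$dna[g1$role_id == "R003"], rand_dna(50)
    )
  })
  contigs <- tibble::tibble(
    contig_id = c("main", "rogue"),
    seq = c(genome_ctg, rogue),
    length = nchar(c(genome_ctg, rogue)),
    coverage = 10
  )
  bin <- manual_bin("bin_001", "main", "G1", "S1")
  asg <- tibble::tibble(
    contig_id = c("main", "rogue"), bin_id = "bin_001",
    stage = c("seed", "kmer"), best_count = NA_integer_,
    runner_up_count = NA_integer_, reason = NA_character_
  )
  cfg <- binning_config()
  ev <- seedbin:::evaluate_bins(bin, asg, contigs, db, cfg)
  m <- ev$metrics
  # the duplicate-bearing contig was pruned and contamination fell to 0
  expect_equal(unlist(m$pruned_contigs), "rogue")
  expect_equal(m$contamination, 0)
  expect_equal(m$completeness, 100)
  expect_equal(m$verdict, "good")
  expect_true(is.na(ev$assignments$bin_id[ev$assignments$contig_id == "rogue"]))
  expect_equal(ev$assignments$reason[ev$assignments$contig_id == "rogue"], "pruned")
})

test_that("problematic-role rows cover exactly the observed/expected disagreements", {
  pred <- pred_tbl(m1 = 1, m2 = 1, m3 = 1)
  perfect <- counts_tbl(m1 = 1, m2 = 1, m3 = 1)
  expect_equal(nrow(problematic_roles(perfect, pred, paste0("m", 1:3), paste0("m", 1:3))), 0)
  obs <- counts_tbl(m1 = 1, m2 = 2, m3 = 0)
  pr <- problematic_roles(obs, pred, paste0("m", 1:3), c("m1", "m2", "m3"))
  expect_equal(pr$role_id, c("m2", "m3"))
  expect_equal(pr$observed, c(2L, 0L))
  expect_equal(pr$expected, c(1L, 1L))
  expect_true(all(pr$universal))
  expect_true(all(pr$in_reference))
})

test_that("an unmutated reference genome annotates to a perfect good bin", {
  db <- tiny_ref_db()
  genome_ctg <- genome_dna(db, "G2")
  contigs <- tibble::tibble(
    contig_id = "whole", seq = genome_ctg,
    length = nchar(genome_ctg), coverage = 20
  )
  bin <- manual_bin("bin_001", "whole", "G2", "S2")
  asg <- tibble::tibble(
    contig_id = "whole", bin_id = "bin_001", stage = "seed",
    best_count = NA_integer_, runner_up_count = NA_integer_,
    reason = NA_character_
  )
  ev <- seedbin:::evaluate_bins(bin, asg, contigs, db, binning_config())
  m <- ev$metrics
  expect_equal(m$completeness, 100)
  expect_equal(m$contamination, 0)
  expect_equal(m$fine_consistency, 100)
  expect_equal(m$seed_count, 1L)
  expect_true(m$seed_length_ok)
  expect_equal(m$verdict, "good")
})
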