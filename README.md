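# seedbin

Supervised metagenome binning for assembled contigs: extract putative draft
genomes (MAGs) by similarity to reference genomes, anchored on a single-copy
universal seed protein.

## The problem and the method

Unsupervised binners group contigs by intrinsic signals (composition,
coverage covariation). seedbin instead takes a curated reference collection
and sorts contigs by explicit similarity to it — the approach behind
reference-database binning services, rebuilt here as a standalone,
fully-testable R package with a bundled synthetic-community generator, so
every stage runs without any external database or network access.

The pipeline, for a sample of contigs `C` and references `G1..Gm`:

1. **QC** — split contigs at runs of ≥ 50 ambiguous bases, drop fragments
   < 400 bp.
2. **Initialize bins** — find every occurrence of the seed protein (a
   pheS-like phenylalanyl-tRNA synthetase alpha chain) by translated local
   alignment; keep hits covering ≥ 2/3 of the seed on contigs with ≥ 4-fold
   coverage and ≥ 400 bp. One bin per seed-bearing contig.
3. **Assign references** — for each bin, the reference genome maximising the
   Jaccard similarity `J(A,B) = |K8(A) ∩ K8(B)| / |K8(A) ∪ K8(B)]` of
   amino-acid 8-mer sets of the seed sequences; bins whose references share
   a species merge.
4. **Bin contigs** — build the sample-specific index of *discriminating
   protein 12-mers* (12-mers occurring in exactly one bin's reference
   proteomes); assign each remaining contig to the bin with the most
   distinct discriminating 12-mers among its six-frame translations, iff
   that count is ≥ 10 and the argmax is unique.
5. **Rescue** — an unbinned contig sharing an exact DNA stretch of ≥ 50 bp
   (either strand) with contigs of exactly one bin joins that bin.
6. **Evaluate & postprocess** — per bin: completeness (% marker roles seen
   ≥ once), contamination (% seen > once), fine/coarse consistency against a
   copy-number predictor, N50, coverage; *high-quality* iff contamination
   ≤ 10, fine consistency ≥ 87, completeness ≥ 80 and exactly one seed gene
   of plausible length. Bins over 10% contamination are pruned of contigs
   that carry only contradicted annotations.

Outputs are a structured HTML report, a machine-readable `report.json`
(schema shipped in `inst/schema/`), per-bin FASTA files, per-bin
problematic-role reports and an assignment table.

## Worked example

```r
library(seedbin)
library(tibble)

db <- simulate_reference_db(n_genomes = 4, n_roles = 30, seed = 42)
spec <- community_spec(
  species = tibble(
    genome_id = c("G001", "G002", "G003"),
    divergence = 0.01, coverage = c(12, 20, 8)
  ),
  seed = 7
)
s <- simulate_sample(db, spec)

res <- bin_metagenome(s$contigs, db)
glance(res)
#> # A tibble: 1 × 9
#>   n_contigs_in n_contigs_qc n_bins n_good_bins n_binned n_seed n_kmer n_rescued
#>          <int>        <int>  <int>       <int>    <int>  <int>  <int>     <int>
#> 1           46           46      3           3       44      3     41         0
#> # ℹ 1 more variable: frac_binned <dbl>

score_binning(res$assignments, res$bins, s$truth, res$contigs)$overall[, 1:3]
#> # A tibble: 1 × 3
#>   precision recall    f1
#>       <dbl>  <dbl> <dbl>
#> 1         1      1     1
```

All 46 simulated contigs pass QC; three bins are initialized (one per
planted species), each recovers its true reference, 44 of 46 contigs are
binned (the 2 random-DNA decoys stay unbinned), every assignment matches
the ground truth, and all three bins meet the high-quality cutoffs.
`tidy(res)` gives the per-bin metric table and `autoplot(res)` plots
completeness against contamination with the cutoffs drawn in.

To write a full run directory (report, FASTAs, logs):

```r
run_pipeline("contigs.fasta", "refdb/", "out/")
```

A thin command-line wrapper with `simulate`, `bin` and `evaluate`
subcommands is installed at `inst/scripts/seedbin.R`.

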