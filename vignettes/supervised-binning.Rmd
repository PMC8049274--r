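---
title: "Supervised metagenome binning with seed proteins and discriminating k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised metagenome binning with seed proteins and discriminating k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedbin)
library(tibble)
```

## The method

seedbin implements a reference-guided (supervised) binning procedure for
assembled metagenomic contigs. Instead of clustering contigs by intrinsic
signals (tetranucleotide frequency, GC, coverage covariation), it sorts them
by similarity to a collection of reference genomes, selected per sample by a
single-copy universal marker protein. The pipeline has six stages:

1. **Contig quality control.** Contigs are upper-cased, split at runs of 50
   or more ambiguous bases (the run is removed, fragments inherit the parent
   coverage), and fragments under 400 bp are dropped.
2. **Bin initialization.** All occurrences of the seed protein — a
   pheS-like phenylalanyl-tRNA synthetase alpha chain, chosen because it is
   long enough (209–405 residues in Bacteria, 293–652 in Archaea) to resolve
   species yet conserved enough to find distant relatives — are located by
   translated local alignment of the contigs against the seed database.
   A hit is kept only if it covers at least two-thirds of the seed, lies on
   a contig with at least 4-fold coverage, and the contig is at least 400 bp.
   Each seed-bearing contig founds one provisional bin, so the number of
   bins estimates the number of sufficiently covered species.
3. **Reference assignment.** Each bin's translated seed is compared with
   every reference seed by the Jaccard similarity of their distinct
   amino-acid 8-mer sets; the closest reference genome (ties broken by
   lexicographically smallest genome id) and its species are assigned. Bins
   whose references share a species are merged.
4. **Contig sorting.** A sample-specific index of *discriminating protein
   12-mers* is built: every distinct 12-mer of a bin's reference proteomes
   that occurs in no other bin's references. Contigs are projected into
   protein k-mer space by six-frame translation (table 11; stop codons break
   the peptide) and assigned to the bin with the most distinct
   discriminating 12-mers, provided the count is at least 10 and the argmax
   is unique — a tie means the evidence is contradictory and the contig
   stays unbinned.
5. **Rescue.** Unbinned contigs containing an exact DNA match of at least
   50 bp (canonical k-mer on either strand) to exactly one binned contig
   join that bin; matches to two or more bins disqualify. Rescue is a single
   pass.
6. **Evaluation and postprocessing.** Each bin is annotated by projecting
   its reference proteins onto its contigs (at least half of a protein's
   distinct 12-mers on one contig calls an occurrence of its role), and
   scored: **completeness** (percent of the domain's universal marker roles
   observed at least once), **contamination** (percent observed more than
   once), **fine consistency** (percent of predictable roles whose observed
   count equals the predicted count exactly) and **coarse consistency**
   (presence/absence agreement). A bin is *high-quality* iff contamination
   ≤ 10, fine consistency ≥ 87, completeness ≥ 80 and it has exactly one
   seed gene of appropriate length — all boundaries inclusive. Bins above
   10% contamination are pruned: contigs all of whose role occurrences are
   flagged as worse duplicates ("not good") are discarded, and metrics are
   recomputed once.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `min_contig_len` | 400 | bp | QC and seed-hit floor |
| `max_ambig_run` | 50 | bp | ambiguity-run split length |
| `min_seed_cov` | 2/3 | fraction | seed-hit coverage of the seed sequence |
| `min_contig_cov` | 4 | fold | coverage floor for seed-bearing contigs |
| `seed_sim_k` | 8 | residues | seed-similarity k-mer length |
| `disc_k` | 12 | residues | discriminating k-mer length |
| `min_disc_hits` | 10 | k-mers | assignment threshold |
| `rescue_k` | 50 | bp | exact-match rescue length |
| `contamination_max` / `fine_min` / `completeness_min` | 10 / 87 / 80 | % | high-quality cutoffs |
| `min_role_kmer_frac` | 0.5 | fraction | annotator occurrence threshold |

The `max_ambig_run` value is a package choice: runs of 50 bp were picked
because 50 bp is also the exact-match length used elsewhere in the pipeline,
and shorter runs are harmless to every k-mer stage (k-mers containing
ambiguous letters never match). Whether a contig with a long ambiguity run
should be split or discarded whole was genuinely open; splitting retains
more sequence and cannot create false joins.

Two further choices deserve a note. Reference assignment operates on
amino-acid 8-mers throughout, because that is the similarity with a defined
formula; a DNA-level comparison would be strictly less robust to synonymous
divergence. And per-contig discriminating hits are counted as *distinct*
k-mers (set intersection), so a repeated peptide cannot vote twice.

## The annotator and predictor are contracts

Production annotation pipelines call genes and assign curated functional
roles; copy-number expectations come from trained per-role predictors. Both
are replaced here by deliberately simple, pluggable components:

* the **k-mer projection annotator** (`annotate_bin()`) calls a role
  occurrence where at least half of a reference protein's distinct 12-mers
  land on one contig;
* the **baseline predictor** (`baseline_predictor()`) expects every
  universal marker role exactly once, so fine consistency reduces to the
  fraction of markers observed exactly once.

Any function with the same signature can drop in. The quality *metrics*
themselves are exact; what varies with the plugin is which occurrences and
expectations feed them.

## What the synthetic generator emulates — and what it does not

`simulate_reference_db()` draws one random ancestral protein per role and
derives each genome by substituting amino acids at rate 0.25 (so two genomes
differ at roughly 40% of positions — comfortably above the ≥20%
inter-species divergence the binning experiments assume), then encodes each
protein with random synonymous codons. The seed protein is drawn at 250–360
residues, inside the bacterial length policy. `simulate_sample()`
concatenates a genome's genes (seed first), applies codon-level amino-acid
substitutions at the community member's divergence rate (untouched codons
keep the reference DNA, so zero divergence yields exact substrings),
fragments the genome into contigs of roughly N(2000, 500) bp truncated at
1000 bp, reverse-complements half of them, embeds the coverage in
SPAdes-style headers, and adds 5% random-DNA decoys. All generators are
deterministic under their seed and record a manifest.

By default fragment breakpoints falling inside the seed gene are moved to
its end (`keep_seed_intact = TRUE`). This emulates assemblies in which the
single-copy marker locus is contiguous — the method *presupposes* a seed hit
covering two-thirds of the seed on one contig, so a breakpoint mid-seed
models assembly failure, not binning behaviour. Disable it to study exactly
that failure mode.

The generator does **not** emulate: intergenic sequence, operon structure or
strand mixture within a genome; repeats and chimeric contigs; coverage
variation along a genome; indels (substitution-only by default, since every
signal in the pipeline is substitution-sensitive already); or realistic
amino-acid composition and codon bias. Passing tests on synthetic data
therefore demonstrate the correctness of the algorithmic machinery under
known truth, not performance on real assemblies.

## Numerical choices and degenerate inputs

* Every tie is broken deterministically (lexicographic genome ids, contig
  ids, interval starts), so identical inputs give byte-identical reports.
* Coordinates are stored 0-based half-open; external 1-based inclusive hit
  tables are converted on import.
* Seed search aligns with a Smith–Waterman (BLOSUM62, gap open 10, extend
  0.5) after an 8-mer prescreen: only frames sharing at least one 8-mer with
  a seed are aligned. At the divergences where a hit can still satisfy the
  two-thirds-coverage filter, many 8-mers survive, so the prescreen does not
  change results; it only avoids aligning the vast majority of irrelevant
  contig/seed pairs.
* No identity floor is applied to seed hits beyond the coverage fraction —
  the coverage rule is the only alignment filter.
* Zero seed hits yield zero bins and a valid, explicitly empty report. A
  single bin makes every reference k-mer discriminating (warned, but
  legitimate). An empty marker set makes completeness/contamination
  undefined and is an error rather than a silent 0.
* Contigs with *no* detected role occurrence are retained during
  contamination pruning: the pruning rule targets contigs whose annotations
  are contradicted, and discarding annotation-free contigs would gut
  completeness under a sparse annotator.

## A worked run

```{r run, eval = FALSE}
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
tidy(res)      # one row per bin: metrics and verdict
glance(res)    # one-row run summary
autoplot(res)  # completeness vs contamination
score_binning(res$assignments, res$bins, s$truth, res$contigs)$overall
```

Problem sizes throughout the package's tests are deliberately modest —
reference collections of 3–6 genomes with 25–40 roles and communities of
one to five species (tens of contigs, genomes of a few tens of kilobases).
These sizes already exercise every code path, including merging, rescue and
pruning, and keep the whole suite reproducible in minutes on one core.

## Known limitations

* **Fragmentation lowers apparent quality.** A marker gene split across two
  contigs so that neither side carries half of its 12-mers is not called,
  costing completeness *and* fine consistency. With ~300-residue genes and
  2 kb fragments this loses a percent or two of markers per bin; bins can
  drop below the fine-consistency cutoff purely through unlucky
  breakpoints. This is a property of the per-contig annotator floor, not of
  the binning itself; a gene-calling annotator plugged into the same
  contract would recover these markers.
* Same-contig tandem duplications of a role are collapsed into one
  occurrence; only duplications on separate loci or contigs register as
  contamination.
* The supervised premise stands or falls with the reference collection: a
  community member whose nearest reference seed shares no 8-mer is flagged
  "no usable reference" and its contigs can at best be rescued.
* Rescue is single-pass by design; it cannot chain through contigs it has
  itself rescued.
* Eukaryotic, viral and plasmid sequence is out of scope, as is abundance
  estimation: coverage is parsed and reported but never used as a
  clustering signal.
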