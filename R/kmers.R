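# k-mer primitives: protein k-mer sets, six-frame projection of DNA into
# protein k-mer space, and canonical DNA k-mers. These are the signals the
# whole binning method runs on.

#' Distinct amino-acid k-mers of a protein sequence
#'
#' Enumerates the distinct k-mers of an amino-acid string. K-mers containing
#' `X` (unknown residue; ambiguous letters are mapped to `X` on load) or `*`
#' (stop) are excluded, so a k-mer never spans a stop codon and ambiguous
#' residues never match anything.
#'
#' @param aa Amino-acid sequence (single string).
#' @param k K-mer length in residues.
#' @return Character vector of distinct k-mers (possibly empty).
#' @export
aa_kmer_set <- function(aa, k) {
  if (is.na(aa)) return(character(0))
  n <- nchar(aa)
  if (n < k) return(character(0))
  i <- seq_len(n - k + 1L)
  km <- substring(aa, i, i + k - 1L)
  unique(km[!grepl("[X*]", km)])
}

#' Jaccard similarity between the k-mer sets of two protein sequences
#'
#' The seed-protein similarity metric: the Jaccard index between the sets of
#' distinct amino-acid k-mers (default 8-mers) of two sequences. K-mers
#' containing `X` or `*` are excluded from both sets. If either sequence is
#' shorter than `k` (empty k-mer set), the similarity is 0.
#'
#' @param seq_a,seq_b Amino-acid sequences.
#' @param k K-mer length (default 8 residues).
#' @return A number in `[0, 1]`.
#' @examples
#' kmer_jaccard("MKTAYIAKQR", "MKTAYIAKQW") # 0.5
#' @export
kmer_jaccard <- function(seq_a, seq_b, k = 8) {
  a <- aa_kmer_set(seq_a, k)
  b <- aa_kmer_set(seq_b, k)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Translate one reading frame with a plain codon lookup (translation
# table 11; the amino-acid map of table 11 coincides with the standard code,
# start-codon rules do not apply here). Codons containing ambiguous bases
# translate to X; stops stay "*" and are excluded at k-mer extraction.
translate_frame <- function(seq, offset) {
  n <- nchar(seq) - offset
  n <- n - n %% 3L
  if (n < 3L) return("")
  if (is.null(.sb$codon_names)) {
    gc <- genetic_code_11()
    .sb$codon_names <- names(gc)
    .sb$codon_aas <- unname(gc)
  }
  starts <- seq.int(offset + 1L, offset + n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- .sb$codon_aas[match(codons, .sb$codon_names)]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Reverse complement of a single DNA string (base R; fast).
revcomp_one <- function(seq) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTNRYSWKMBDHVacgtn", "TGCANYRSWMKVHDBTGCAN", seq))))
}

# Translations of all six reading frames under the bacterial/archaeal genetic
# code. Returns a tibble with one row per frame: strand ("+"/"-"),
# offset (0..2) and the translation.
six_frame_translations <- function(seq) {
  seq <- toupper(seq)
  rc <- revcomp_one(seq)
  rows <- vector("list", 6L)
  i <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (off in 0:2) {
      i <- i + 1L
      rows[[i]] <- tibble(strand = strand, offset = off, aa = translate_frame(s, off))
    }
  }
  bind_rows(rows)
}

#' Protein k-mers of a DNA sequence via six-frame translation
#'
#' Projects a DNA contig into protein k-mer space: all six reading frames are
#' translated with the bacterial/archaeal genetic code (table 11), and the
#' distinct amino-acid k-mers are collected. Stop codons break the peptide (no
#' k-mer spans a stop) and k-mers containing `X` are excluded. A contig
#' shorter than `3 * k` nucleotides yields an empty set.
#'
#' @param seq DNA sequence (single string).
#' @param k K-mer length in residues (default 12).
#' @return Character vector of distinct protein k-mers.
#' @export
six_frame_kmers <- function(seq, k = 12) {
  if (nchar(seq) < 3L * k) return(character(0))
  tr <- six_frame_translations(seq)
  unique(unlist(lapply(tr$aa, aa_kmer_set, k = k), use.names = FALSE))
}

# Six-frame protein k-mers with their nucleotide footprint on the contig.
# Coordinates are 0-based half-open on the forward strand of the input.
six_frame_kmer_table <- function(seq, k = 12) {
  L <- nchar(seq)
  if (L < 3L * k) {
    return(tibble(
      kmer = character(0), strand = character(0),
      start = integer(0), end = integer(0)
    ))
  }
  tr <- six_frame_translations(seq)
  rows <- pmap(tr, function(strand, offset, aa) {
    na <- nchar(aa)
    if (na < k) return(NULL)
    j <- seq_len(na - k + 1L)
    km <- substring(aa, j, j + k - 1L)
    ok <- !grepl("[X*]", km)
    if (!any(ok)) return(NULL)
    j <- j[ok]
    km <- km[ok]
    if (strand == "+") {
      start <- offset + 3L * (j - 1L)
      end <- start + 3L * k
    } else {
      end <- L - (offset + 3L * (j - 1L))
      start <- end - 3L * k
    }
    tibble(kmer = km, strand = strand, start = as.integer(start), end = as.integer(end))
  })
  bind_rows(rows)
}

# Reverse complement for plain character DNA (vectorized).
revcomp_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical DNA k-mers of a sequence
#'
#' Distinct DNA k-mers in canonical form: each k-mer is represented by the
#' lexicographically smaller of itself and its reverse complement, so both
#' strands share one representation. K-mers containing ambiguous bases are
#' excluded.
#'
#' @param seq DNA sequence (single string).
#' @param k K-mer length in base pairs (default 50).
#' @return Character vector of distinct canonical k-mers.
#' @export
dna_canonical_kmers <- function(seq, k = 50) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  i <- seq_len(n - k + 1L)
  km <- substring(seq, i, i + k - 1L)
  km <- unique(km[!grepl("[^ACGT]", km)])
  if (length(km) == 0L) return(character(0))
  rc <- revcomp_chr(km)
  unique(ifelse(km <= rc, km, rc))
}

# Back-translate an amino-acid sequence to DNA by drawing a random synonymous
# codon per residue (table 11, sense codons only). Uses the current RNG state;
# callers scope it with withr::with_seed.
back_translate <- function(aa) {
  tab <- codons_by_aa()
  letters <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste0(vapply(letters, function(a) {
    cs <- tab[[a]]
    if (is.null(cs)) abort(paste0("cannot back-translate residue '", a, "'"))
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE), collapse = "")
}

codons_by_aa <- function() {
  if (is.null(.sb$codons_by_aa)) {
    gc <- genetic_code_11()
    gc <- gc[gc != "*"]
    .sb$codons_by_aa <- split(names(gc), unname(gc))
  }
  .sb$codons_by_aa
}

# Substitute amino acids at a given per-site rate (uniform over the 19 other
# residues). Uses the current RNG state.
mutate_protein <- function(aa, rate) {
  if (rate <= 0) return(aa)
  letters <- strsplit(aa, "", fixed = TRUE)[[1]]
  alphabet <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  hit <- stats::runif(length(letters)) < rate
  if (any(hit)) {
    letters[hit] <- vapply(letters[hit], function(a) {
      sample(setdiff(alphabet, a), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste0(letters, collapse = "")
}
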