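# Contig quality control: coverage extraction from assembler headers,
# ambiguity-run splitting and the minimum-length filter.

#' Parse fold-coverage from a FASTA description line
#'
#' Recognises the SPAdes header dialect (`..._cov_12.4`) and a generic
#' `cov=12.4` token. When neither token is present the default is returned;
#' a token followed by a malformed number yields a warning and the default.
#'
#' @param header Character vector of FASTA description lines.
#' @param default Coverage used when no token is found (default 50, i.e. the
#'   contig is assumed adequately covered when the assembler reports nothing).
#' @return Numeric vector of coverages.
#' @examples
#' parse_coverage("NODE_1_length_5000_cov_12.4") # 12.4
#' parse_coverage("contig7 cov=3.0") # 3
#' @export
parse_coverage <- function(header, default = 50) {
  vapply(header, function(h) {
    tok <- NA_character_
    m <- regmatches(h, regexec("_cov_([^_[:space:]]+)", h))[[1]]
    if (length(m) == 2L) {
      tok <- m[2]
    } else {
      m <- regmatches(h, regexec("cov=([^[:space:]]+)", h))[[1]]
      if (length(m) == 2L) tok <- m[2]
    }
    if (is.na(tok)) return(default)
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v) || v < 0) {
      warn(paste0("malformed coverage token in header '", h, "'; using default ", default))
      return(default)
    }
    v
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read contigs from a FASTA file
#'
#' Sequences are upper-cased; the contig id is the first whitespace-delimited
#' token of the header and coverage is parsed from the full header with
#' [parse_coverage()].
#'
#' @param path FASTA file.
#' @param default_coverage Coverage for headers without a coverage token.
#' @return A tibble with columns `contig_id`, `seq`, `length`, `coverage`.
#' @export
read_contigs <- function(path, default_coverage = 50) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  tibble(
    contig_id = sub("\\s.*$", "", hdr),
    seq = unname(toupper(as.character(ss))),
    length = Biostrings::width(ss),
    coverage = parse_coverage(hdr, default_coverage)
  )
}

#' Write contigs to a FASTA file
#'
#' @param contigs Contig tibble (`contig_id`, `seq`).
#' @param path Output file.
#' @param headers Optional header lines (default the contig ids).
#' @return The path, invisibly.
#' @export
write_contigs <- function(contigs, path, headers = contigs$contig_id) {
  write_fasta(headers, contigs$seq, path, "DNA")
  invisible(path)
}

#' Quality-control contigs: split long ambiguity runs, drop short contigs
#'
#' Contigs are split at runs of `max_ambig_run` or more ambiguous bases (any
#' letter other than A, C, G, T); the run itself is removed. Fragments
#' shorter than `min_len` base pairs are dropped. Fragment ids derive
#' deterministically from the parent id (suffix `_p1`, `_p2`, ... in genomic
#' order); a contig returned whole keeps its id. Coverage is inherited from
#' the parent. Cleaning is idempotent.
#'
#' @param contigs Contig tibble (`contig_id`, `seq`, `coverage`).
#' @param min_len Minimum fragment length in bp (default 400).
#' @param max_ambig_run Ambiguity-run length that triggers a split (default 50).
#' @return A contig tibble of QC-passing fragments.
#' @export
clean_contigs <- function(contigs, min_len = 400, max_ambig_run = 50) {
  stopifnot(min_len >= 1, max_ambig_run >= 1)
  if (nrow(contigs) == 0L) {
    return(tibble(
      contig_id = character(0), seq = character(0),
      length = integer(0), coverage = numeric(0)
    ))
  }
  pat <- sprintf("[^ACGT]{%d,}", as.integer(max_ambig_run))
  out <- pmap(
    list(contigs$contig_id, contigs$seq, contigs$coverage),
    function(id, s, cov) {
      s <- toupper(s)
      frags <- strsplit(s, pat)[[1]]
      if (length(frags) == 0L) return(NULL)
      ids <- if (length(frags) == 1L && nchar(frags) == nchar(s)) {
        id
      } else {
        paste0(id, "_p", seq_along(frags))
      }
      keep <- nchar(frags) >= min_len
      if (!any(keep)) return(NULL)
      tibble(
        contig_id = ids[keep], seq = frags[keep],
        length = nchar(frags[keep]), coverage = cov
      )
    }
  )
  bind_rows(out)
}
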