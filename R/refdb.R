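# Reference collection: role-labelled proteomes, seed-protein database,
# taxonomy and the universal-marker-role catalog. This is the supervised
# signal the binning method leans on, standing in for a large curated
# genome database.

#' Seed-protein length policy
#'
#' Closed per-domain intervals (in amino-acid residues) within which a
#' single-copy seed protein is considered plausible: 209-405 for Bacteria and
#' 293-652 for Archaea by default.
#'
#' @param bacteria,archaea Length-2 numeric vectors `c(lower, upper)`.
#' @return A `seed_length_policy` list.
#' @export
seed_length_policy <- function(bacteria = c(209, 405), archaea = c(293, 652)) {
  for (r in list(bacteria, archaea)) {
    if (length(r) != 2 || r[1] < 1 || r[1] >= r[2]) {
      abort("seed length ranges must be c(lower, upper) with 1 <= lower < upper")
    }
  }
  structure(list(Bacteria = bacteria, Archaea = archaea),
    class = "seed_length_policy"
  )
}

new_ref_db <- function(genomes, proteins, seeds, roles, seed_role_id,
                       seed_policy = seed_length_policy()) {
  db <- structure(
    list(
      genomes = genomes, proteins = proteins, seeds = seeds,
      roles = roles, seed_role_id = seed_role_id, seed_policy = seed_policy
    ),
    class = "ref_db"
  )
  validate_ref_db(db)
}

clean_aa <- function(aa) {
  # ambiguous amino-acid letters map to X; X-containing k-mers never match
  chartr("BZJUO", "XXXXX", toupper(aa))
}

validate_ref_db <- function(db) {
  g <- db$genomes
  if (anyDuplicated(g$genome_id)) {
    dup <- unique(g$genome_id[duplicated(g$genome_id)])
    abort(paste0("duplicate genome_id in reference database: ", paste(dup, collapse = ", ")))
  }
  bad_dom <- setdiff(unique(g$domain), c("Bacteria", "Archaea"))
  if (length(bad_dom)) {
    abort(paste0("unknown domain(s): ", paste(bad_dom, collapse = ", ")))
  }
  missing_tax <- setdiff(unique(db$proteins$genome_id), g$genome_id)
  if (length(missing_tax)) {
    abort(paste0(
      "genome(s) in protein file absent from taxonomy: ",
      paste(missing_tax, collapse = ", ")
    ))
  }
  missing_seed <- setdiff(g$genome_id, db$seeds$genome_id)
  if (length(missing_seed)) {
    abort(paste0(
      "genome(s) without a seed-protein entry: ",
      paste(missing_seed, collapse = ", ")
    ))
  }
  if (any(!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", db$seeds$aa))) {
    bad <- db$seeds$genome_id[!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", db$seeds$aa)]
    abort(paste0("seed entry with illegal characters: ", paste(bad, collapse = ", ")))
  }
  if (any(nchar(db$seeds$aa) == 0)) {
    abort("seed proteins must have length > 0")
  }
  if (any(!grepl("^[ACDEFGHIKLMNPQRSTVWYX*]*$", db$proteins$aa))) {
    abort("protein sequences must use the 20-letter amino-acid alphabet plus X")
  }
  mk <- db$roles
  if (!db$seed_role_id %in% mk$role_id[mk$is_marker_bacteria] ||
    !db$seed_role_id %in% mk$role_id[mk$is_marker_archaea]) {
    abort("seed role must be a universal marker role for both domains")
  }
  if (!any(mk$is_marker_bacteria) || !any(mk$is_marker_archaea)) {
    abort("marker role sets must be non-empty for both domains")
  }
  db
}

#' Marker roles of a domain
#'
#' @param db A `ref_db`.
#' @param domain `"Bacteria"` or `"Archaea"`.
#' @return Character vector of role ids expected exactly once in that domain.
#' @export
marker_roles <- function(db, domain = c("Bacteria", "Archaea")) {
  domain <- match.arg(domain)
  col <- if (domain == "Bacteria") "is_marker_bacteria" else "is_marker_archaea"
  sort(db$roles$role_id[db$roles[[col]]])
}

#' @export
print.ref_db <- function(x, ...) {
  cat(
    "<ref_db> ", nrow(x$genomes), " genomes, ", nrow(x$proteins),
    " proteins, ", length(marker_roles(x, "Bacteria")),
    " bacterial marker roles (seed role: ", x$seed_role_id, ")\n",
    sep = ""
  )
  invisible(x)
}

read_fasta_tbl <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  ss <- if (type == "AA") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  tibble(header = names(ss), seq = unname(as.character(ss)))
}

#' Load a reference database from its four files
#'
#' Reads the reference collection from disk: a role-labelled protein FASTA
#' (`>protein_id role_id genome_id` headers; role `hypothetical` marks
#' unannotated proteins), a seed-protein FASTA (amino acid, with an optional
#' DNA sibling whose extension is `.fna`), a taxonomy TSV
#' (`genome_id, species_id, species_name, domain`, with a header row) and a
#' role catalog TSV (`role_id, role_name, is_marker_bacteria,
#' is_marker_archaea`). Ambiguous amino-acid letters (B, Z, J, U, O) are
#' mapped to `X` on load.
#'
#' @param proteins_path Path to `proteins.faa`.
#' @param seeds_path Path to `seeds.faa` (a `seeds.fna` DNA sibling is read
#'   when present).
#' @param taxonomy_path Path to `taxonomy.tsv`.
#' @param roles_path Path to `roles.tsv`.
#' @param seed_role_id Role id of the designated seed role. When `NULL`, a
#'   marker role whose name mentions a phenylalanyl-tRNA synthetase alpha
#'   chain (pheS) is auto-detected.
#' @param seed_policy A [seed_length_policy()].
#' @return A `ref_db` object.
#' @export
load_reference_db <- function(proteins_path, seeds_path, taxonomy_path,
                              roles_path, seed_role_id = NULL,
                              seed_policy = seed_length_policy()) {
  for (p in c(proteins_path, seeds_path, taxonomy_path, roles_path)) {
    if (!file.exists(p)) abort(paste0("reference database file not found: ", p))
  }
  prot_raw <- read_fasta_tbl(proteins_path, "AA")
  toks <- strsplit(prot_raw$header, "\\s+")
  bad <- lengths(toks) < 3L
  if (any(bad)) {
    abort(paste0(
      "malformed protein header (need 'protein_id role_id genome_id'): ",
      prot_raw$header[which(bad)[1]]
    ))
  }
  proteins <- tibble(
    protein_id = map_chr(toks, 1),
    genome_id = map_chr(toks, 3),
    role_id = map_chr(toks, 2),
    aa = clean_aa(prot_raw$seq)
  )

  seeds_aa <- read_fasta_tbl(seeds_path, "AA")
  seeds <- tibble(
    genome_id = sub("\\s.*$", "", seeds_aa$header),
    aa = clean_aa(seeds_aa$seq), dna = NA_character_
  )
  fna <- sub("\\.fa(a|sta)?$", ".fna", seeds_path)
  if (!identical(fna, seeds_path) && file.exists(fna)) {
    dna <- read_fasta_tbl(fna, "DNA")
    dna_tbl <- tibble(genome_id = sub("\\s.*$", "", dna$header), dna2 = toupper(dna$seq))
    seeds <- seeds |>
      left_join(dna_tbl, by = "genome_id") |>
      mutate(dna = .data$dna2) |>
      select(-"dna2")
  }

  tax <- utils::read.delim(taxonomy_path, sep = "\t", colClasses = "character")
  need <- c("genome_id", "species_id", "species_name", "domain")
  if (!all(need %in% names(tax))) {
    abort(paste0("taxonomy.tsv must have columns: ", paste(need, collapse = ", ")))
  }
  roles_raw <- utils::read.delim(roles_path, sep = "\t", colClasses = "character")
  roles <- tibble(
    role_id = roles_raw$role_id,
    role_name = roles_raw$role_name,
    is_marker_bacteria = tolower(roles_raw$is_marker_bacteria) %in% c("true", "1", "yes"),
    is_marker_archaea = tolower(roles_raw$is_marker_archaea) %in% c("true", "1", "yes")
  )

  genome_ids <- sort(unique(c(proteins$genome_id, seeds$genome_id)))
  genomes <- tibble(genome_id = genome_ids) |>
    left_join(as_tibble(tax), by = "genome_id")
  if (anyNA(genomes$species_id)) {
    abort(paste0(
      "genome(s) absent from taxonomy: ",
      paste(genomes$genome_id[is.na(genomes$species_id)], collapse = ", ")
    ))
  }
  genomes <- genomes |> rename(name = "species_name") |> mutate(name = .data$name)
  genomes$species_name <- genomes$name

  if (is.null(seed_role_id)) {
    hit <- grepl("phenylalanyl-tRNA synthetase alpha|\\bpheS\\b", roles$role_name,
      ignore.case = TRUE
    )
    if (!any(hit)) {
      abort("seed_role_id not given and no pheS-like role found in roles.tsv")
    }
    seed_role_id <- roles$role_id[which(hit)[1]]
  }

  db <- new_ref_db(
    genomes = genomes[, c("genome_id", "name", "species_id", "species_name", "domain")],
    proteins = proteins, seeds = seeds, roles = roles,
    seed_role_id = seed_role_id, seed_policy = seed_policy
  )
  inform(paste0(
    "loaded reference database: ", nrow(db$genomes), " genomes, ",
    nrow(db$proteins), " proteins, ",
    length(marker_roles(db, "Bacteria")), " bacterial / ",
    length(marker_roles(db, "Archaea")), " archaeal marker roles"
  ))
  db
}

write_fasta <- function(headers, seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  ss <- if (type == "AA") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write a reference database to a directory
#'
#' Emits `proteins.faa`, `seeds.faa` (+ `seeds.fna` when DNA is present),
#' `taxonomy.tsv` and `roles.tsv` in the formats read by
#' [load_reference_db()].
#'
#' @param db A `ref_db`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(
    paste(db$proteins$protein_id, db$proteins$role_id, db$proteins$genome_id),
    db$proteins$aa, file.path(dir, "proteins.faa"), "AA"
  )
  write_fasta(db$seeds$genome_id, db$seeds$aa, file.path(dir, "seeds.faa"), "AA")
  if (!all(is.na(db$seeds$dna))) {
    has <- !is.na(db$seeds$dna)
    write_fasta(db$seeds$genome_id[has], db$seeds$dna[has],
      file.path(dir, "seeds.fna"), "DNA"
    )
  }
  utils::write.table(
    db$genomes[, c("genome_id", "species_id", "species_name", "domain")],
    file.path(dir, "taxonomy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  roles_out <- db$roles
  roles_out$is_marker_bacteria <- ifelse(roles_out$is_marker_bacteria, "true", "false")
  roles_out$is_marker_archaea <- ifelse(roles_out$is_marker_archaea, "true", "false")
  utils::write.table(roles_out, file.path(dir, "roles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' Load a reference database from a directory
#'
#' Convenience wrapper around [load_reference_db()] for the standard layout
#' written by [write_reference_db()].
#'
#' @param dir Directory containing `proteins.faa`, `seeds.faa`,
#'   `taxonomy.tsv`, `roles.tsv`.
#' @inheritParams load_reference_db
#' @return A `ref_db`.
#' @export
load_reference_db_dir <- function(dir, seed_role_id = NULL,
                                  seed_policy = seed_length_policy()) {
  load_reference_db(
    file.path(dir, "proteins.faa"), file.path(dir, "seeds.faa"),
    file.path(dir, "taxonomy.tsv"), file.path(dir, "roles.tsv"),
    seed_role_id = seed_role_id, seed_policy = seed_policy
  )
}

#' Filter reference genomes by quality cutoffs
#'
#' Retains only genomes meeting the high-quality criteria: contamination
#' <= 10 percent, fine consistency >= 87 percent, completeness >= 80 percent,
#' and exactly one seed gene whose length lies within the domain's policy
#' range (all boundaries inclusive). Filtering is idempotent.
#'
#' @param db A `ref_db`.
#' @param metrics_per_genome Tibble with columns `genome_id`, `completeness`,
#'   `contamination`, `fine_consistency`, `seed_count`, `seed_length`.
#' @param policy A [seed_length_policy()]; defaults to the database's.
#' @param contamination_max,fine_min,completeness_min Quality cutoffs.
#' @return A filtered `ref_db`.
#' @export
filter_reference_candidates <- function(db, metrics_per_genome,
                                        policy = db$seed_policy,
                                        contamination_max = 10,
                                        fine_min = 87,
                                        completeness_min = 80) {
  m <- as_tibble(metrics_per_genome) |>
    inner_join(db$genomes[, c("genome_id", "domain")], by = "genome_id")
  in_range <- map_lgl(seq_len(nrow(m)), function(i) {
    r <- policy[[m$domain[i]]]
    m$seed_length[i] >= r[1] && m$seed_length[i] <= r[2]
  })
  keep <- m$genome_id[
    m$contamination <= contamination_max &
      m$fine_consistency >= fine_min &
      m$completeness >= completeness_min &
      m$seed_count == 1L &
      in_range
  ]
  if (length(keep) == 0L) {
    warn("no reference genome passes the quality cutoffs; empty database returned")
  }
  db$genomes <- db$genomes |> filter(.data$genome_id %in% keep)
  db$proteins <- db$proteins |> filter(.data$genome_id %in% keep)
  db$seeds <- db$seeds |> filter(.data$genome_id %in% keep)
  db
}
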