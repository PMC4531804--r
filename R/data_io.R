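#' Read per-species protein FASTA files into a sequence catalogue
#'
#' Each FASTA file defines one species; sequences are assigned dense integer
#' gene ids (0-based, unique across all species) and species ids in the order
#' the files are given. Protein lengths are counted after stripping terminal
#' stop characters (`*`).
#'
#' @param fasta_paths Character vector of FASTA file paths, one per species,
#'   length >= 2. Species ids follow the order of this vector.
#' @param species_names Optional character vector of species names; defaults
#'   to the file names without extension.
#'
#' @return A tibble (the sequence catalogue) with columns `gene_id`,
#'   `species_id`, `external_name` (header token up to first whitespace),
#'   `full_header`, `length_aa`, `species_name`.
#' @export
read_fasta_lengths <- function(fasta_paths, species_names = NULL) {
  if (length(fasta_paths) < 2) {
    stop("at least 2 species FASTA files are required")
  }
  if (is.null(species_names)) {
    species_names <- sub("\\.[^.]*$", "", basename(fasta_paths))
  }
  per_species <- purrr::map2(fasta_paths, seq_along(fasta_paths) - 1L, function(path, sp) {
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0) {
      stop(sprintf("empty FASTA file for species '%s' (%s)", species_names[sp + 1L], path))
    }
    full_header <- names(seqs)
    external_name <- vapply(strsplit(full_header, "\\s+"), `[[`, character(1), 1L)
    if (anyDuplicated(external_name)) {
      dup <- unique(external_name[duplicated(external_name)])
      stop(sprintf(
        "duplicate FASTA header(s) in species '%s': %s",
        species_names[sp + 1L], paste(dup, collapse = ", ")
      ))
    }
    chars <- as.character(seqs)
    chars <- sub("\\*+$", "", chars)
    len <- nchar(chars)
    if (any(len < 1)) {
      stop(sprintf(
        "zero-length sequence(s) after stop-codon stripping in species '%s': %s",
        species_names[sp + 1L], paste(external_name[len < 1], collapse = ", ")
      ))
    }
    tibble::tibble(
      species_id = sp,
      external_name = external_name,
      full_header = full_header,
      length_aa = as.integer(len)
    )
  })
  catalog <- dplyr::bind_rows(per_species)
  catalog$gene_id <- seq_len(nrow(catalog)) - 1L
  catalog$species_name <- species_names[catalog$species_id + 1L]
  dplyr::select(
    catalog, "gene_id", "species_id", "external_name",
    "full_header", "length_aa", "species_name"
  )
}

#' Parse BLAST tabular (outfmt 6) similarity results
#'
#' Reads 12-column tab-separated BLAST output (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore), resolves
#' sequence names through the catalogue, discards rows above the e-value
#' cutoff and self-hits (query == subject gene). Extra columns beyond 12 are
#' ignored with a warning.
#'
#' @param path Path to a BLAST tabular file (or a character vector of lines
#'   via `lines =`).
#' @param catalog Sequence catalogue from [read_fasta_lengths()].
#' @param evalue_max Maximum e-value retained (default `1e-3`).
#' @param lines Optional character vector of raw lines instead of `path`.
#'
#' @return A hit tibble with columns `query`, `subject` (gene ids),
#'   `bitscore`, `evalue`, `qspecies`, `sspecies`.
#' @export
parse_blast_tabular <- function(path = NULL, catalog, evalue_max = 1e-3, lines = NULL) {
  if (is.null(lines)) {
    lines <- readLines(path)
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    bad <- which(nf < 12)[1]
    stop(sprintf("malformed BLAST tabular line %d: expected 12 columns, found %d", bad, nf[bad]))
  }
  if (any(nf > 12)) {
    warning("BLAST tabular input has more than 12 columns; extra columns ignored")
  }
  qname <- vapply(fields, `[[`, character(1), 1L)
  sname <- vapply(fields, `[[`, character(1), 2L)
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 11L)))
  bitscore <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 12L)))
  if (anyNA(bitscore)) {
    bad <- which(is.na(bitscore))[1]
    stop(sprintf("non-numeric bitscore on line %d", bad))
  }
  if (anyNA(evalue)) {
    bad <- which(is.na(evalue))[1]
    stop(sprintf("non-numeric e-value on line %d", bad))
  }
  idx_q <- match(qname, catalog$external_name)
  idx_s <- match(sname, catalog$external_name)
  if (anyNA(idx_q) || anyNA(idx_s)) {
    unknown <- unique(c(qname[is.na(idx_q)], sname[is.na(idx_s)]))
    stop(sprintf("unknown sequence name(s): %s", paste(unknown, collapse = ", ")))
  }
  hits <- tibble::tibble(
    query = catalog$gene_id[idx_q],
    subject = catalog$gene_id[idx_s],
    bitscore = bitscore,
    evalue = evalue,
    qspecies = catalog$species_id[idx_q],
    sspecies = catalog$species_id[idx_s]
  )
  dplyr::filter(hits, .data$evalue <= evalue_max, .data$query != .data$subject)
}

empty_hits <- function() {
  tibble::tibble(
    query = integer(), subject = integer(),
    bitscore = numeric(), evalue = numeric(),
    qspecies = integer(), sspecies = integer()
  )
}

#' Collapse multiple HSPs per gene pair to a single hit
#'
#' BLAST can report several high-scoring segment pairs for one (query,
#' subject) pair; downstream steps need one score per ordered pair. The hit
#' with maximal bitscore is kept; among equal bitscores the one with minimal
#' e-value; remaining ties broken by first occurrence. Idempotent.
#'
#' @param hits Hit tibble as returned by [parse_blast_tabular()].
#' @return Deduplicated hit tibble, at most one row per ordered (query,
#'   subject) pair.
#' @export
dedupe_hits <- function(hits) {
  hits |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::arrange(.data$query, .data$subject, dplyr::desc(.data$bitscore), .data$evalue, .data$.row) |>
    dplyr::distinct(.data$query, .data$subject, .keep_all = TRUE) |>
    dplyr::select(-".row")
}

#' Read a directory of per-species-pair BLAST tabular files
#'
#' Files must be named `Blast<i>_<j>.txt` where `i` and `j` are the species
#' ids of the query and subject species (same-species pairs included).
#'
#' @param dir Directory containing the BLAST files.
#' @param catalog Sequence catalogue.
#' @param evalue_max Maximum e-value retained.
#' @return A single deduplicated hit tibble covering all ordered species pairs.
#' @export
read_blast_dir <- function(dir, catalog, evalue_max = 1e-3) {
  n_sp <- length(unique(catalog$species_id))
  pairs <- expand.grid(q = seq_len(n_sp) - 1L, s = seq_len(n_sp) - 1L)
  paths <- file.path(dir, sprintf("Blast%d_%d.txt", pairs$q, pairs$s))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop(sprintf(
      "missing BLAST result file(s) for species pair(s): %s",
      paste(sprintf("%d vs %d", pairs$q[missing], pairs$s[missing]), collapse = "; ")
    ))
  }
  hits <- purrr::map(paths, parse_blast_tabular, catalog = catalog, evalue_max = evalue_max)
  dedupe_hits(dplyr::bind_rows(hits))
}

#' Write a hit tibble back to BLAST tabular format
#'
#' Only the fields the pipeline uses are meaningful; alignment columns are
#' filled with placeholders so the output remains valid 12-column outfmt 6.
#'
#' @param hits Hit tibble.
#' @param catalog Sequence catalogue (for external names).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, catalog, path) {
  qn <- catalog$external_name[match(hits$query, catalog$gene_id)]
  sn <- catalog$external_name[match(hits$subject, catalog$gene_id)]
  lines <- sprintf(
    "%s\t%s\t0.0\t0\t0\t0\t0\t0\t0\t0\t%s\t%s",
    qn, sn, format(hits$evalue, scientific = TRUE, digits = 6),
    format(hits$bitscore, digits = 10, scientific = FALSE, trim = TRUE)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write species and sequence id maps
#'
#' Plain-text "index: name" files for user inspection of the internal id
#' assignment.
#'
#' @param catalog Sequence catalogue.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_id_maps <- function(catalog, dir) {
  sp <- dplyr::distinct(catalog, .data$species_id, .data$species_name)
  sp_path <- file.path(dir, "SpeciesIDs.txt")
  seq_path <- file.path(dir, "SequenceIDs.txt")
  writeLines(sprintf("%d: %s", sp$species_id, sp$species_name), sp_path)
  writeLines(sprintf("%d: %s", catalog$gene_id, catalog$external_name), seq_path)
  invisible(c(sp_path, seq_path))
}
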