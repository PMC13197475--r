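#' Read a proteome FASTA file into a protein table
#'
#' Parses an amino-acid FASTA file into one row per sequence entry. Headers
#' are split into a gene identifier and an isoform identifier: by default the
#' gene is everything before the last `"."` in the first whitespace-delimited
#' word of the header (the common `gene.isoform` accession dialect), and the
#' isoform identifier is the full accession. Sequences are upper-cased, `*`
#' stop symbols are stripped, and any character outside the 20 standard amino
#' acids and the usual ambiguity codes (B, Z, X, U, O, J) is replaced by the
#' unknown-residue symbol `X` with a warning.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param species_id Species identifier attached to every record.
#' @param gene_pattern Regular expression with one capture group extracting
#'   the gene id from the accession. Accessions that do not match keep the
#'   whole accession as the gene id.
#' @return A tibble with columns `species_id`, `gene_id`, `isoform_id`,
#'   `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1.t1", "MKV", ">g1.t2", "MKVLA"), fa)
#' read_fasta(fa, species_id = "sp1")
#' @export
read_fasta <- function(path, species_id, gene_pattern = "^(.*)\\.[^.]+$") {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  # read as raw strings: the amino-acid alphabet check (with replacement,
  # not silent removal) is applied below
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) abort(sprintf("no sequences in FASTA file: %s", path))

  accession <- sub("\\s.*$", "", names(seqs))
  gene_id <- ifelse(grepl(gene_pattern, accession),
    sub(gene_pattern, "\\1", accession), accession
  )
  sequence <- unname(toupper(gsub("\\*", "", as.character(seqs))))

  bad <- grepl(sprintf("[^%s]", paste(c(AMINO_ACIDS, AMBIGUITY_CODES), collapse = "")), sequence)
  if (any(bad)) {
    warn(sprintf(
      "%d sequence(s) in %s contain non-amino-acid characters; mapped to '%s'",
      sum(bad), basename(path), UNK_RESIDUE
    ))
    sequence[bad] <- gsub(
      sprintf("[^%s]", paste(c(AMINO_ACIDS, AMBIGUITY_CODES), collapse = "")),
      UNK_RESIDUE, sequence[bad]
    )
  }
  if (any(nchar(sequence) == 0L)) abort(sprintf("zero-length sequence after '*' stripping in %s", path))

  out <- tibble::tibble(
    species_id = species_id,
    gene_id = gene_id,
    isoform_id = accession,
    sequence = sequence
  )
  if (anyDuplicated(out$isoform_id)) {
    abort(sprintf("duplicated (species_id, isoform_id) in %s", path))
  }
  out
}

#' Write a protein table to FASTA
#'
#' Inverse of [read_fasta()]: one entry per row, headers are the isoform ids.
#'
#' @param proteins Tibble with `isoform_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- proteins$isoform_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Keep the longest isoform of each gene
#'
#' Collapses a protein table to exactly one record per `(species_id, gene_id)`
#' pair: the longest sequence, with length ties broken by the
#' lexicographically smallest isoform id. Idempotent.
#'
#' @param proteins Tibble as returned by [read_fasta()].
#' @return A tibble with one row per gene.
#' @export
select_longest_isoform <- function(proteins) {
  proteins |>
    dplyr::mutate(.len = nchar(.data$sequence)) |>
    dplyr::arrange(
      .data$species_id, .data$gene_id,
      dplyr::desc(.data$.len), .data$isoform_id
    ) |>
    dplyr::distinct(.data$species_id, .data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-".len")
}

#' Read an orthogroup membership table
#'
#' Reads the tab-separated orthogroup dialect written by orthology inference
#' tools: first column the orthogroup id, one column per species containing a
#' comma-separated list of gene ids (blank where the species has no member).
#'
#' @param path Path to the TSV file.
#' @param species Optional character vector of known species ids; species
#'   columns outside this set raise an error.
#' @return A long tibble with columns `orthogroup_id`, `species_id`,
#'   `gene_id`, one row per member gene. Orthogroups with no members and the
#'   full species column set are preserved in the `"orthogroup_ids"` and
#'   `"species"` attributes.
#' @export
read_orthogroups <- function(path, species = NULL) {
  wide <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(wide) < 2L) abort("orthogroup table needs an id column plus one column per species")
  names(wide)[1] <- "orthogroup_id"
  if (anyDuplicated(wide$orthogroup_id)) {
    abort("duplicated orthogroup_id in orthogroup table")
  }
  sp_cols <- names(wide)[-1]
  if (!is.null(species)) {
    unknown <- setdiff(sp_cols, species)
    if (length(unknown)) {
      abort(sprintf("species column(s) not in species table: %s", paste(unknown, collapse = ", ")))
    }
  }
  long <- wide |>
    tidyr::pivot_longer(-"orthogroup_id", names_to = "species_id", values_to = "gene_id") |>
    dplyr::filter(!is.na(.data$gene_id), .data$gene_id != "") |>
    tidyr::separate_longer_delim("gene_id", delim = ",") |>
    dplyr::mutate(gene_id = trimws(.data$gene_id)) |>
    dplyr::filter(.data$gene_id != "")
  attr(long, "orthogroup_ids") <- wide$orthogroup_id
  attr(long, "species") <- sp_cols
  long
}

#' Write an orthogroup membership table
#'
#' Inverse of [read_orthogroups()]: reconstructs the wide comma-separated
#' dialect. Species columns and empty orthogroups are taken from the table's
#' attributes when present, otherwise from the rows.
#'
#' @param orthogroups Long membership tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(orthogroups, path) {
  og_ids <- attr(orthogroups, "orthogroup_ids") %||% sort(unique(orthogroups$orthogroup_id))
  species <- attr(orthogroups, "species") %||% sort(unique(orthogroups$species_id))
  wide <- orthogroups |>
    dplyr::group_by(.data$orthogroup_id, .data$species_id) |>
    dplyr::summarise(gene_id = paste(sort(.data$gene_id), collapse = ", "), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species_id", values_from = "gene_id")
  full <- tibble::tibble(orthogroup_id = og_ids) |>
    dplyr::left_join(wide, by = "orthogroup_id")
  for (sp in species) if (!sp %in% names(full)) full[[sp]] <- NA_character_
  full <- full[, c("orthogroup_id", species)]
  full[is.na(full)] <- ""
  names(full)[1] <- "Orthogroup"
  readr::write_tsv(full, path)
  invisible(path)
}

#' Select orthogroups by species coverage
#'
#' Coverage of an orthogroup is the fraction of the species list with at
#' least one member gene. Orthogroups at or above the threshold are selected
#' and ordered lexicographically by id; this canonical order fixes the
#' sentence-slot positions used by every downstream stage.
#'
#' @param orthogroups Long membership tibble from [read_orthogroups()].
#' @param species_ids Character vector of species over which coverage is
#'   computed.
#' @param threshold Minimum coverage fraction in `[0, 1]` (default 0.98).
#' @return A tibble of class `coverage_selection` with columns
#'   `orthogroup_id`, `coverage`, `selected`, sorted by id, carrying the
#'   threshold as an attribute.
#' @export
select_by_coverage <- function(orthogroups, species_ids, threshold = 0.98) {
  if (length(species_ids) == 0L) abort("`species_ids` must be non-empty")
  check_fraction(threshold, "threshold")
  og_ids <- attr(orthogroups, "orthogroup_ids") %||% unique(orthogroups$orthogroup_id)

  cov <- orthogroups |>
    dplyr::filter(.data$species_id %in% species_ids) |>
    dplyr::distinct(.data$orthogroup_id, .data$species_id) |>
    dplyr::count(.data$orthogroup_id, name = "n_species")
  out <- tibble::tibble(orthogroup_id = og_ids) |>
    dplyr::left_join(cov, by = "orthogroup_id") |>
    dplyr::mutate(
      n_species = dplyr::coalesce(.data$n_species, 0L),
      coverage = .data$n_species / length(species_ids),
      selected = .data$coverage >= threshold
    ) |>
    dplyr::select("orthogroup_id", "coverage", "selected") |>
    dplyr::arrange(.data$orthogroup_id)
  attr(out, "threshold") <- threshold
  class(out) <- c("coverage_selection", class(out))
  out
}

#' Orthogroup ids selected by a coverage selection
#'
#' @param selection A `coverage_selection` tibble.
#' @return Character vector of selected orthogroup ids in canonical
#'   (lexicographic) order.
#' @export
selected_orthogroups <- function(selection) {
  selection$orthogroup_id[selection$selected]
}

#' Read a species table
#'
#' Reads a TSV with columns `species_id`, `label` (0/"wingless" or
#' 1/"winged"), `path` (proteome FASTA), and optionally `completeness` (a
#' fraction in `[0, 1]`, e.g. a proteome completeness score).
#'
#' @param path Path to the TSV file.
#' @return A tibble with integer `label` (0 = wingless, 1 = winged).
#' @export
read_species_table <- function(path) {
  sp <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("species_id", "label") %in% names(sp))) {
    abort("species table needs `species_id` and `label` columns")
  }
  if (anyDuplicated(sp$species_id)) abort("duplicated species_id in species table")
  lab <- tolower(sp$label)
  lab[lab == "wingless"] <- "0"
  lab[lab == "winged"] <- "1"
  if (!all(lab %in% c("0", "1"))) abort("labels must be 0/1 or wingless/winged")
  sp$label <- as.integer(lab)
  if ("completeness" %in% names(sp)) sp$completeness <- as.numeric(sp$completeness)
  sp
}

#' Filter species by proteome completeness
#'
#' Drops species whose `completeness` falls below the cutoff. Species without
#' a completeness value (or tables without the column) are kept.
#'
#' @param species Species tibble.
#' @param min_completeness Minimum completeness fraction (default 0.9).
#' @return Filtered species tibble.
#' @export
filter_by_completeness <- function(species, min_completeness = 0.9) {
  if (!"completeness" %in% names(species)) return(species)
  dplyr::filter(species, is.na(.data$completeness) | .data$completeness >= min_completeness)
}
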