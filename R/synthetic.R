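# Planted-signal proteome simulator: two classes of species share background
# orthogroups; a designated subset of orthogroups carries a class-specific
# sequence motif, detectable through 3-mer composition, so the pipeline's
# ability to recover known discriminative orthogroups can be measured.

#' Synthetic benchmark configuration
#'
#' Defaults define the package's desk-scale benchmark: 20 + 20 species over
#' 200 orthogroups, 10 of which are discriminative; winged-class members of
#' discriminative orthogroups carry 3 embedded copies of a 9-residue motif
#' on an otherwise uniform residue background. A small presence/absence
#' dropout leaves 2% of (species, orthogroup) pairs empty.
#'
#' @param n_species_class0,n_species_class1 Species per class (wingless /
#'   winged; defaults 20 and 20).
#' @param n_orthogroups Total orthogroups (default 200).
#' @param n_discriminative Orthogroups carrying the planted motif (default
#'   10; 0 gives the null model with exchangeable classes).
#' @param members_per_orthogroup Integer range (min, max) of member genes
#'   per present (species, orthogroup) pair (default `c(1, 2)`).
#' @param seq_length Integer range of gene lengths in residues (default
#'   `c(90, 150)`).
#' @param motif Planted motif, residues over the 20-letter alphabet, length
#'   at least the tokenizer k (default `"CHWCHWCHW"`).
#' @param motif_copies Motif copies embedded per winged-class gene in a
#'   discriminative orthogroup (default 3).
#' @param background_frequencies Length-20 residue frequency vector summing
#'   to 1 (default uniform).
#' @param dropout_fraction Fraction of (species, orthogroup) pairs left
#'   empty (default 0.02).
#' @param seed Integer seed; generation is bitwise reproducible.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species_class0 = 20L, n_species_class1 = 20L,
                             n_orthogroups = 200L, n_discriminative = 10L,
                             members_per_orthogroup = c(1L, 2L),
                             seq_length = c(90L, 150L),
                             motif = "CHWCHWCHW", motif_copies = 3L,
                             background_frequencies = rep(1 / 20, 20),
                             dropout_fraction = 0.02, seed = 1L) {
  if (n_discriminative > n_orthogroups) {
    abort("`n_discriminative` cannot exceed `n_orthogroups`")
  }
  residues <- strsplit(toupper(motif), "")[[1]]
  if (!all(residues %in% AMINO_ACIDS)) {
    abort("motif contains residues outside the 20-letter amino-acid alphabet")
  }
  if (length(background_frequencies) != 20L ||
      abs(sum(background_frequencies) - 1) > 1e-8) {
    abort("`background_frequencies` must be 20 values summing to 1")
  }
  check_fraction(dropout_fraction, "dropout_fraction")
  structure(
    list(
      n_species_class0 = as.integer(n_species_class0),
      n_species_class1 = as.integer(n_species_class1),
      n_orthogroups = as.integer(n_orthogroups),
      n_discriminative = as.integer(n_discriminative),
      members_per_orthogroup = as.integer(members_per_orthogroup),
      seq_length = as.integer(seq_length),
      motif = toupper(motif), motif_copies = as.integer(motif_copies),
      background_frequencies = background_frequencies,
      dropout_fraction = dropout_fraction, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Embed non-overlapping motif copies into a background sequence at random
# positions; returns the sequence and the start positions.
plant_motif <- function(residues, motif_res, copies) {
  L <- length(residues)
  ml <- length(motif_res)
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < copies && tries < 200L) {
    cand <- sample.int(L - ml + 1L, 1L)
    if (!any(abs(cand - starts) < ml)) starts <- c(starts, cand)
    tries <- tries + 1L
  }
  for (s in starts) residues[s:(s + ml - 1L)] <- motif_res
  list(residues = residues, starts = sort(starts))
}

#' Generate a two-class synthetic proteome benchmark
#'
#' Draws background sequences i.i.d. from the background residue
#' frequencies; in each discriminative orthogroup, every member gene of a
#' winged-class species carries `motif_copies` embedded copies of the motif
#' at random non-overlapping positions (wingless-class members carry none).
#' Presence/absence dropout is applied per (species, orthogroup) pair.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `wing_simulation` with `species` (tibble
#'   `species_id`, `label`), `proteins` (protein tibble as from
#'   [read_fasta()]), `orthogroups` (long membership tibble), `truth`
#'   (list with `discriminative_orthogroup_ids` and a `motif_positions`
#'   tibble), and `config`.
#' @export
simulate_proteomes <- function(config = synthetic_config()) {
  n_sp <- config$n_species_class0 + config$n_species_class1
  species <- tibble::tibble(
    species_id = sprintf("sp%03d", seq_len(n_sp)),
    label = rep(c(0L, 1L), c(config$n_species_class0, config$n_species_class1))
  )
  og_ids <- sprintf("OG%04d", seq_len(config$n_orthogroups))
  motif_res <- strsplit(config$motif, "")[[1]]
  mrange <- config$members_per_orthogroup
  lrange <- config$seq_length

  proteins <- NULL
  membership <- NULL
  disc <- character(0)
  motif_pos <- list()

  withr::with_seed(config$seed, {
    disc <- sort(sample(og_ids, config$n_discriminative))
    rows_p <- vector("list", n_sp)
    rows_m <- vector("list", n_sp)
    for (si in seq_len(n_sp)) {
      sp <- species$species_id[si]
      lab <- species$label[si]
      genes <- character(0)
      seqs <- character(0)
      ogs <- character(0)
      for (og in og_ids) {
        if (runif(1) < config$dropout_fraction) next
        n_mem <- if (mrange[1] == mrange[2]) mrange[1] else sample(mrange[1]:mrange[2], 1L)
        for (j in seq_len(n_mem)) {
          L <- if (lrange[1] == lrange[2]) lrange[1] else sample(lrange[1]:lrange[2], 1L)
          res <- sample(AMINO_ACIDS, L, replace = TRUE,
                        prob = config$background_frequencies)
          gid <- sprintf("%s_%s_g%d", sp, og, j)
          if (lab == 1L && og %in% disc) {
            pl <- plant_motif(res, motif_res, config$motif_copies)
            res <- pl$residues
            motif_pos[[length(motif_pos) + 1L]] <- tibble::tibble(
              species_id = sp, orthogroup_id = og, gene_id = gid,
              start = pl$starts
            )
          }
          genes <- c(genes, gid)
          seqs <- c(seqs, paste(res, collapse = ""))
          ogs <- c(ogs, og)
        }
      }
      rows_p[[si]] <- tibble::tibble(
        species_id = sp, gene_id = genes,
        isoform_id = paste0(genes, ".t1"), sequence = seqs
      )
      rows_m[[si]] <- tibble::tibble(
        orthogroup_id = ogs, species_id = sp, gene_id = genes
      )
    }
    proteins <- dplyr::bind_rows(rows_p)
    membership <- dplyr::bind_rows(rows_m) |>
      dplyr::arrange(.data$orthogroup_id, .data$species_id, .data$gene_id)
  })

  attr(membership, "orthogroup_ids") <- og_ids
  attr(membership, "species") <- species$species_id
  structure(
    list(
      species = species, proteins = proteins, orthogroups = membership,
      truth = list(
        discriminative_orthogroup_ids = disc,
        motif_positions = if (length(motif_pos)) {
          dplyr::bind_rows(motif_pos)
        } else {
          tibble::tibble(
            species_id = character(), orthogroup_id = character(),
            gene_id = character(), start = integer()
          )
        }
      ),
      config = config
    ),
    class = "wing_simulation"
  )
}

#' @export
print.wing_simulation <- function(x, ...) {
  cat(sprintf(
    "<wing_simulation> %d + %d species, %d orthogroups (%d discriminative), %d genes\n",
    x$config$n_species_class0, x$config$n_species_class1,
    x$config$n_orthogroups, x$config$n_discriminative, nrow(x$proteins)
  ))
  invisible(x)
}

#' Write a simulation to disk in the standard formats
#'
#' One FASTA per species, a species table TSV (`species_id`, `label`,
#' `path`), the orthogroup membership TSV, and the ground truth as JSON.
#'
#' @param sim A `wing_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(sim$species))
  for (i in seq_len(nrow(sim$species))) {
    sp <- sim$species$species_id[i]
    paths[i] <- file.path(dir, paste0(sp, ".fa"))
    write_fasta(sim$proteins[sim$proteins$species_id == sp, ], paths[i])
  }
  readr::write_tsv(
    dplyr::mutate(sim$species, path = paths),
    file.path(dir, "species.tsv")
  )
  write_orthogroups(sim$orthogroups, file.path(dir, "Orthogroups.tsv"))
  jsonlite::write_json(
    sim$truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Fraction of planted orthogroups recovered by a selection
#'
#' @param selection A `selection_result` (or a character vector of selected
#'   orthogroup ids).
#' @param truth Ground truth from a `wing_simulation` (or a character
#'   vector of discriminative orthogroup ids).
#' @return `|selected intersect discriminative| / |discriminative|`.
#' @export
score_recovery <- function(selection, truth) {
  sel <- if (inherits(selection, "selection_result")) {
    selection$selected$orthogroup_id
  } else {
    selection
  }
  tru <- if (is.list(truth)) truth$discriminative_orthogroup_ids else truth
  if (length(tru) == 0L) abort("ground truth contains no discriminative orthogroups")
  length(intersect(sel, tru)) / length(tru)
}
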