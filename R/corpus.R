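# A species document is one training sample: an ordered list of tokenized
# gene sentences, one slot per selected orthogroup (canonical lexicographic
# order). Slots where the species has no member gene are EMPTY, represented
# as a single PAD token and masked downstream.

EMPTY_SENTENCE <- 0L # a single PAD token

#' Build one species document
#'
#' For every selected orthogroup (in canonical order), draws one member gene
#' of the species uniformly at random (seeded) and takes its tokenized
#' sentence; orthogroups with no member in this species yield an EMPTY
#' sentence. Random per-document resampling of orthologs is the augmentation
#' mechanism: two documents of the same species differ wherever an
#' orthogroup offers more than one member.
#'
#' @param species_id Species identifier.
#' @param label Class label (0 = wingless, 1 = winged).
#' @param selection_ids Character vector of selected orthogroup ids in
#'   canonical order.
#' @param members Named list mapping `"<orthogroup>\r<species>"` to member
#'   gene ids (as built by [build_corpus()]), or a long orthogroup tibble.
#' @param sentences_by_gene Named list mapping `"<species>\r<gene>"` to
#'   integer token-id vectors.
#' @param seed Sampling seed for this document.
#' @param sample_id Identifier for the document (defaults to the species id).
#' @return A list of class `species_document` with fields `sample_id`,
#'   `species_id`, `label`, `sampling_seed`, `gene_ids`, `sentences`.
#' @export
build_document <- function(species_id, label, selection_ids, members,
                           sentences_by_gene, seed, sample_id = species_id) {
  if (is.data.frame(members)) members <- member_index(members)
  keys <- paste(selection_ids, species_id, sep = "\r")
  gene_ids <- rep(NA_character_, length(selection_ids))
  withr::with_seed(seed, {
    for (i in seq_along(keys)) {
      g <- members[[keys[i]]]
      if (is.null(g)) next
      gene_ids[i] <- if (length(g) == 1L) g else g[sample.int(length(g), 1L)]
    }
  })
  if (all(is.na(gene_ids))) {
    abort(sprintf("species '%s' is absent from every selected orthogroup", species_id))
  }
  sentences <- vector("list", length(selection_ids))
  for (i in seq_along(sentences)) {
    if (is.na(gene_ids[i])) {
      sentences[[i]] <- EMPTY_SENTENCE
    } else {
      s <- sentences_by_gene[[paste(species_id, gene_ids[i], sep = "\r")]]
      if (is.null(s)) {
        abort(sprintf(
          "gene '%s' of species '%s' is not resolvable against the tokenized proteome",
          gene_ids[i], species_id
        ))
      }
      sentences[[i]] <- if (length(s) == 0L) EMPTY_SENTENCE else s
    }
  }
  structure(
    list(
      sample_id = sample_id, species_id = species_id, label = as.integer(label),
      sampling_seed = as.integer(seed), gene_ids = gene_ids, sentences = sentences
    ),
    class = "species_document"
  )
}

# Index a long orthogroup tibble as "<og>\r<species>" -> gene ids.
member_index <- function(orthogroups) {
  split(
    orthogroups$gene_id,
    paste(orthogroups$orthogroup_id, orthogroups$species_id, sep = "\r")
  )
}

# Index a tokenized protein tibble as "<species>\r<gene>" -> token ids.
sentence_index <- function(proteins_tok) {
  setNames(
    proteins_tok$token_ids,
    paste(proteins_tok$species_id, proteins_tok$gene_id, sep = "\r")
  )
}

#' Assemble an augmented document corpus
#'
#' Builds `per_species_samples` documents per species, each with a distinct
#' sampling seed derived from the corpus seed, so the corpus size is
#' `n_species * per_species_samples`. With `per_species_samples = 1` this is
#' the identity (un-augmented) corpus.
#'
#' @param species Species tibble with `species_id` and `label`.
#' @param orthogroups Long orthogroup membership tibble.
#' @param proteins_tok Tokenized protein tibble (see [tokenize_proteins()]);
#'   must contain every member gene of the selected orthogroups.
#' @param selection_ids Selected orthogroup ids in canonical order.
#' @param per_species_samples Documents per species (default 1).
#' @param seed Corpus seed; per-document seeds are derived from it.
#' @return A tibble with columns `sample_id`, `species_id`, `label`,
#'   `sampling_seed` and a `document` list-column of `species_document`s.
#' @export
build_corpus <- function(species, orthogroups, proteins_tok, selection_ids,
                         per_species_samples = 1L, seed = 1L) {
  if (per_species_samples < 1L) abort("`per_species_samples` must be >= 1")
  members <- member_index(orthogroups)
  sentences <- sentence_index(proteins_tok)
  grid <- tidyr::expand_grid(
    species_id = species$species_id,
    replicate = seq_len(per_species_samples)
  ) |>
    dplyr::left_join(species[, c("species_id", "label")], by = "species_id") |>
    dplyr::mutate(
      sample_id = sprintf("%s_s%02d", .data$species_id, .data$replicate),
      sampling_seed = stage_seed(seed, dplyr::row_number())
    )
  docs <- purrr::pmap(
    list(grid$species_id, grid$label, grid$sampling_seed, grid$sample_id),
    function(sp, lab, s, sid) {
      build_document(sp, lab, selection_ids, members, sentences, s, sample_id = sid)
    }
  )
  tibble::tibble(
    sample_id = grid$sample_id,
    species_id = grid$species_id,
    label = grid$label,
    sampling_seed = grid$sampling_seed,
    document = docs
  )
}

#' Split samples into training, validation and test sets
#'
#' Shuffles the sample ids (stratified by label when labels are supplied)
#' and partitions them in the given ratio. Sizes follow the floor rule:
#' `n_train = floor(r1/10 * n)`, `n_val = floor(r2/10 * n)`, and the test
#' set takes the remainder, so 2,355 samples at 7:2:1 yield exactly
#' (1648, 471, 236).
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels Optional integer labels (same length); when supplied the
#'   class mix of every subset matches the corpus as closely as the floor
#'   rule allows.
#' @param ratios Three non-negative numbers summing to 10 (default
#'   `c(7, 2, 1)`).
#' @param seed Shuffling seed.
#' @param groups Optional grouping vector (same length), e.g. the species
#'   id of each augmented document. When supplied, the *groups* are split
#'   7:2:1 (floor rule on the group count, stratified by the group label)
#'   and every sample inherits its group's subset, so no group straddles
#'   two subsets. Use this to measure generalisation to unseen species
#'   rather than to unseen resamples of a seen species.
#' @return A tibble of class `dataset_split` with columns `sample_id` and
#'   `split` (factor train/validation/test), plus `label` when given.
#' @export
split_dataset <- function(sample_ids, labels = NULL, ratios = c(7, 2, 1), seed = 1L,
                          groups = NULL) {
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(sample_ids))
    gu <- unique(groups)
    glab <- NULL
    if (!is.null(labels)) {
      glab <- vapply(gu, function(g) {
        l <- unique(labels[groups == g])
        if (length(l) != 1L) abort("labels differ within a group")
        l
      }, labels[1])
    }
    gsplit <- split_dataset(gu, glab, ratios = ratios, seed = seed)
    out <- tibble::tibble(
      sample_id = sample_ids,
      split = gsplit$split[match(groups, gsplit$sample_id)]
    )
    if (!is.null(labels)) out$label <- labels
    attr(out, "seed") <- as.integer(seed)
    attr(out, "ratios") <- ratios
    class(out) <- c("dataset_split", class(out))
    return(out)
  }
  n <- length(sample_ids)
  if (n < 3L) abort("need at least 3 samples to split")
  if (length(ratios) != 3L || any(ratios < 0) || sum(ratios) != 10) {
    abort("`ratios` must be three non-negative numbers summing to 10")
  }
  if (anyDuplicated(sample_ids)) abort("duplicated sample ids")
  n_train <- floor(ratios[1] / 10 * n)
  n_val <- floor(ratios[2] / 10 * n)

  assign_one <- function(ids, k_train, k_val) {
    sh <- sample(ids)
    rep(c("train", "validation", "test"),
        c(k_train, k_val, length(ids) - k_train - k_val)) |>
      setNames(sh)
  }

  withr::with_seed(seed, {
    if (is.null(labels)) {
      assignment <- assign_one(sample_ids, n_train, n_val)
    } else {
      stopifnot(length(labels) == n)
      classes <- sort(unique(labels))
      n_c <- vapply(classes, function(cl) sum(labels == cl), integer(1))
      alloc <- function(total, n_c, cap) {
        base <- floor(total * n_c / n)
        base <- pmin(base, cap)
        frac <- total * n_c / n - floor(total * n_c / n)
        ord <- order(-frac, seq_along(n_c))
        i <- 1L
        while (sum(base) < total) {
          cl <- ord[(i - 1L) %% length(ord) + 1L]
          if (base[cl] < cap[cl]) base[cl] <- base[cl] + 1L
          i <- i + 1L
        }
        base
      }
      t_c <- alloc(n_train, n_c, n_c)
      v_c <- alloc(n_val, n_c, n_c - t_c)
      assignment <- character(0)
      for (ci in seq_along(classes)) {
        ids_c <- sample_ids[labels == classes[ci]]
        assignment <- c(assignment, assign_one(ids_c, t_c[ci], v_c[ci]))
      }
    }
  })

  out <- tibble::tibble(
    sample_id = names(assignment),
    split = factor(assignment, levels = c("train", "validation", "test"))
  )
  if (!is.null(labels)) {
    out$label <- labels[match(out$sample_id, sample_ids)]
  }
  out <- dplyr::arrange(out, match(.data$sample_id, sample_ids))
  attr(out, "seed") <- as.integer(seed)
  attr(out, "ratios") <- ratios
  class(out) <- c("dataset_split", class(out))
  out
}

#' Sample ids belonging to one subset of a split
#'
#' @param split A `dataset_split` tibble.
#' @param which One of `"train"`, `"validation"`, `"test"`.
#' @return Character vector of sample ids.
#' @export
split_ids <- function(split, which = c("train", "validation", "test")) {
  which <- match.arg(which)
  split$sample_id[split$split == which]
}

#' Write a document corpus as JSON lines
#'
#' One JSON object per line with the sample id, species, label, sampling
#' seed, and the per-slot gene ids and token ids.
#'
#' @param corpus Corpus tibble from [build_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    doc <- corpus$document[[i]]
    writeLines(jsonlite::toJSON(
      list(
        sample_id = doc$sample_id, species_id = doc$species_id,
        label = doc$label, sampling_seed = doc$sampling_seed,
        gene_ids = doc$gene_ids, sentences = doc$sentences
      ),
      auto_unbox = TRUE, null = "null", na = "null"
    ), con)
  }
  invisible(path)
}
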