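# From attention matrices to the headline output: a per-orthogroup weight
# table and the top-fraction candidate selection.

#' Collapse an attention matrix to per-position sentence weights
#'
#' The weight of sentence position j is the mean attention it receives over
#' all unmasked query positions, `w_j = mean_i a_ij`; masked positions carry
#' exactly zero weight (their columns are zeroed before the softmax).
#'
#' @param attention_output An `attention_output` from [attention()], or a
#'   row-stochastic weight matrix.
#' @param mask Logical mask when a bare matrix is given.
#' @return Numeric weight vector, one entry per sentence position.
#' @export
sentence_weights <- function(attention_output, mask = NULL) {
  if (inherits(attention_output, "attention_output")) {
    A <- attention_output$weights
    mask <- attention_output$mask
  } else {
    A <- attention_output
    if (is.null(mask)) mask <- rep(TRUE, nrow(A))
  }
  colMeans(A[mask, , drop = FALSE])
}

#' Aggregate per-sample sentence weights into an orthogroup weight table
#'
#' Averages the per-document weight vectors position-wise across samples,
#' then min-max normalises the averages to `[0, 1]`. If every orthogroup
#' receives the same average weight (degenerate min = max), all weights are
#' reported as 0.
#'
#' @param weight_matrix A samples x orthogroups matrix of per-document
#'   sentence weights (rows in canonical orthogroup order), or a list of
#'   such vectors.
#' @param orthogroup_ids Orthogroup ids in canonical order.
#' @return A tibble of class `og_weight_table` with columns
#'   `orthogroup_id`, `weight`, `rank` (1 = highest weight), sorted by rank;
#'   the number of aggregated samples is kept in the `n_samples` attribute.
#' @export
aggregate_weights <- function(weight_matrix, orthogroup_ids) {
  if (is.list(weight_matrix)) weight_matrix <- do.call(rbind, weight_matrix)
  if (is.null(dim(weight_matrix))) weight_matrix <- matrix(weight_matrix, nrow = 1L)
  if (nrow(weight_matrix) == 0L) abort("no samples to aggregate")
  if (ncol(weight_matrix) != length(orthogroup_ids)) {
    abort("weight vectors and `orthogroup_ids` have different lengths")
  }
  avg <- colMeans(weight_matrix)
  rng <- range(avg)
  weight <- if (rng[1] == rng[2]) rep(0, length(avg)) else (avg - rng[1]) / (rng[2] - rng[1])
  out <- tibble::tibble(orthogroup_id = orthogroup_ids, weight = weight) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$orthogroup_id) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "n_samples") <- nrow(weight_matrix)
  class(out) <- c("og_weight_table", class(out))
  out
}

#' Select the top fraction of orthogroups by weight
#'
#' Keeps the `floor(fraction * N)` highest-weight orthogroups (at least one
#' when the floor is zero would leave the selection empty is *not* padded:
#' the floor rule is applied verbatim, so a 27,883-row table at fraction
#' 0.05 selects exactly 1,394 orthogroups). Ties at the cut are broken by
#' lexicographically smallest orthogroup id. When an orthogroup membership
#' table is supplied, the member genes of the selected orthogroups are
#' enumerated as candidate genes.
#'
#' @param weight_table An `og_weight_table`.
#' @param fraction Fraction of orthogroups to keep, in `(0, 1]` (default
#'   0.05).
#' @param orthogroups Optional long membership tibble used to enumerate
#'   candidate genes.
#' @return A list of class `selection_result` with `fraction`,
#'   `n_selected`, `selected` (tibble of selected orthogroups with weights
#'   and ranks) and `candidate_genes` (tibble of `orthogroup_id`,
#'   `species_id`, `gene_id`, or `NULL`).
#' @export
select_top_fraction <- function(weight_table, fraction = 0.05, orthogroups = NULL) {
  if (nrow(weight_table) == 0L) abort("empty weight table")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1]")
  }
  n_sel <- as.integer(floor(fraction * nrow(weight_table)))
  ordered <- weight_table |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$orthogroup_id)
  selected <- utils::head(ordered, n_sel)
  candidates <- NULL
  if (!is.null(orthogroups)) {
    candidates <- orthogroups |>
      dplyr::filter(.data$orthogroup_id %in% selected$orthogroup_id) |>
      dplyr::select("orthogroup_id", "species_id", "gene_id") |>
      dplyr::arrange(.data$orthogroup_id, .data$species_id, .data$gene_id)
  }
  structure(
    list(
      fraction = fraction, n_selected = n_sel,
      selected = selected, candidate_genes = candidates
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> top %.1f%%: %d orthogroup(s)%s\n",
    100 * x$fraction, x$n_selected,
    if (!is.null(x$candidate_genes)) {
      sprintf(", %d candidate gene(s)", nrow(x$candidate_genes))
    } else ""
  ))
  invisible(x)
}

#' Score a corpus and build the orthogroup weight table
#'
#' Runs every document through the fitted model, collapses each attention
#' matrix to per-orthogroup sentence weights, and aggregates across
#' samples. Optionally restricts aggregation to correctly classified
#' winged samples.
#'
#' @param model A fitted `wing_model`.
#' @param corpus Corpus tibble.
#' @param embedding The training `kmer_embedding`.
#' @param orthogroup_ids Selected orthogroup ids in canonical order.
#' @param samples Which samples to aggregate: `"all"` (default) or
#'   `"correct_winged"` (correctly classified winged samples only).
#' @return An `og_weight_table`.
#' @export
score_orthogroups <- function(model, corpus, embedding, orthogroup_ids,
                              samples = c("all", "correct_winged")) {
  samples <- match.arg(samples)
  inf <- infer_corpus(model, corpus, embedding, collect = TRUE)
  keep <- rep(TRUE, length(inf$p))
  if (samples == "correct_winged") {
    keep <- inf$y == 1L & inf$p >= 0.5
    if (!any(keep)) abort("no correctly classified winged samples to aggregate")
  }
  aggregate_weights(inf$sentence_weights[keep, , drop = FALSE], orthogroup_ids)
}

#' Write an orthogroup weight table as TSV
#'
#' @param weight_table An `og_weight_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weight_table, path) {
  readr::write_tsv(weight_table[, c("orthogroup_id", "weight", "rank")], path)
  invisible(path)
}
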