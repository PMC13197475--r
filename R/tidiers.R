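# broom-style accessors and ggplot2 methods for the fitted objects.

#' Tidy a fitted model's training history
#'
#' @param x A `wing_model`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`,
#'   `train_acc`, `val_loss`, `val_acc`).
#' @method tidy wing_model
#' @export
tidy.wing_model <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `wing_model`.
#' @param ... Unused.
#' @return A one-row tibble: epochs trained, best validation epoch and its
#'   loss/accuracy, and the architecture widths.
#' @method glance wing_model
#' @export
glance.wing_model <- function(x, ...) {
  best <- x$history[x$history$epoch == x$best_epoch, ]
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    val_loss = if (nrow(best)) best$val_loss else NA_real_,
    val_accuracy = if (nrow(best)) best$val_acc else NA_real_,
    embedding_dim = x$config$embedding_dim,
    hidden_size = x$config$hidden_size,
    d_k = x$config$d_k
  )
}

#' Tidy a top-fraction selection
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return The tibble of selected orthogroups (`orthogroup_id`, `weight`,
#'   `rank`).
#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) x$selected

#' One-row summary of a top-fraction selection
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A one-row tibble with the fraction, the number of selected
#'   orthogroups and of candidate genes.
#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    fraction = x$fraction,
    n_selected = x$n_selected,
    n_candidate_genes = if (is.null(x$candidate_genes)) NA_integer_ else nrow(x$candidate_genes)
  )
}

#' Tidy a pipeline result
#'
#' @param x A `wing_pipeline`.
#' @param ... Unused.
#' @return The orthogroup weight table.
#' @method tidy wing_pipeline
#' @export
tidy.wing_pipeline <- function(x, ...) x$weight_table

#' One-row summary of a pipeline run
#'
#' @param x A `wing_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble: corpus and selection counts, test metrics and
#'   AUC.
#' @method glance wing_pipeline
#' @export
glance.wing_pipeline <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      n_species = nrow(x$species),
      n_orthogroups_selected = sum(x$selection$selected),
      n_documents = nrow(x$corpus),
      n_top_orthogroups = x$top_selection$n_selected
    ),
    x$evaluation$metrics
  )
}

#' Plot training and validation curves
#'
#' Loss and accuracy per epoch for the training and validation sets, with
#' the best validation epoch marked.
#'
#' @param object A `wing_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wing_model
#' @export
autoplot.wing_model <- function(object, ...) {
  h <- object$history |>
    tidyr::pivot_longer(-"epoch", names_to = c("set", "metric"),
                        names_sep = "_", values_to = "value") |>
    dplyr::mutate(
      set = dplyr::recode(.data$set, train = "training", val = "validation"),
      metric = dplyr::recode(.data$metric, acc = "accuracy")
    )
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$value, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the orthogroup weight distribution
#'
#' Histogram of the normalised attention weights with the top-fraction
#' cut marked.
#'
#' @param object An `og_weight_table`.
#' @param fraction Fraction whose cut to mark (default 0.05).
#' @param bins Histogram bins (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot og_weight_table
#' @export
autoplot.og_weight_table <- function(object, fraction = 0.05, bins = 50, ...) {
  n_sel <- floor(fraction * nrow(object))
  cut <- if (n_sel >= 1L) sort(object$weight, decreasing = TRUE)[n_sel] else Inf
  ggplot2::ggplot(object, ggplot2::aes(.data$weight)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = cut, linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "normalised attention weight", y = "orthogroups",
      title = sprintf("Top %.0f%% cut at weight %.3f", 100 * fraction, cut)
    ) +
    ggplot2::theme_minimal()
}

#' Plot layer features in two principal components
#'
#' Projects exported layer features to their first two principal components
#' (a light-weight stand-in for an external t-SNE), coloured by class.
#'
#' @param object A `layer_features` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot layer_features
#' @export
autoplot.layer_features <- function(object, ...) {
  mat <- as.matrix(object[, grep("^f\\d+$", names(object))])
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  df <- tibble::tibble(
    pc1 = pc$x[, 1], pc2 = pc$x[, 2],
    class = factor(object$label, levels = c(0, 1),
                   labels = c("wingless (0)", "winged (1)"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "PC1", y = "PC2", colour = NULL,
      title = sprintf("%s-layer features", attr(object, "layer"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param roc ROC points tibble from [roc_auc()] (or the list it returns).
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  if (is.list(roc) && !is.data.frame(roc)) roc <- roc$roc
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
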