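#' CBOW training configuration
#'
#' Hyper-parameters for continuous bag-of-words (CBOW) embedding training.
#' The embedding dimension defaults to 150 and the context window to 5
#' tokens each side; training uses negative-sampling logistic loss with a
#' linearly decaying learning rate, the standard word2vec recipe.
#'
#' @param dim Embedding dimension `d` (default 150).
#' @param window Context half-width `c` in tokens (default 5).
#' @param epochs Training passes over the corpus (default 5).
#' @param learning_rate Initial learning rate (default 0.025, linear decay).
#' @param negative Negative samples per center token (default 5).
#' @param batch_size Mini-batch size in center tokens (default 1024).
#' @param max_examples Optional cap on the number of (center, context)
#'   examples per epoch; a seeded subsample is used when the corpus exceeds
#'   it.
#' @param seed Integer seed; training is bitwise reproducible given the seed.
#' @return A list of class `cbow_config`.
#' @export
cbow_config <- function(dim = 150L, window = 5L, epochs = 5L,
                        learning_rate = 0.025, negative = 5L,
                        batch_size = 1024L, max_examples = NULL, seed = 1L) {
  if (dim < 1L || window < 1L) abort("`dim` and `window` must be >= 1")
  if (learning_rate <= 0) abort("`learning_rate` must be positive")
  structure(
    list(
      dim = as.integer(dim), window = as.integer(window),
      epochs = as.integer(epochs), learning_rate = learning_rate,
      negative = as.integer(negative), batch_size = as.integer(batch_size),
      max_examples = max_examples, seed = as.integer(seed)
    ),
    class = "cbow_config"
  )
}

#' Average the embedding vectors of a context window
#'
#' The CBOW context representation: the arithmetic mean of the embedding
#' rows of the context tokens. Full interior windows divide by `2c`;
#' boundary windows carry fewer context tokens and divide by the actual
#' count.
#'
#' @param context_ids Integer token ids of the context tokens (center
#'   excluded).
#' @param embedding Embedding matrix (rows indexed by token id + 1).
#' @return A numeric vector of length `ncol(embedding)`.
#' @export
context_vector <- function(context_ids, embedding) {
  if (length(context_ids) == 0L) abort("context window contains no tokens")
  colMeans(embedding[context_ids + 1L, , drop = FALSE])
}

# Build the (center, padded-context) example arrays for a tokenized corpus.
# Sentences are separated by `window` PAD tokens so a single global shift
# never leaks context across sentence boundaries; PAD context slots point at
# the frozen all-zero PAD row and are excluded from the mean via the count.
cbow_examples <- function(corpus, window) {
  gap <- rep(PAD_ID, window)
  stream <- unlist(lapply(corpus, function(s) c(s, gap)), use.names = FALSE)
  stream <- c(gap, stream)
  centers_pos <- which(stream != PAD_ID)
  shifts <- setdiff(seq.int(-window, window), 0L)
  ctx <- vapply(shifts, function(j) stream[centers_pos + j], integer(length(centers_pos)))
  if (is.null(dim(ctx))) ctx <- matrix(ctx, nrow = length(centers_pos))
  counts <- rowSums(ctx != PAD_ID)
  keep <- counts > 0L
  list(
    centers = stream[centers_pos][keep],
    context = ctx[keep, , drop = FALSE],
    counts = counts[keep]
  )
}

#' Train CBOW embeddings over a tokenized corpus
#'
#' Learns one d-dimensional vector per vocabulary token by predicting each
#' center token from the mean of its context vectors, with negative-sampling
#' logistic loss (negatives drawn from the unigram distribution raised to
#' 3/4). The PAD row is frozen at zero throughout. Training is deterministic
#' given `config$seed`.
#'
#' @param corpus List of integer token-id vectors (one per gene sentence).
#' @param vocab The `kmer_vocab` the corpus was segmented with.
#' @param config A [cbow_config()].
#' @return A `vocab_size(vocab)` x `dim` matrix of class `kmer_embedding`,
#'   row names `<PAD>`, `<UNK>`, then the vocabulary tokens; the per-epoch
#'   mean negative-sampling loss is attached as attribute `history`.
#' @export
train_cbow <- function(corpus, vocab, config = cbow_config()) {
  if (length(corpus) == 0L) abort("empty corpus")
  V <- vocab_size(vocab)
  d <- config$dim
  ex <- cbow_examples(corpus, config$window)
  n_ex <- length(ex$centers)
  if (n_ex == 0L) abort("corpus has no usable context windows")

  # Unigram^0.75 negative-sampling distribution over non-PAD ids.
  counts <- tabulate(ex$centers + 1L, nbins = V)
  neg_ids <- which(counts > 0L) - 1L
  neg_prob <- counts[counts > 0L]^0.75
  neg_prob <- neg_prob / sum(neg_prob)

  w_in <- NULL
  w_out <- matrix(0, V, d)
  history <- numeric(config$epochs)
  n_cols_ctx <- ncol(ex$context)

  withr::with_seed(config$seed, {
    w_in <- matrix(runif(V * d, -0.5, 0.5) / d, V, d)
    w_in[PAD_ID + 1L, ] <- 0

    epoch_n <- if (!is.null(config$max_examples)) min(n_ex, config$max_examples) else n_ex
    total_batches <- max(1L, config$epochs * ceiling(epoch_n / config$batch_size))
    batch_no <- 0L

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_ex, epoch_n)
      loss_sum <- 0
      loss_n <- 0L
      for (start in seq.int(1L, epoch_n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, epoch_n)]
        B <- length(idx)
        lr <- config$learning_rate * max(1e-4, 1 - batch_no / total_batches)
        batch_no <- batch_no + 1L

        ctx <- ex$context[idx, , drop = FALSE]
        cnt <- ex$counts[idx]
        grp <- rep.int(seq_len(B), n_cols_ctx)
        h <- rowsum(w_in[as.vector(ctx) + 1L, , drop = FALSE], grp, reorder = TRUE) / cnt

        negs <- matrix(
          sample(neg_ids, B * config$negative, replace = TRUE, prob = neg_prob),
          B, config$negative
        )
        outs <- cbind(ex$centers[idx], negs)
        labels <- c(1, rep(0, config$negative))

        g <- matrix(0, B, ncol(outs))
        dh <- matrix(0, B, d)
        for (j in seq_len(ncol(outs))) {
          rows_j <- outs[, j] + 1L
          s <- rowSums(h * w_out[rows_j, , drop = FALSE])
          p <- sigmoid(s)
          loss_sum <- loss_sum + sum(-log(pmax(if (labels[j] == 1) p else 1 - p, 1e-10)))
          g[, j] <- p - labels[j]
          dh <- dh + g[, j] * w_out[rows_j, , drop = FALSE]
        }
        loss_n <- loss_n + B

        # Output-matrix update: scatter-add the per-example outer products.
        out_rows <- as.vector(outs) + 1L
        out_grp <- rep.int(seq_len(B), ncol(outs))
        upd <- rowsum(h[out_grp, , drop = FALSE] * as.vector(g), out_rows)
        ui <- as.integer(rownames(upd))
        w_out[ui, ] <- w_out[ui, ] - lr * upd

        # Input-matrix update: each real context token receives dh / count.
        ctx_rows <- as.vector(ctx) + 1L
        gin <- (dh / cnt)[grp, , drop = FALSE]
        upd_in <- rowsum(gin, ctx_rows)
        ui <- as.integer(rownames(upd_in))
        w_in[ui, ] <- w_in[ui, ] - lr * upd_in
        w_in[PAD_ID + 1L, ] <- 0
      }
      history[epoch] <- loss_sum / max(loss_n, 1L)
    }
  })

  rownames(w_in) <- c("<PAD>", "<UNK>", vocab$tokens)
  structure(w_in, class = c("kmer_embedding", "matrix", "array"),
            k = vocab$k, history = history)
}

#' Look up the embedding rows of a token sequence
#'
#' Maps a token-id vector to the matrix of its embedding vectors, one row
#' per token (PAD rows are zero).
#'
#' @param token_ids Integer token ids.
#' @param embedding A `kmer_embedding` (or any matrix indexed by id + 1).
#' @return A `length(token_ids)` x `d` numeric matrix.
#' @export
embed_document <- function(token_ids, embedding) {
  if (length(token_ids) == 0L) {
    return(matrix(numeric(0), 0L, ncol(embedding)))
  }
  if (any(token_ids < 0L) || any(token_ids + 1L > nrow(embedding))) {
    abort("token id out of embedding range")
  }
  unname(embedding[token_ids + 1L, , drop = FALSE])
}

#' Write an embedding matrix in word2vec text format
#'
#' First line `"<vocab_size> <dim>"`, then one line per token:
#' `token v1 ... vd`.
#'
#' @param embedding A `kmer_embedding` with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(embedding), ncol(embedding)), con)
  lines <- paste(
    rownames(embedding),
    apply(embedding, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read an embedding matrix in word2vec text format
#'
#' @param path Path written by [write_embedding()].
#' @return A `kmer_embedding` matrix with token row names.
#' @export
read_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(mat) <- tokens
  structure(mat, class = c("kmer_embedding", "matrix", "array"))
}
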