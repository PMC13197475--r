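# The classifier: sentence pooling -> BiLSTM -> self-attention -> masked
# mean of context vectors -> dropout -> affine head -> sigmoid probability
# of the winged class. Trained with binary cross-entropy and Adam.

#' Model configuration
#'
#' Architecture and training hyper-parameters. The embedding dimension
#' follows the pre-trained CBOW vectors (150 by default); the Adam learning
#' rate defaults to 0.001. Dropout (on the document representation) and
#' early stopping on validation loss guard against overfitting.
#'
#' @param embedding_dim Input sentence-vector dimension d (default 150).
#' @param hidden_size LSTM hidden width H per direction (default 128).
#' @param d_k Attention query/key projection width (default `hidden_size`).
#' @param dropout Dropout rate on the document representation, in `[0, 1)`
#'   (default 0.3); active only during training.
#' @param sentence_dropout Optional fraction of real sentence slots hidden
#'   (masked and zeroed) per document per training batch, in `[0, 1)`
#'   (default 0, i.e. off). Hiding slots discourages the attention from
#'   relying on a small subset of orthogroups; inactive at inference.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience: training stops once validation
#'   loss has failed to improve for more than `patience` consecutive epochs,
#'   and the best-validation weights are restored (default 5).
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return A list of class `wing_model_config`.
#' @export
model_config <- function(embedding_dim = 150L, hidden_size = 128L,
                         d_k = hidden_size, dropout = 0.3,
                         sentence_dropout = 0,
                         learning_rate = 0.001, batch_size = 32L,
                         max_epochs = 100L, patience = 5L, seed = 1L) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1)")
  if (sentence_dropout < 0 || sentence_dropout >= 1) {
    abort("`sentence_dropout` must be in [0, 1)")
  }
  if (d_k <= 0) abort("`d_k` must be positive")
  structure(
    list(
      embedding_dim = as.integer(embedding_dim),
      hidden_size = as.integer(hidden_size), d_k = as.integer(d_k),
      dropout = dropout, sentence_dropout = sentence_dropout,
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
      patience = as.integer(patience), seed = as.integer(seed)
    ),
    class = "wing_model_config"
  )
}

# Glorot-uniform initialisation; LSTM forget-gate biases start at 1, the
# classification head at zero (an untrained model outputs exactly 0.5).
init_params <- function(config) {
  d <- config$embedding_dim
  H <- config$hidden_size
  glorot <- function(nr, nc) {
    r <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -r, r), nr, nc)
  }
  lstm_dir <- function() {
    b <- numeric(4L * H)
    b[seq_len(H)] <- 1
    list(W = glorot(H + d, 4L * H), b = b)
  }
  list(
    fwd = lstm_dir(),
    bwd = lstm_dir(),
    WQ = glorot(2L * H, config$d_k),
    WK = glorot(2L * H, config$d_k),
    w = numeric(2L * H),
    b0 = 0
  )
}

# Recursive elementwise map over nested parameter lists.
pmap_params <- function(lists, f) {
  first <- lists[[1]]
  if (is.list(first)) {
    out <- vector("list", length(first))
    names(out) <- names(first)
    for (i in seq_along(first)) {
      out[[i]] <- pmap_params(lapply(lists, `[[`, i), f)
    }
    out
  } else {
    do.call(f, lists)
  }
}

#' Precompute network inputs for a document corpus
#'
#' Pools every document's tokenized sentences into its sentence-vector
#' matrix (mean of non-PAD token embeddings per orthogroup slot; EMPTY
#' slots are zero and masked) and stacks the corpus into the arrays the
#' network consumes.
#'
#' @param corpus Corpus tibble from [build_corpus()].
#' @param embedding A `kmer_embedding` matrix.
#' @return A list with `X` (B x n x d array), `mask` (B x n logical),
#'   `y` (labels), `sample_ids`.
#' @export
document_inputs <- function(corpus, embedding) {
  d <- ncol(embedding)
  B <- nrow(corpus)
  n <- length(corpus$document[[1]]$sentences)
  X <- array(0, c(B, n, d))
  maskM <- matrix(FALSE, B, n)
  for (b in seq_len(B)) {
    doc <- corpus$document[[b]]
    if (length(doc$sentences) != n) abort("documents have differing sentence counts")
    lens <- lengths(doc$sentences)
    ids <- unlist(doc$sentences, use.names = FALSE)
    slot <- rep.int(seq_len(n), lens)
    keep <- ids != PAD_ID
    if (any(keep)) {
      sums <- rowsum(embedding[ids[keep] + 1L, , drop = FALSE], slot[keep])
      counts <- tabulate(slot[keep], n)
      present <- as.integer(rownames(sums))
      X[b, present, ] <- sums / counts[present]
      maskM[b, present] <- TRUE
    }
  }
  list(X = X, mask = maskM, y = corpus$label, sample_ids = corpus$sample_id)
}

# Per-dimension standardisation of the sentence vectors, fitted on the
# training documents and stored in the model: CBOW means are small and
# anisotropic, and the recurrence trains poorly on raw scale. EMPTY
# (masked) slots stay exactly zero.
fit_input_scaling <- function(X, maskM) {
  d <- dim(X)[3]
  Xm <- matrix(X, prod(dim(X)[1:2]), d)
  rows <- as.vector(maskM)
  mu <- colMeans(Xm[rows, , drop = FALSE])
  sd_ <- pmax(apply(Xm[rows, , drop = FALSE], 2L, stats::sd), 1e-8)
  list(center = mu, scale = sd_)
}

apply_input_scaling <- function(inputs, scaling) {
  if (is.null(scaling)) return(inputs)
  dims <- dim(inputs$X)
  Xm <- matrix(inputs$X, prod(dims[1:2]), dims[3])
  rows <- as.vector(inputs$mask)
  Xm[rows, ] <- sweep(
    sweep(Xm[rows, , drop = FALSE], 2L, scaling$center, "-"),
    2L, scaling$scale, "/"
  )
  inputs$X <- array(Xm, dims)
  inputs
}

# Full forward pass over a batch. `drop_mask` (B x 2H in {0,1}) is supplied
# by the training loop when dropout is active. With `collect = TRUE` the
# per-document attention weight vectors (mean over unmasked queries) and
# layer summaries are returned for scoring and feature extraction.
network_forward <- function(X, maskM, params, dropout = 0, drop_mask = NULL,
                            collect = FALSE) {
  B <- dim(X)[1]
  n <- dim(X)[2]
  H <- length(params$fwd$b) / 4L
  # C++ engine layout: rows = documents, columns = features, slices = positions
  Xp <- aperm(X, c(1L, 3L, 2L))
  fwdF <- lstm_forward_cpp(Xp, params$fwd$W, params$fwd$b, FALSE)
  bwdF <- lstm_forward_cpp(Xp, params$bwd$W, params$bwd$b, TRUE)

  Hmats <- vector("list", B)
  att <- vector("list", B)
  R <- matrix(0, B, 2L * H)
  W_sent <- if (collect) matrix(0, B, n) else NULL
  H_pool <- if (collect) matrix(0, B, 2L * H) else NULL
  for (b in seq_len(B)) {
    m <- maskM[b, ]
    if (!any(m)) abort("document with zero unmasked sentences")
    Hmat <- cbind(
      t(matrix(fwdF$H[b, , ], H, n)),
      t(matrix(bwdF$H[b, , ], H, n))
    )
    a <- attention_forward(Hmat, params$WQ, params$WK, m)
    R[b, ] <- colMeans(a$C[m, , drop = FALSE])
    Hmats[[b]] <- Hmat
    att[[b]] <- a
    if (collect) {
      W_sent[b, ] <- colMeans(a$A[m, , drop = FALSE])
      H_pool[b, ] <- colMeans(Hmat[m, , drop = FALSE])
    }
  }
  R_drop <- R
  if (dropout > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(rbinom(length(R), 1L, 1 - dropout), nrow(R), ncol(R))
    }
    R_drop <- R * drop_mask / (1 - dropout)
  }
  z <- drop(R_drop %*% params$w) + params$b0
  p <- sigmoid(z)
  list(
    p = p, z = z, R = R, R_drop = R_drop, drop_mask = drop_mask,
    Hmats = Hmats, att = att, fwdF = fwdF, bwdF = bwdF, Xp = Xp,
    sentence_weights = W_sent, bilstm_pooled = H_pool
  )
}

# Backward pass matching network_forward; returns gradients in the shape of
# the parameter list. Loss is mean binary cross-entropy over the batch.
network_backward <- function(fp, X, maskM, y, params, dropout = 0) {
  B <- dim(X)[1]
  n <- dim(X)[2]
  H <- length(params$fwd$b) / 4L
  dz <- (fp$p - y) / B
  dw <- drop(crossprod(fp$R_drop, dz))
  db0 <- sum(dz)
  dR <- outer(dz, params$w)
  if (dropout > 0) dR <- dR * fp$drop_mask / (1 - dropout)

  dWQ <- matrix(0, nrow(params$WQ), ncol(params$WQ))
  dWK <- matrix(0, nrow(params$WK), ncol(params$WK))
  dHf <- array(0, c(B, H, n))
  dHb <- array(0, c(B, H, n))
  for (b in seq_len(B)) {
    m <- maskM[b, ]
    dC <- matrix(0, n, 2L * H)
    dC[m, ] <- matrix(dR[b, ], sum(m), 2L * H, byrow = TRUE) / sum(m)
    bk <- attention_backward(dC, fp$Hmats[[b]], params$WQ, params$WK, fp$att[[b]])
    dWQ <- dWQ + bk$dWQ
    dWK <- dWK + bk$dWK
    dHf[b, , ] <- t(bk$dH[, seq_len(H), drop = FALSE])
    dHb[b, , ] <- t(bk$dH[, H + seq_len(H), drop = FALSE])
  }
  gf <- lstm_backward_cpp(dHf, fp$Xp, params$fwd$W, fp$fwdF)
  gb <- lstm_backward_cpp(dHb, fp$Xp, params$bwd$W, fp$bwdF)
  list(
    fwd = list(W = gf$dW, b = drop(gf$db)),
    bwd = list(W = gb$dW, b = drop(gb$db)),
    WQ = dWQ, WK = dWK, w = dw, b0 = db0
  )
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Thin wrappers around the compiled engine (hot paths). The R-level
# network_forward/network_backward implement the identical computation and
# serve as the cross-checked reference.
cpp_forward <- function(X, maskM, params, collect = FALSE) {
  Xp <- aperm(X, c(1L, 3L, 2L))
  storage.mode(maskM) <- "integer"
  fp <- network_forward_cpp(
    Xp, maskM, params$fwd$W, params$fwd$b, params$bwd$W, params$bwd$b,
    params$WQ, params$WK, params$w, params$b0, collect
  )
  fp$p <- drop(fp$p)
  fp
}

cpp_grad_step <- function(batch, params, dropout, drop_mask) {
  Xp <- aperm(batch$X, c(1L, 3L, 2L))
  mk <- batch$mask
  storage.mode(mk) <- "integer"
  st <- network_grad_cpp(
    Xp, mk, params$fwd$W, params$fwd$b, params$bwd$W, params$bwd$b,
    params$WQ, params$WK, params$w, params$b0,
    as.numeric(batch$y), dropout, drop_mask
  )
  st$p <- drop(st$p)
  st$grads$fwd$b <- drop(st$grads$fwd$b)
  st$grads$bwd$b <- drop(st$grads$bwd$b)
  st$grads$w <- drop(st$grads$w)
  st
}

#' Fit the classifier on a split corpus
#'
#' Trains the BiLSTM-attention network with the Adam optimiser on binary
#' cross-entropy, monitoring validation loss for early stopping. Dropout is
#' active only during training; the weights from the best validation epoch
#' are restored at the end. Fully deterministic given `config$seed`.
#'
#' @param corpus Corpus tibble from [build_corpus()].
#' @param embedding A `kmer_embedding` matrix (frozen during training).
#' @param split A `dataset_split` over the corpus sample ids.
#' @param config A [model_config()]; `embedding_dim` must match the
#'   embedding.
#' @return An object of class `wing_model` with elements `params`,
#'   `config`, `history` (per-epoch loss/accuracy tibble), `best_epoch`,
#'   `n_slots`.
#' @export
fit_wing_model <- function(corpus, embedding, split, config = model_config()) {
  if (config$embedding_dim != ncol(embedding)) {
    abort("`config$embedding_dim` does not match the embedding matrix")
  }
  inputs <- document_inputs(corpus, embedding)
  tr <- which(inputs$sample_ids %in% split_ids(split, "train"))
  va <- which(inputs$sample_ids %in% split_ids(split, "validation"))
  if (length(tr) == 0L || length(va) == 0L) {
    abort("training and validation sets must be non-empty")
  }
  scaling <- fit_input_scaling(
    inputs$X[tr, , , drop = FALSE], inputs$mask[tr, , drop = FALSE]
  )
  inputs <- apply_input_scaling(inputs, scaling)

  sub <- function(idx) {
    list(
      X = inputs$X[idx, , , drop = FALSE],
      mask = inputs$mask[idx, , drop = FALSE],
      y = inputs$y[idx]
    )
  }
  val <- sub(va)

  params <- NULL
  history <- vector("list", config$max_epochs)
  best <- list(loss = Inf, params = NULL, epoch = 0L)

  withr::with_seed(config$seed, {
    params <- init_params(config)
    adam_m <- pmap_params(list(params), function(p) p * 0)
    adam_v <- adam_m
    adam_t <- 0L
    bad_epochs <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(tr)
      tl_sum <- 0
      tc_sum <- 0
      for (start in seq.int(1L, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        batch <- sub(idx)
        if (config$sentence_dropout > 0) {
          B_b <- length(idx)
          n_b <- ncol(batch$mask)
          keep <- matrix(
            rbinom(B_b * n_b, 1L, 1 - config$sentence_dropout), B_b, n_b
          ) == 1L
          newmask <- batch$mask & keep
          empty <- rowSums(newmask) == 0L
          newmask[empty, ] <- batch$mask[empty, ]
          hidden <- batch$mask & !newmask
          if (any(hidden)) {
            Xm <- matrix(batch$X, B_b * n_b, dim(batch$X)[3])
            Xm[as.vector(hidden), ] <- 0
            batch$X <- array(Xm, dim(batch$X))
          }
          batch$mask <- newmask
        }
        drop_mask <- if (config$dropout > 0) {
          matrix(
            rbinom(length(idx) * 2L * config$hidden_size, 1L, 1 - config$dropout),
            length(idx), 2L * config$hidden_size
          )
        } else {
          matrix(1, 1, 1)
        }
        st <- cpp_grad_step(batch, params, config$dropout, drop_mask)
        if (!is.finite(st$loss)) {
          abort(sprintf("training diverged (non-finite loss at epoch %d)", epoch))
        }
        tl_sum <- tl_sum + st$loss * length(idx)
        tc_sum <- tc_sum + sum((st$p >= 0.5) == (batch$y == 1L))
        grads <- st$grads
        adam_t <- adam_t + 1L
        b1 <- 0.9
        b2 <- 0.999
        adam_m <- pmap_params(list(adam_m, grads), function(m, g) b1 * m + (1 - b1) * g)
        adam_v <- pmap_params(list(adam_v, grads), function(v, g) b2 * v + (1 - b2) * g^2)
        corr <- config$learning_rate * sqrt(1 - b2^adam_t) / (1 - b1^adam_t)
        params <- pmap_params(
          list(params, adam_m, adam_v),
          function(p, m, v) p - corr * m / (sqrt(v) + 1e-8)
        )
      }

      vp <- cpp_forward(val$X, val$mask, params)$p
      val_loss <- bce_loss(vp, val$y)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_loss = tl_sum / length(tr),
        train_acc = tc_sum / length(tr),
        val_loss = val_loss,
        val_acc = mean((vp >= 0.5) == (val$y == 1L))
      )

      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > config$patience) break
      }
    }
  })

  structure(
    list(
      params = best$params %||% params,
      config = config,
      scaling = scaling,
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch,
      n_slots = dim(inputs$X)[2]
    ),
    class = "wing_model"
  )
}

#' @export
print.wing_model <- function(x, ...) {
  cat(sprintf(
    "<wing_model> d = %d, H = %d, d_k = %d; trained %d epoch(s), best validation epoch %d\n",
    x$config$embedding_dim, x$config$hidden_size, x$config$d_k,
    nrow(x$history), x$best_epoch
  ))
  invisible(x)
}

# Batched inference over a corpus; chunked to bound the attention memory.
infer_corpus <- function(model, corpus, embedding, collect = FALSE,
                         chunk_size = 64L) {
  raw_inputs <- document_inputs(corpus, embedding)
  inputs <- apply_input_scaling(raw_inputs, model$scaling)
  B <- dim(inputs$X)[1]
  n <- dim(inputs$X)[2]
  H2 <- 2L * model$config$hidden_size
  p <- numeric(B)
  W_sent <- if (collect) matrix(0, B, n) else NULL
  R <- if (collect) matrix(0, B, H2) else NULL
  H_pool <- if (collect) matrix(0, B, H2) else NULL
  S_pool <- if (collect) matrix(0, B, dim(inputs$X)[3]) else NULL
  for (start in seq.int(1L, B, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, B)
    fp <- cpp_forward(
      inputs$X[idx, , , drop = FALSE], inputs$mask[idx, , drop = FALSE],
      model$params, collect = collect
    )
    p[idx] <- fp$p
    if (collect) {
      W_sent[idx, ] <- fp$sentence_weights
      R[idx, ] <- fp$R
      H_pool[idx, ] <- fp$bilstm_pooled
      for (j in seq_along(idx)) {
        b <- idx[j]
        m <- inputs$mask[b, ]
        # embedding-layer features are reported on the raw embedding scale
        S_pool[b, ] <- colMeans(matrix(raw_inputs$X[b, m, ], sum(m)))
      }
    }
  }
  list(
    p = p, sample_ids = inputs$sample_ids, y = inputs$y,
    sentence_weights = W_sent, attention_pooled = R,
    bilstm_pooled = H_pool, embedding_pooled = S_pool, mask = inputs$mask
  )
}

#' Predict winged-class probabilities for a corpus
#'
#' @param object A fitted `wing_model`.
#' @param corpus Corpus tibble from [build_corpus()].
#' @param embedding The `kmer_embedding` used in training.
#' @param threshold Decision threshold on the winged-class probability
#'   (default 0.5).
#' @param ... Unused.
#' @return A tibble with `sample_id`, `species_id`, `label`, `p_winged`,
#'   `predicted`.
#' @export
predict.wing_model <- function(object, corpus, embedding, threshold = 0.5, ...) {
  inf <- infer_corpus(object, corpus, embedding)
  tibble::tibble(
    sample_id = inf$sample_ids,
    species_id = corpus$species_id,
    label = inf$y,
    p_winged = inf$p,
    predicted = as.integer(inf$p >= threshold)
  )
}

#' Run one document through the network
#'
#' Single-document forward pass: embed and pool sentences, encode with the
#' BiLSTM, apply self-attention, average the unmasked context vectors, and
#' map through the affine head and sigmoid. Returns the winged-class
#' probability together with the full attention output for weight scoring.
#'
#' @param document A `species_document`.
#' @param embedding A `kmer_embedding`.
#' @param model A `wing_model` (fitted or freshly initialised).
#' @return A list with `p_winged` and `attention` (an `attention_output`).
#' @export
forward_document <- function(document, embedding, model) {
  corpus <- tibble::tibble(
    sample_id = document$sample_id, species_id = document$species_id,
    label = document$label, document = list(document)
  )
  inputs <- apply_input_scaling(document_inputs(corpus, embedding), model$scaling)
  m <- inputs$mask[1, ]
  if (!any(m)) abort("document with zero unmasked sentences")
  n <- length(m)
  S <- matrix(inputs$X[1, , ], n)
  Hmat <- bilstm_encode(S, model$params, mask = m)
  att <- attention(Hmat, list(WQ = model$params$WQ, WK = model$params$WK), mask = m)
  r <- colMeans(att$contexts[m, , drop = FALSE])
  p <- sigmoid(drop(r %*% model$params$w) + model$params$b0)
  list(p_winged = unname(p), attention = att)
}

#' Initialise an untrained model
#'
#' Seeded parameter initialisation without training; useful for forward
#' smoke tests and as the starting point of [fit_wing_model()].
#'
#' @param config A [model_config()].
#' @param n_slots Number of orthogroup sentence slots (stored for
#'   reference).
#' @return A `wing_model` with untrained parameters and empty history.
#' @export
init_wing_model <- function(config = model_config(), n_slots = NA_integer_) {
  params <- withr::with_seed(config$seed, init_params(config))
  structure(
    list(
      params = params, config = config,
      history = tibble::tibble(
        epoch = integer(), train_loss = numeric(), train_acc = numeric(),
        val_loss = numeric(), val_acc = numeric()
      ),
      best_epoch = 0L, n_slots = n_slots
    ),
    class = "wing_model"
  )
}

#' Write a model checkpoint
#'
#' Serialises all parameter tensors, the input scaling, the configuration
#' and the training history into a single JSON file (full double
#' precision).
#'
#' @param model A `wing_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wing_model <- function(model, path) {
  payload <- list(
    params = model$params,
    scaling = model$scaling,
    config = unclass(model$config),
    history = model$history,
    best_epoch = model$best_epoch,
    n_slots = model$n_slots
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a model checkpoint written by [write_wing_model()]
#'
#' @param path Path to the checkpoint JSON.
#' @return A `wing_model`.
#' @export
read_wing_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  params <- list(
    fwd = list(W = as_mat(raw$params$fwd$W), b = as.numeric(raw$params$fwd$b)),
    bwd = list(W = as_mat(raw$params$bwd$W), b = as.numeric(raw$params$bwd$b)),
    WQ = as_mat(raw$params$WQ), WK = as_mat(raw$params$WK),
    w = as.numeric(raw$params$w), b0 = as.numeric(raw$params$b0)
  )
  cfg <- raw$config
  config <- model_config(
    embedding_dim = cfg$embedding_dim, hidden_size = cfg$hidden_size,
    d_k = cfg$d_k, dropout = cfg$dropout,
    sentence_dropout = cfg$sentence_dropout %||% 0,
    learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
    max_epochs = cfg$max_epochs, patience = cfg$patience, seed = cfg$seed
  )
  scaling <- NULL
  if (!is.null(raw$scaling)) {
    scaling <- list(center = as.numeric(raw$scaling$center),
                    scale = as.numeric(raw$scaling$scale))
  }
  structure(
    list(
      params = params, config = config, scaling = scaling,
      history = tibble::as_tibble(raw$history),
      best_epoch = raw$best_epoch, n_slots = raw$n_slots
    ),
    class = "wing_model"
  )
}
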