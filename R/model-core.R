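# Low-level network operations.
#
# The network runs over *sentence* positions: each document is a fixed-length
# sequence of per-orthogroup sentence vectors (token-embedding means), encoded
# by a bidirectional LSTM whose per-position hidden states feed a scaled
# dot-product self-attention (queries = keys = values = hidden states, values
# unprojected). EMPTY/PAD positions are masked in pooling and attention so the
# softmax normalisation stays over real sentences; the recurrence itself runs
# over all positions (empty slots contribute zero input vectors).

#' Pool token vectors into a sentence vector
#'
#' The sentence representation is the mean of its non-PAD token embedding
#' vectors. An all-PAD (EMPTY) sentence pools to the zero vector and is
#' flagged masked.
#'
#' @param token_vectors A tokens x d matrix of embedding vectors.
#' @param pad_mask Logical vector, `TRUE` where the token is PAD. Defaults
#'   to all-real.
#' @return A list with `s` (the d-vector) and `masked` (logical).
#' @export
sentence_pool <- function(token_vectors, pad_mask = NULL) {
  if (is.null(pad_mask)) pad_mask <- rep(FALSE, nrow(token_vectors))
  real <- !pad_mask
  if (nrow(token_vectors) == 0L || !any(real)) {
    return(list(s = numeric(ncol(token_vectors)), masked = TRUE))
  }
  list(s = colMeans(token_vectors[real, , drop = FALSE]), masked = FALSE)
}

#' One LSTM cell step
#'
#' Computes the forget, input and output gates and the candidate cell from
#' the concatenated `[h_prev, x]` input, then the new cell and hidden
#' states:
#' \deqn{f = \sigma(W_f [h_{t-1}, x_t] + b_f), \quad
#'       i = \sigma(W_i [h_{t-1}, x_t] + b_i), \quad
#'       o = \sigma(W_o [h_{t-1}, x_t] + b_o)}
#' \deqn{\tilde c = \tanh(W_c [h_{t-1}, x_t] + b_c), \quad
#'       c_t = f \odot c_{t-1} + i \odot \tilde c, \quad
#'       h_t = o \odot \tanh(c_t)}
#'
#' @param x_t Input vector (length d) or a B x d matrix for a batch.
#' @param h_prev,c_prev Previous hidden/cell state, length H or B x H.
#' @param params List with `W` (a `(H+d) x 4H` matrix, gate blocks ordered
#'   f, i, o, c) and `b` (length 4H).
#' @return List with `h` and `c` (same shape as `h_prev`), plus the gate
#'   activations `f`, `i`, `o`, `ctilde`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, params) {
  vec_in <- is.null(dim(x_t))
  if (vec_in) {
    x_t <- matrix(x_t, 1L)
    h_prev <- matrix(h_prev, 1L)
    c_prev <- matrix(c_prev, 1L)
  }
  H <- ncol(h_prev)
  if (nrow(params$W) != H + ncol(x_t) || ncol(params$W) != 4L * H) {
    abort("LSTM parameter shapes inconsistent with input/hidden dimensions")
  }
  z <- cbind(h_prev, x_t) %*% params$W
  z <- sweep(z, 2L, params$b, "+")
  f <- sigmoid(z[, seq_len(H), drop = FALSE])
  i <- sigmoid(z[, H + seq_len(H), drop = FALSE])
  o <- sigmoid(z[, 2L * H + seq_len(H), drop = FALSE])
  ctilde <- tanh(z[, 3L * H + seq_len(H), drop = FALSE])
  c_t <- f * c_prev + i * ctilde
  h_t <- o * tanh(c_t)
  if (vec_in) {
    list(h = drop(h_t), c = drop(c_t), f = drop(f), i = drop(i),
         o = drop(o), ctilde = drop(ctilde))
  } else {
    list(h = h_t, c = c_t, f = f, i = i, o = o, ctilde = ctilde)
  }
}

#' Encode a sentence sequence with a bidirectional LSTM
#'
#' Runs a forward recurrence left-to-right and a backward recurrence
#' right-to-left over the sentence vectors (both from zero initial states)
#' and concatenates the two hidden states at each position:
#' `h_i = [h_i_fwd, h_i_bwd]`.
#'
#' @param sentence_vectors An n x d matrix of sentence vectors.
#' @param params List with `fwd` and `bwd`, each a list `W`, `b` as in
#'   [lstm_step()].
#' @param mask Logical length-n vector, `TRUE` for real (non-EMPTY)
#'   positions; at least one must be real. The recurrence runs over all
#'   positions (EMPTY slots carry zero vectors); the mask is enforced
#'   downstream in attention and pooling.
#' @return An n x 2H matrix of concatenated hidden states.
#' @export
bilstm_encode <- function(sentence_vectors, params, mask = NULL) {
  n <- nrow(sentence_vectors)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!any(mask)) abort("all sentence positions are masked")
  H <- ncol(params$fwd$W) / 4L
  run <- function(p, idx) {
    h <- numeric(H)
    c <- numeric(H)
    out <- matrix(0, n, H)
    for (t in idx) {
      st <- lstm_step(sentence_vectors[t, ], h, c, p)
      h <- st$h
      c <- st$c
      out[t, ] <- h
    }
    out
  }
  cbind(run(params$fwd, seq_len(n)), run(params$bwd, rev(seq_len(n))))
}

#' Scaled dot-product self-attention over hidden states
#'
#' Queries and keys are linear projections of the hidden states
#' (`Q W_Q`, `K W_K`); scores are their scaled dot products
#' `e_ij = (QW_Q)(KW_K)^T / sqrt(d_k)`, masked positions are set to
#' `-Inf` before the row-wise softmax, and each context vector is the
#' attention-weighted sum of the (unprojected) value vectors
#' `c_i = sum_j a_ij V_j` with `V = h`.
#'
#' @param h_sequence An n x 2H matrix of hidden states (queries = keys =
#'   values).
#' @param params List with projections `WQ`, `WK` (both `2H x d_k`).
#' @param mask Logical length-n vector, `TRUE` for real positions.
#' @return A list of class `attention_output` with `weights` (n x n
#'   row-stochastic on unmasked rows, masked columns exactly zero),
#'   `contexts` (n x 2H), and `mask`.
#' @export
attention <- function(h_sequence, params, mask = NULL) {
  n <- nrow(h_sequence)
  if (is.null(mask)) mask <- rep(TRUE, n)
  d_k <- ncol(params$WQ)
  if (is.null(d_k) || d_k <= 0L) abort("`d_k` must be positive")
  if (!any(mask)) abort("all positions are masked")
  fw <- attention_forward(h_sequence, params$WQ, params$WK, mask)
  structure(
    list(weights = fw$A, contexts = fw$C, mask = mask),
    class = "attention_output"
  )
}

# Internal attention forward pass, returning the caches needed by backprop.
attention_forward <- function(h, WQ, WK, mask) {
  d_k <- ncol(WQ)
  Aq <- h %*% WQ
  Ak <- h %*% WK
  E <- (Aq %*% t(Ak)) / sqrt(d_k)
  E[, !mask] <- -Inf
  A <- softmax_rows(E)
  A[!mask, ] <- 0
  C <- A %*% h
  list(A = A, C = C, Aq = Aq, Ak = Ak)
}

# Backprop through one document's attention given dC (n x 2H).
# Returns gradients for WQ, WK and the hidden states.
attention_backward <- function(dC, h, WQ, WK, cache) {
  d_k <- ncol(WQ)
  dA <- dC %*% t(h)
  dH <- t(cache$A) %*% dC
  dE <- cache$A * (dA - rowSums(dA * cache$A))
  dAq <- (dE %*% cache$Ak) / sqrt(d_k)
  dAk <- (t(dE) %*% cache$Aq) / sqrt(d_k)
  list(
    dWQ = t(h) %*% dAq,
    dWK = t(h) %*% dAk,
    dH = dH + dAq %*% t(WQ) + dAk %*% t(WK)
  )
}
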