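# Independent oracles: literal scalar-loop transcriptions of the model
# equations and brute-force reference computations, deliberately written
# without reusing any package internals.

# One LSTM step, scalar loops only.
lstm_step_oracle <- function(x, h, c, W, b) {
  H <- length(h)
  inp <- c(h, x)
  z <- numeric(4L * H)
  for (g in seq_len(4L * H)) {
    s <- b[g]
    for (k in seq_along(inp)) s <- s + inp[k] * W[k, g]
    z[g] <- s
  }
  sig <- function(v) 1 / (1 + exp(-v))
  f <- sig(z[1:H])
  i <- sig(z[H + 1:H])
  o <- sig(z[2 * H + 1:H])
  ct <- tanh(z[3 * H + 1:H])
  c_new <- f * c + i * ct
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new)
}

# Unidirectional LSTM over a sequence from zero states, via the scalar step.
lstm_run_oracle <- function(S, W, b, reverse = FALSE) {
  n <- nrow(S)
  H <- length(b) / 4L
  h <- numeric(H)
  c <- numeric(H)
  out <- matrix(0, n, H)
  idx <- if (reverse) rev(seq_len(n)) else seq_len(n)
  for (t in idx) {
    st <- lstm_step_oracle(S[t, ], h, c, W, b)
    h <- st$h
    c <- st$c
    out[t, ] <- h
  }
  out
}

# Brute-force scaled dot-product self-attention with masking.
attention_oracle <- function(Hm, WQ, WK, mask) {
  n <- nrow(Hm)
  d_k <- ncol(WQ)
  Q <- Hm %*% WQ
  K <- Hm %*% WK
  E <- matrix(-Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mask[j]) E[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    }
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (!mask[i]) next
    e <- exp(E[i, ] - max(E[i, mask]))
    e[!mask] <- 0
    A[i, ] <- e / sum(e)
  }
  C <- matrix(0, n, ncol(Hm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) C[i, ] <- C[i, ] + A[i, j] * Hm[j, ]
  }
  list(A = A, C = C)
}

# AUC as the pairwise rank statistic, ties counted half.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) {
    for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  }
  s / (length(pos) * length(neg))
}

# Random small network parameter sets.
rand_lstm_params <- function(d, H) {
  list(W = matrix(rnorm((H + d) * 4 * H, sd = 0.5), H + d, 4 * H), b = rnorm(4 * H, sd = 0.5))
}
rand_bilstm_params <- function(d, H) {
  list(fwd = rand_lstm_params(d, H), bwd = rand_lstm_params(d, H))
}
rand_attention_params <- function(width, d_k) {
  list(WQ = matrix(rnorm(width * d_k, sd = 0.5), width, d_k),
       WK = matrix(rnorm(width * d_k, sd = 0.5), width, d_k))
}
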