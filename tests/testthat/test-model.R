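test_that("sentence_pool averages non-PAD token vectors and flags EMPTY", {
  tv <- rbind(c(1, 1), c(3, 3))
  expect_equal(sentence_pool(tv)$s, c(2, 2))
  pooled <- sentence_pool(rbind(c(0, 0)), pad_mask = TRUE)
  expect_true(pooled$masked)
  expect_equal(pooled$s, c(0, 0))
  set.seed(51)
  tv2 <- matrix(rnorm(12), 4, 3)
  pm <- c(FALSE, TRUE, FALSE, FALSE)
  expect_equal(sentence_pool(tv2, pm)$s, colMeans(tv2[!pm, ]), tolerance = 1e-12)
})

test_that("lstm_step reproduces the closed-form zero-parameter cases", {
  H <- 3L
  d <- 2L
  params <- list(W = matrix(0, H + d, 4 * H), b = numeric(4 * H))
  c_prev <- c(0.4, -1, 2)
  st <- lstm_step(c(1, -2), numeric(H), c_prev, params)
  expect_equal(st$f, rep(0.5, H))
  expect_equal(st$i, rep(0.5, H))
  expect_equal(st$o, rep(0.5, H))
  expect_equal(st$ctilde, rep(0, H))
  expect_equal(st$c, 0.5 * c_prev)
  expect_equal(st$h, 0.5 * tanh(0.5 * c_prev))
  st0 <- lstm_step(c(5, 5), numeric(H), numeric(H), params)
  expect_equal(st0$h, rep(0, H))
  expect_error(lstm_step(c(1, 2, 3), numeric(H), numeric(H), params), "shapes")
})

test_that("gate activations stay in (0,1) and |h| < 1 on random inputs", {
  set.seed(52)
  for (rep in 1:25) {
    H <- sample(2:4, 1)
    d <- sample(2:5, 1)
    params <- rand_lstm_params(d, H)
    st <- lstm_step(rnorm(d), rnorm(H), rnorm(H), params)
    expect_true(all(st$f > 0 & st$f < 1))
    expect_true(all(st$i > 0 & st$i < 1))
    expect_true(all(st$o > 0 & st$o < 1))
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("bilstm_encode handles length-1 sequences and tied-parameter palindromes", {
  set.seed(53)
  d <- 3L
  H <- 2L
  params <- rand_bilstm_params(d, H)
  s1 <- matrix(rnorm(d), 1L)
  enc <- bilstm_encode(s1, params)
  step <- lstm_step(s1[1, ], numeric(H), numeric(H), params$fwd)
  expect_equal(enc[1, 1:H], step$h, tolerance = 1e-12)

  tied <- params
  tied$bwd <- tied$fwd
  half <- matrix(rnorm(3 * d), 3, d)
  pal <- rbind(half, half[3:1, ])
  enc_p <- bilstm_encode(pal, tied)
  n <- nrow(pal)
  for (i in seq_len(n)) {
    expect_equal(enc_p[i, 1:H], enc_p[n + 1 - i, H + 1:H], tolerance = 1e-12)
  }
  expect_error(bilstm_encode(pal, params, mask = rep(FALSE, n)), "masked")
})

test_that("attention softmax cases: singleton, uniform, masked columns", {
  set.seed(54)
  H2 <- 4L
  ap <- rand_attention_params(H2, 3L)
  h1 <- matrix(rnorm(H2), 1L)
  out <- attention(h1, ap)
  expect_equal(out$weights, matrix(1, 1, 1))
  expect_equal(out$contexts[1, ], h1[1, ], tolerance = 1e-12)

  hsame <- matrix(rep(rnorm(H2), each = 5L), 5L, H2)
  outu <- attention(hsame, ap)
  expect_equal(outu$weights, matrix(1 / 5, 5, 5), tolerance = 1e-12)

  h <- matrix(rnorm(6 * H2), 6L, H2)
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  outm <- attention(h, ap, mask)
  expect_true(all(outm$weights[, !mask] == 0))
  expect_true(all(outm$weights[!mask, ] == 0))
  expect_equal(rowSums(outm$weights)[mask], rep(1, sum(mask)), tolerance = 1e-9)
  expect_error(attention(h, list(WQ = matrix(numeric(0), H2, 0), WK = ap$WK)), "d_k")
})

test_that("the compiled training step agrees with the R reference implementation", {
  set.seed(55)
  B <- 4L; n <- 9L; d <- 6L; H <- 5L
  X <- array(rnorm(B * n * d), c(B, n, d))
  maskM <- matrix(TRUE, B, n)
  maskM[2, 8:9] <- FALSE
  y <- c(0, 1, 0, 1)
  cfg <- model_config(embedding_dim = d, hidden_size = H, d_k = 4L, dropout = 0)
  params <- withr::with_seed(2L, wingtrait:::init_params(cfg))
  st <- wingtrait:::cpp_grad_step(list(X = X, mask = maskM, y = y), params, 0, matrix(1, 1, 1))
  fp <- wingtrait:::network_forward(X, maskM, params)
  gr <- wingtrait:::network_backward(fp, X, maskM, y, params)
  expect_equal(st$p, fp$p, tolerance = 1e-12)
  expect_equal(st$loss, wingtrait:::bce_loss(fp$p, y), tolerance = 1e-12)
  expect_equal(st$grads$fwd$W, gr$fwd$W, tolerance = 1e-10)
  expect_equal(st$grads$bwd$W, gr$bwd$W, tolerance = 1e-10)
  expect_equal(st$grads$WQ, gr$WQ, tolerance = 1e-10)
  expect_equal(st$grads$WK, gr$WK, tolerance = 1e-10)
  expect_equal(st$grads$w, gr$w, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  set.seed(56)
  B <- 3L; n <- 7L; d <- 5L; H <- 4L
  X <- array(rnorm(B * n * d), c(B, n, d))
  maskM <- matrix(TRUE, B, n)
  maskM[1, 6:7] <- FALSE
  y <- c(0, 1, 1)
  cfg <- model_config(embedding_dim = d, hidden_size = H, d_k = 3L, dropout = 0)
  params <- withr::with_seed(7L, wingtrait:::init_params(cfg))
  loss_at <- function(pp) {
    wingtrait:::bce_loss(wingtrait:::network_forward(X, maskM, pp)$p, y)
  }
  gr <- wingtrait:::cpp_grad_step(list(X = X, mask = maskM, y = y), params, 0, matrix(1, 1, 1))$grads
  eps <- 1e-6
  check <- function(getter, g) {
    for (ii in seq_len(min(length(g), 8L))) {
      p_plus <- params
      p_minus <- params
      if (length(getter) == 2L) {
        p_plus[[getter[1]]][[getter[2]]][ii] <- p_plus[[getter[1]]][[getter[2]]][ii] + eps
        p_minus[[getter[1]]][[getter[2]]][ii] <- p_minus[[getter[1]]][[getter[2]]][ii] - eps
      } else {
        p_plus[[getter[1]]][ii] <- p_plus[[getter[1]]][ii] + eps
        p_minus[[getter[1]]][ii] <- p_minus[[getter[1]]][ii] - eps
      }
      num <- (loss_at(p_plus) - loss_at(p_minus)) / (2 * eps)
      expect_equal(g[ii], num, tolerance = 1e-5)
    }
  }
  check(c("fwd", "W"), gr$fwd$W)
  check(c("fwd", "b"), gr$fwd$b)
  check(c("bwd", "W"), gr$bwd$W)
  check("WQ", gr$WQ)
  check("WK", gr$WK)
  check("w", gr$w)
})

test_that("an untrained zero-head model outputs exactly 0.5 and is deterministic", {
  sim <- tiny_simulation()
  voc <- build_hf_vocabulary(count_kmers(sim$proteins$sequence, 3))
  ptok <- tokenize_proteins(select_longest_isoform(sim$proteins), voc)
  sel <- sort(unique(sim$orthogroups$orthogroup_id))
  corp <- build_corpus(sim$species, sim$orthogroups, ptok, sel, 1L, seed = 8L)
  emb <- train_cbow(ptok$token_ids, voc,
                    cbow_config(dim = 10L, epochs = 1L, batch_size = 2048L, seed = 4L))
  model <- init_wing_model(model_config(embedding_dim = 10L, hidden_size = 4L, d_k = 4L))
  f1 <- forward_document(corp$document[[1]], emb, model)
  expect_equal(f1$p_winged, 0.5)
  f2 <- forward_document(corp$document[[1]], emb, model)
  expect_identical(f1$p_winged, f2$p_winged)
  expect_s3_class(f1$attention, "attention_output")
  # probabilities stay strictly inside (0,1) across random parameter draws
  for (s in 1:10) {
    m <- init_wing_model(model_config(embedding_dim = 10L, hidden_size = 4L,
                                      d_k = 4L, seed = s))
    m$params$w <- rnorm(8L)
    m$params$b0 <- rnorm(1L)
    p <- forward_document(corp$document[[sample(nrow(corp), 1)]], emb, m)$p_winged
    expect_gt(p, 0)
    expect_lt(p, 1)
  }
})

# One tiny trained model shared by the training-behaviour tests.
tiny_fit <- function(max_epochs = 12L, patience = 10L, batch_size = 16L, seed = 21L) {
  sim <- tiny_simulation(seed = 409L)
  voc <- build_hf_vocabulary(count_kmers(sim$proteins$sequence, 3))
  ptok <- tokenize_proteins(select_longest_isoform(sim$proteins), voc)
  sel <- sort(unique(sim$orthogroups$orthogroup_id))
  corp <- build_corpus(sim$species, sim$orthogroups, ptok, sel, 3L, seed = 14L)
  emb <- train_cbow(ptok$token_ids, voc,
                    cbow_config(dim = 12L, epochs = 1L, batch_size = 4096L, seed = 6L))
  split <- split_dataset(corp$sample_id, corp$label, seed = 15L, groups = corp$species_id)
  cfg <- model_config(
    embedding_dim = 12L, hidden_size = 6L, d_k = 6L, dropout = 0,
    batch_size = batch_size, max_epochs = max_epochs, patience = patience, seed = seed
  )
  list(model = fit_wing_model(corp, emb, split, cfg),
       corp = corp, emb = emb, split = split, cfg = cfg)
}

test_that("training loss decreases on a strongly separable synthetic corpus", {
  ft <- tiny_fit()
  h <- ft$model$history
  expect_gte(nrow(h), 3L)
  expect_true(all(diff(h$train_loss[1:3]) < 0))
})

test_that("training is reproducible and early stopping honours patience zero", {
  ft1 <- tiny_fit(max_epochs = 6L)
  ft2 <- tiny_fit(max_epochs = 6L)
  expect_identical(ft1$model$history$val_loss, ft2$model$history$val_loss)
  expect_identical(ft1$model$params, ft2$model$params)

  ft0 <- tiny_fit(max_epochs = 30L, patience = 0L)
  h <- ft0$model$history$val_loss
  if (nrow(ft0$model$history) < 30L) {
    # stopped exactly at the first epoch whose validation loss did not improve
    n <- length(h)
    best_before <- cummin(h)[n - 1L]
    expect_gte(h[n], best_before - 1e-9)
    if (n > 2L) expect_true(all(h[2:(n - 1L)] < cummin(h)[1:(n - 2L)] + 1e-9))
  }
})

test_that("predict returns calibrated tibbles and matches forward_document", {
  ft <- tiny_fit(max_epochs = 4L)
  preds <- predict(ft$model, ft$corp, ft$emb)
  expect_named(preds, c("sample_id", "species_id", "label", "p_winged", "predicted"))
  expect_true(all(preds$p_winged > 0 & preds$p_winged < 1))
  i <- 5L
  f <- forward_document(ft$corp$document[[i]], ft$emb, ft$model)
  expect_equal(f$p_winged, preds$p_winged[i], tolerance = 1e-10)
  # tidy/glance accessors
  expect_s3_class(tidy(ft$model), "tbl_df")
  expect_equal(glance(ft$model)$hidden_size, 6L)
})
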