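test_that("confusion counts treat winged as positive at the threshold", {
  perfect <- confusion_counts(rep(c(1L, 0L), each = 10), rep(c(0.9, 0.1), each = 10))
  expect_equal(unlist(perfect), c(tp = 10L, tn = 10L, fp = 0L, fn = 0L))
  all_pos <- confusion_counts(rep(c(1L, 0L), each = 10), rep(1, 20))
  expect_equal(unlist(all_pos), c(tp = 10L, tn = 0L, fp = 10L, fn = 0L))
  expect_error(confusion_counts(c(1L, 0L), 0.5), "length")
})

test_that("confusion counts match a per-element loop on random cases", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    labels <- rbinom(n, 1, 0.5)
    scores <- runif(n)
    th <- runif(1)
    cc <- confusion_counts(labels, scores, threshold = th)
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_len(n)) {
      pred <- scores[i] >= th
      if (labels[i] == 1 && pred) tp <- tp + 1L
      if (labels[i] == 0 && !pred) tn <- tn + 1L
      if (labels[i] == 0 && pred) fp <- fp + 1L
      if (labels[i] == 1 && !pred) fn <- fn + 1L
    }
    expect_equal(unlist(cc), c(tp = tp, tn = tn, fp = fp, fn = fn))
  }
})

test_that("metrics implement the exact formulas with undefined-not-zero policy", {
  perfect <- classification_metrics(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  m <- classification_metrics(list(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-12)

  expect_warning(und <- classification_metrics(list(tp = 0, tn = 5, fp = 0, fn = 5)),
                 "precision undefined")
  expect_true(is.na(und$precision))
  expect_equal(und$recall, 0)
  expect_true(is.na(und$f1))
  expect_error(classification_metrics(list(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
})

test_that("F1 is the harmonic mean of precision and recall when defined", {
  set.seed(72)
  for (rep in 1:20) {
    cc <- list(tp = sample(1:30, 1), tn = sample(0:30, 1),
               fp = sample(0:30, 1), fn = sample(0:30, 1))
    m <- classification_metrics(cc)
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-12)
    expect_equal(m$accuracy, (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn),
                 tolerance = 1e-12)
  }
})

test_that("ROC endpoints and tie conventions are honoured", {
  sep <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1)
  expect_equal(sep$roc$fpr[1], 0)
  expect_equal(tail(sep$roc$tpr, 1), 1)
  ties <- roc_auc(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("trapezoid AUC equals the pairwise rank statistic and pROC agrees", {
  set.seed(73)
  labels <- rep(c(1L, 0L), 25)
  scores <- round(runif(50) + 0.3 * labels, 2) # ties guaranteed by rounding
  out <- roc_auc(scores, labels)
  expect_equal(out$auc, auc_oracle(scores, labels), tolerance = 1e-9)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE, direction = "<")))
  expect_equal(out$auc, proc_auc, tolerance = 1e-9)
})

test_that("layer features have the documented widths and deterministic rows", {
  sim <- tiny_simulation()
  voc <- build_hf_vocabulary(count_kmers(sim$proteins$sequence, 3))
  ptok <- tokenize_proteins(select_longest_isoform(sim$proteins), voc)
  sel <- sort(unique(sim$orthogroups$orthogroup_id))
  corp <- build_corpus(sim$species, sim$orthogroups, ptok, sel, 1L, seed = 19L)
  emb <- train_cbow(ptok$token_ids, voc,
                    cbow_config(dim = 9L, epochs = 1L, batch_size = 2048L, seed = 2L))
  model <- init_wing_model(model_config(embedding_dim = 9L, hidden_size = 5L, d_k = 4L))

  fe <- extract_layer_features(model, corp, emb, "embedding")
  fb <- extract_layer_features(model, corp, emb, "bilstm")
  fa <- extract_layer_features(model, corp, emb, "attention")
  expect_equal(sum(grepl("^f\\d+$", names(fe))), 9L)
  expect_equal(sum(grepl("^f\\d+$", names(fb))), 10L)
  expect_equal(sum(grepl("^f\\d+$", names(fa))), 10L)
  expect_equal(nrow(fe), nrow(corp))
  expect_error(extract_layer_features(model, corp, emb, "nope"))

  # identical documents give identical feature rows
  corp2 <- corp[c(1L, 1L), ]
  corp2$sample_id <- c("a", "b")
  f2 <- extract_layer_features(model, corp2, emb, "attention")
  expect_equal(as.numeric(f2[1, -(1:2)]), as.numeric(f2[2, -(1:2)]))

  # rows match the single-document forward pass
  fw <- forward_document(corp$document[[3]], emb, model)
  m <- fw$attention$mask
  expect_equal(as.numeric(fa[3, -(1:2)]),
               colMeans(fw$attention$contexts[m, , drop = FALSE]),
               tolerance = 1e-10)
})

test_that("evaluate_model assembles counts, threshold metrics and AUC", {
  sim <- tiny_simulation()
  cfg <- tiny_pipeline_config()
  res <- run_wing_pipeline(sim$proteins, sim$species, sim$orthogroups, cfg)
  ev <- res$evaluation
  expect_equal(sum(unlist(ev$counts)), length(split_ids(res$split, "test")))
  expect_true(is.na(ev$metrics$auc) || (ev$metrics$auc >= 0 && ev$metrics$auc <= 1))
  expect_equal(nrow(ev$predictions), length(split_ids(res$split, "test")))
})
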