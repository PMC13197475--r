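# Shared fixtures. Everything is generated in code; the expensive
# benchmark runs are memoised so several test files can share one run.

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

# A small deterministic simulation used by several unit tests.
# 6+6 species so a species-level 7:2:1 split puts one species of each
# class in the test subset.
tiny_simulation <- function(seed = 401L) {
  simulate_proteomes(synthetic_config(
    n_species_class0 = 6L, n_species_class1 = 6L,
    n_orthogroups = 12L, n_discriminative = 3L,
    seq_length = c(45L, 60L), dropout_fraction = 0.05,
    seed = seed
  ))
}

# A tiny pipeline configuration that runs in a few seconds.
tiny_pipeline_config <- function(seed = 402L) {
  pipeline_config(
    seed = seed, coverage_threshold = 0.5, per_species_samples = 2L,
    split_by = "species",
    cbow = cbow_config(dim = 12L, epochs = 1L, batch_size = 2048L),
    model = model_config(
      embedding_dim = 12L, hidden_size = 6L, d_k = 6L,
      batch_size = 4L, max_epochs = 4L, patience = 2L
    )
  )
}

.run_cache <- new.env(parent = emptyenv())

# Memoised default-benchmark run (the desk-scale study conditions).
cached_benchmark <- function(seed = 1L) {
  key <- paste0("bench_", seed)
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- run_benchmark(seed = seed)
  .run_cache[[key]]
}

# Accuracy of a ridge-regularised logistic probe trained on the training
# split of a layer-feature table and evaluated on the test split.
linear_probe_accuracy <- function(features, split) {
  mat <- as.matrix(features[, grep("^f\\d+$", names(features))])
  tr <- features$sample_id %in% split_ids(split, "train")
  te <- features$sample_id %in% split_ids(split, "test")
  fit <- glmnet::glmnet(
    mat[tr, ], features$label[tr], family = "binomial",
    alpha = 0, lambda = 0.05
  )
  pred <- as.numeric(stats::predict(fit, mat[te, ], type = "response") >= 0.5)
  mean(pred == features$label[te])
}
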