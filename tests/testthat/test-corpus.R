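# Hand-built two-species fixture: OG1 has two members for sp1 (sampled),
# OG2 one member, OG3 none for sp1.
corpus_fixture <- function() {
  og <- tibble::tibble(
    orthogroup_id = c("OG1", "OG1", "OG2", "OG3"),
    species_id = c("sp1", "sp1", "sp1", "sp2"),
    gene_id = c("g1", "g2", "g3", "g4")
  )
  attr(og, "orthogroup_ids") <- c("OG1", "OG2", "OG3")
  attr(og, "species") <- c("sp1", "sp2")
  ptok <- tibble::tibble(
    species_id = c("sp1", "sp1", "sp1", "sp2"),
    gene_id = c("g1", "g2", "g3", "g4"),
    token_ids = list(c(2L, 3L), c(4L, 5L), c(6L), c(7L))
  )
  list(og = og, ptok = ptok)
}

test_that("build_document draws one member per slot and marks missing slots EMPTY", {
  fx <- corpus_fixture()
  doc <- build_document("sp1", 0L, c("OG1", "OG2", "OG3"), fx$og,
                        wingtrait:::sentence_index(fx$ptok), seed = 5L)
  expect_s3_class(doc, "species_document")
  expect_length(doc$sentences, 3L)
  expect_true(doc$gene_ids[1] %in% c("g1", "g2"))
  expect_equal(doc$gene_ids[2], "g3")            # single member always chosen
  expect_true(is.na(doc$gene_ids[3]))            # EMPTY slot
  expect_equal(doc$sentences[[3]], 0L)           # a single PAD token
})

test_that("document sampling is reproducible per seed and uniform over members", {
  fx <- corpus_fixture()
  sidx <- wingtrait:::sentence_index(fx$ptok)
  sel <- c("OG1", "OG2", "OG3")
  d1 <- build_document("sp1", 0L, sel, fx$og, sidx, seed = 11L)
  d2 <- build_document("sp1", 0L, sel, fx$og, sidx, seed = 11L)
  expect_identical(d1$gene_ids, d2$gene_ids)
  draws <- vapply(1:10000, function(s) {
    build_document("sp1", 0L, "OG1", fx$og, sidx, seed = s)$gene_ids[1]
  }, character(1))
  # binomial sampling: each member chosen with frequency 0.5 +- 0.02
  expect_equal(mean(draws == "g1"), 0.5, tolerance = 0.02)
})

test_that("build_document rejects species absent from every selected orthogroup", {
  fx <- corpus_fixture()
  expect_error(
    build_document("sp2", 1L, c("OG1", "OG2"), fx$og,
                   wingtrait:::sentence_index(fx$ptok), seed = 1L),
    "absent from every selected orthogroup"
  )
})

test_that("augmentation produces the requested documents with distinct seeds", {
  sim <- tiny_simulation()
  voc <- build_hf_vocabulary(count_kmers(sim$proteins$sequence, 3))
  ptok <- tokenize_proteins(select_longest_isoform(sim$proteins), voc)
  sel <- sort(unique(sim$orthogroups$orthogroup_id))
  one <- build_corpus(sim$species, sim$orthogroups, ptok, sel, 1L, seed = 9L)
  expect_equal(nrow(one), nrow(sim$species)) # identity augmentation
  three <- build_corpus(sim$species, sim$orthogroups, ptok, sel, 3L, seed = 9L)
  expect_equal(nrow(three), 3L * nrow(sim$species))
  expect_equal(anyDuplicated(three$sampling_seed), 0L)
  expect_equal(anyDuplicated(three$sample_id), 0L)
  # constant sentence count across the corpus
  expect_equal(unique(vapply(three$document, function(d) length(d$sentences), integer(1))),
               length(sel))
})

test_that("same-species documents differ when an orthogroup offers a choice", {
  og <- tibble::tibble(
    orthogroup_id = rep("OG1", 2), species_id = "sp1", gene_id = c("g1", "g2")
  )
  attr(og, "orthogroup_ids") <- "OG1"
  ptok <- tibble::tibble(
    species_id = "sp1", gene_id = c("g1", "g2"),
    token_ids = list(c(2L, 2L), c(3L, 3L))
  )
  species <- tibble::tibble(species_id = "sp1", label = 1L)
  corp <- build_corpus(species, og, ptok, "OG1", 20L, seed = 2L)
  genes <- vapply(corp$document, function(d) d$gene_ids[1], character(1))
  expect_true(length(unique(genes)) == 2L)
})

test_that("split sizes follow the floor rule", {
  ids <- sprintf("s%05d", 1:2355)
  sp <- split_dataset(ids, seed = 1L)
  expect_equal(as.integer(table(sp$split)), c(1648L, 471L, 236L))
  expect_equal(as.integer(table(split_dataset(sprintf("s%02d", 1:10), seed = 2L)$split)),
               c(7L, 2L, 1L))
  expect_equal(as.integer(table(split_dataset(sprintf("s%02d", 1:23), seed = 3L)$split)),
               c(16L, 4L, 3L))
})

test_that("splits are exhaustive, disjoint, seeded, and validated", {
  ids <- sprintf("s%03d", 1:40)
  labs <- rep(c(0L, 1L), 20)
  s1 <- split_dataset(ids, labs, seed = 7L)
  s2 <- split_dataset(ids, labs, seed = 7L)
  expect_identical(s1$split, s2$split)
  expect_setequal(s1$sample_id, ids)
  expect_equal(anyDuplicated(s1$sample_id), 0L)
  # stratified: class mix in train matches the corpus
  expect_equal(sum(s1$label[s1$split == "train"] == 1L), 14L)
  expect_error(split_dataset(ids, ratios = c(6, 2, 1)), "summing to 10")
  expect_error(split_dataset(ids[1:2]), "at least 3")
})

test_that("group-aware splits keep all documents of a species together", {
  ids <- sprintf("doc%03d", 1:60)
  groups <- rep(sprintf("sp%02d", 1:20), each = 3L)
  labs <- rep(rep(c(0L, 1L), 10), each = 3L)
  sp <- split_dataset(ids, labs, seed = 5L, groups = groups)
  per_group <- tapply(as.character(sp$split), groups, function(x) length(unique(x)))
  expect_true(all(per_group == 1L))
  # floor rule applies to the 20 groups: 14/4/2 species -> 42/12/6 documents
  expect_equal(as.integer(table(sp$split)), c(42L, 12L, 6L))
  expect_error(split_dataset(ids, rep(0:1, 30), seed = 1L, groups = groups),
               "labels differ within a group")
})

test_that("corpora serialise to JSON lines with per-slot gene and token ids", {
  sim <- tiny_simulation()
  voc <- build_hf_vocabulary(count_kmers(sim$proteins$sequence, 3))
  ptok <- tokenize_proteins(select_longest_isoform(sim$proteins), voc)
  sel <- sort(unique(sim$orthogroups$orthogroup_id))[1:5]
  corp <- build_corpus(sim$species[1:2, ], sim$orthogroups, ptok, sel, 1L, seed = 3L)
  path <- tempfile(fileext = ".jsonl")
  write_corpus(corp, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$sample_id, corp$sample_id[1])
  expect_length(rec$sentences, 5L)
})
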