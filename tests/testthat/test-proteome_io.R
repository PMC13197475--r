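test_that("read_fasta parses entries, normalises case and strips stop symbols", {
  fa <- write_tmp_fasta(c(">g1.t1", "MKV", ">g1.t2", "mkvla*"))
  recs <- read_fasta(fa, species_id = "sp1")
  expect_equal(nrow(recs), 2L)
  expect_equal(nchar(recs$sequence), c(3L, 5L))
  expect_equal(recs$sequence[2], "MKVLA")
  expect_equal(recs$gene_id, c("g1", "g1"))
  expect_equal(recs$isoform_id, c("g1.t1", "g1.t2"))
})

test_that("read_fasta rejects empty files and maps illegal characters to X", {
  empty <- write_tmp_fasta(character(0))
  expect_error(read_fasta(empty, "sp1"), "no sequences")
  bad <- write_tmp_fasta(c(">g1.t1", "MK4V"))
  expect_warning(recs <- read_fasta(bad, "sp1"), "non-amino-acid")
  expect_equal(recs$sequence, "MKXV")
})

test_that("headers without the gene.isoform dialect fall back to the accession", {
  fa <- write_tmp_fasta(c(">prot1 some description", "MKV"))
  recs <- read_fasta(fa, "sp1")
  expect_equal(recs$gene_id, "prot1")
  expect_equal(recs$isoform_id, "prot1")
})

test_that("select_longest_isoform keeps the longest, ties to smallest isoform id", {
  prot <- tibble::tibble(
    species_id = "sp1",
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    isoform_id = c("g1.a", "g1.b", "g2.t1", "g3.b", "g3.a"),
    sequence = c(strrep("A", 100), strrep("A", 120), "MKV",
                 strrep("C", 80), strrep("D", 80))
  )
  out <- select_longest_isoform(prot)
  expect_equal(nrow(out), 3L)
  expect_equal(out$isoform_id[out$gene_id == "g1"], "g1.b")   # longest
  expect_equal(out$isoform_id[out$gene_id == "g2"], "g2.t1")  # single kept
  expect_equal(out$isoform_id[out$gene_id == "g3"], "g3.a")   # tie -> smallest id
  # idempotence
  expect_equal(select_longest_isoform(out), out)
})

test_that("read_orthogroups parses the wide comma-separated dialect", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Orthogroup\tsp1\tsp2\tsp3",
    "OG0000001\tg1, g2\t\tg9"
  ), path)
  og <- read_orthogroups(path)
  expect_equal(sort(og$gene_id[og$species_id == "sp1"]), c("g1", "g2"))
  expect_equal(sum(og$species_id == "sp2"), 0L)
  expect_equal(og$gene_id[og$species_id == "sp3"], "g9")
  expect_equal(attr(og, "species"), c("sp1", "sp2", "sp3"))
})

test_that("read_orthogroups handles degenerate and invalid tables", {
  hdr_only <- tempfile(fileext = ".tsv")
  writeLines("Orthogroup\tsp1\tsp2", hdr_only)
  og <- read_orthogroups(hdr_only)
  expect_equal(nrow(og), 0L)
  expect_equal(length(attr(og, "orthogroup_ids")), 0L)

  dup <- tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tsp1", "OG0000001\tg1", "OG0000001\tg2"), dup)
  expect_error(read_orthogroups(dup), "duplicated orthogroup_id")

  unknown <- tempfile(fileext = ".tsv")
  writeLines(c("Orthogroup\tspX", "OG0000001\tg1"), unknown)
  expect_error(read_orthogroups(unknown, species = c("sp1", "sp2")), "not in species table")
})

test_that("orthogroup tables round-trip through write/read", {
  sim <- tiny_simulation()
  path <- tempfile(fileext = ".tsv")
  write_orthogroups(sim$orthogroups, path)
  back <- read_orthogroups(path)
  key <- function(x) {
    dplyr::arrange(
      tibble::as_tibble(x[, c("orthogroup_id", "species_id", "gene_id")]),
      orthogroup_id, species_id, gene_id
    )
  }
  expect_equal(key(back), key(sim$orthogroups))
  expect_equal(attr(back, "orthogroup_ids"), attr(sim$orthogroups, "orthogroup_ids"))
})

test_that("select_by_coverage computes fractions and respects the threshold", {
  og <- tibble::tibble(
    orthogroup_id = c("OG1", "OG1", "OG2"),
    species_id = c("sp1", "sp2", "sp1"),
    gene_id = c("a", "b", "c")
  )
  sel <- select_by_coverage(og, c("sp1", "sp2", "sp3"), threshold = 0.5)
  expect_equal(sel$coverage[sel$orthogroup_id == "OG1"], 2 / 3, tolerance = 1e-12)
  expect_true(sel$selected[sel$orthogroup_id == "OG1"])
  expect_false(sel$selected[sel$orthogroup_id == "OG2"])
  # threshold 1 keeps only universal orthogroups
  sel1 <- select_by_coverage(og, c("sp1", "sp2"), threshold = 1)
  expect_equal(selected_orthogroups(sel1), "OG1")
  expect_error(select_by_coverage(og, character(0), 0.5), "non-empty")
})

test_that("coverage selection matches a brute-force scan on a seeded grid", {
  set.seed(31)
  n_og <- 100L
  species <- sprintf("sp%02d", 1:50)
  present <- lapply(1:n_og, function(i) sample(species, sample(40:50, 1)))
  og <- tibble::tibble(
    orthogroup_id = rep(sprintf("OG%03d", 1:n_og), lengths(present)),
    species_id = unlist(present),
    gene_id = paste0("g", seq_len(sum(lengths(present))))
  )
  sel <- select_by_coverage(og, species, threshold = 0.98)
  brute <- sum(vapply(present, function(p) length(unique(p)) / 50 >= 0.98, logical(1)))
  expect_equal(sum(sel$selected), brute)
  # monotone: raising the threshold never adds orthogroups
  for (th in c(0.5, 0.8, 0.9, 0.98, 1)) {
    sel_lo <- selected_orthogroups(select_by_coverage(og, species, threshold = th))
    if (th > 0.5) expect_true(all(sel_lo %in% prev))
    prev <- sel_lo
  }
})

test_that("species tables read labels in both encodings and filter on completeness", {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    species_id = c("a", "b", "c"),
    label = c("winged", "wingless", "1"),
    path = "x.fa",
    completeness = c(0.99, 0.85, NA)
  ), path)
  sp <- read_species_table(path)
  expect_equal(sp$label, c(1L, 0L, 1L))
  kept <- filter_by_completeness(sp, 0.9)
  expect_equal(kept$species_id, c("a", "c")) # NA completeness is kept
})
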