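# Token id convention, used everywhere downstream:
#   PAD = 0 (doubles as the zero-fill / empty-slot symbol),
#   UNK = 1 (out-of-vocabulary window or trailing remainder),
#   vocabulary k-mers = 2, 3, ... in vocabulary order.
PAD_ID <- 0L
UNK_ID <- 1L
N_SPECIALS <- 2L

# Collapse ambiguity codes to the unknown-residue symbol; tokenization only
# sees the 20-letter alphabet plus X.
normalise_residues <- function(sequences) {
  chartr(paste(AMBIGUITY_CODES, collapse = ""),
         strrep(UNK_RESIDUE, length(AMBIGUITY_CODES)), toupper(sequences))
}

# Cut one sequence into k-windows. Non-overlapping left-to-right windows by
# default; overlapping mode slides by one residue.
kmer_windows <- function(sequence, k, overlap = FALSE) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  starts <- if (overlap) seq.int(1L, n - k + 1L) else seq.int(1L, n - k + 1L, by = k)
  substring(sequence, starts, starts + k - 1L)
}

#' Count k-mer occurrences across protein sequences
#'
#' Counts left-to-right, non-overlapping k-residue windows over all
#' sequences (the segmentation rule used throughout the pipeline); trailing
#' remainders shorter than k are not counted, and windows containing the
#' unknown-residue symbol (any ambiguity code) are skipped.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param k Window length in residues (default 3).
#' @param overlap If `TRUE`, count overlapping windows at every position
#'   instead of the default frame-aligned windows.
#' @return A named integer vector of counts.
#' @examples
#' count_kmers(c("ACDEFG", "ACDEF"), k = 3)
#' @export
count_kmers <- function(sequences, k = 3L, overlap = FALSE) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) abort("`k` must be a positive integer")
  k <- as.integer(k)
  seqs <- normalise_residues(sequences)
  windows <- unlist(lapply(seqs, kmer_windows, k = k, overlap = overlap), use.names = FALSE)
  windows <- windows[!grepl(UNK_RESIDUE, windows, fixed = TRUE)]
  if (length(windows) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(windows)
  setNames(as.integer(tab), names(tab))
}

#' Build a high-frequency k-mer vocabulary
#'
#' Selects the vocabulary from a k-mer count table: k-mers with at least
#' `min_count` occurrences, truncated to the `top_n` most frequent
#' (frequency ties broken lexicographically). The vocabulary is ordered by
#' descending frequency then lexicographically, and carries the PAD (id 0)
#' and UNK (id 1) specials; k-mer ids start at 2.
#'
#' @param frequency Named integer vector from [count_kmers()].
#' @param top_n Maximum vocabulary size (default 8000, effectively all
#'   observed 3-mers).
#' @param min_count Minimum occurrence count (default 1).
#' @return An object of class `kmer_vocab`.
#' @export
build_hf_vocabulary <- function(frequency, top_n = 8000L, min_count = 1L) {
  if (length(frequency) == 0L) abort("empty frequency map")
  keep <- frequency[frequency >= min_count]
  if (length(keep) == 0L) abort("vocabulary selection is empty: no k-mer reaches `min_count`")
  ord <- order(-keep, names(keep))
  keep <- keep[ord]
  if (length(keep) > top_n) keep <- keep[seq_len(top_n)]
  vocab <- structure(
    list(
      k = unique(nchar(names(keep)))[1],
      tokens = names(keep),
      frequency = keep,
      pad_id = PAD_ID,
      unk_id = UNK_ID
    ),
    class = "kmer_vocab"
  )
  vocab
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf(
    "<kmer_vocab> k = %d, %d tokens + PAD/UNK specials\n", x$k, length(x$tokens)
  ))
  invisible(x)
}

#' Number of embedding rows implied by a vocabulary
#'
#' @param vocab A `kmer_vocab`.
#' @return Integer: number of tokens plus the two specials.
#' @export
vocab_size <- function(vocab) length(vocab$tokens) + N_SPECIALS

#' Segment a protein sequence into token ids
#'
#' Cuts the sequence into left-to-right non-overlapping k-windows and maps
#' each window to its vocabulary id; out-of-vocabulary windows and any
#' trailing remainder shorter than k map to UNK. An empty sequence yields an
#' empty token list.
#'
#' @param sequence A single amino-acid sequence.
#' @param vocab A `kmer_vocab`.
#' @param overlap Use overlapping windows (must match how the vocabulary was
#'   counted).
#' @return Integer vector of token ids.
#' @export
segment_sequence <- function(sequence, vocab, overlap = FALSE) {
  seq <- normalise_residues(sequence)
  windows <- kmer_windows(seq, vocab$k, overlap = overlap)
  ids <- match(windows, vocab$tokens) + 1L
  ids[is.na(ids)] <- UNK_ID
  if (!overlap && nchar(seq) %% vocab$k != 0L && nchar(seq) > 0L) ids <- c(ids, UNK_ID)
  as.integer(ids)
}

#' Decode token ids back to k-mer strings
#'
#' @param token_ids Integer vector of token ids.
#' @param vocab A `kmer_vocab`.
#' @return Character vector; PAD and UNK decode to `"<PAD>"` and `"<UNK>"`.
#' @export
decode_tokens <- function(token_ids, vocab) {
  out <- character(length(token_ids))
  out[token_ids == PAD_ID] <- "<PAD>"
  out[token_ids == UNK_ID] <- "<UNK>"
  real <- token_ids >= N_SPECIALS
  out[real] <- vocab$tokens[token_ids[real] - 1L]
  out
}

#' Tokenize a protein table
#'
#' Adds a `token_ids` list-column and a `n_residues_covered` column (k times
#' the number of in-vocabulary tokens) to a protein table.
#'
#' @param proteins Protein tibble with a `sequence` column.
#' @param vocab A `kmer_vocab`.
#' @return The input tibble with `token_ids` and `n_residues_covered`.
#' @export
tokenize_proteins <- function(proteins, vocab) {
  ids <- lapply(proteins$sequence, segment_sequence, vocab = vocab)
  proteins$token_ids <- ids
  proteins$n_residues_covered <- vapply(
    ids, function(x) vocab$k * sum(x >= N_SPECIALS), integer(1)
  )
  proteins
}

#' Write a vocabulary to disk
#'
#' Serialises the vocabulary as a two-column TSV (token, count) plus a JSON
#' sidecar holding k and the special-token ids.
#'
#' @param vocab A `kmer_vocab`.
#' @param path Path for the TSV; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  readr::write_tsv(
    tibble::tibble(token = vocab$tokens, count = as.integer(vocab$frequency)),
    path
  )
  jsonlite::write_json(
    list(k = vocab$k, pad_id = vocab$pad_id, unk_id = vocab$unk_id),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary()]
#'
#' @param path Path to the vocabulary TSV.
#' @return A `kmer_vocab`.
#' @export
read_vocabulary <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ci")
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(
    list(
      k = as.integer(meta$k),
      tokens = tab$token,
      frequency = setNames(tab$count, tab$token),
      pad_id = as.integer(meta$pad_id),
      unk_id = as.integer(meta$unk_id)
    ),
    class = "kmer_vocab"
  )
}
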