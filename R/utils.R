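# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical; the coordinate system for
# k-mer vocabularies and background frequencies.
AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Ambiguity / non-standard residue codes accepted on input; collapsed to a
# single unknown-residue symbol before tokenization.
AMBIGUITY_CODES <- c("B", "Z", "X", "U", "O", "J")
UNK_RESIDUE <- "X"

#' Derive a per-stage seed from a global seed
#'
#' Each pipeline stage draws randomness from its own seed so stages are
#' independently reproducible. Stage seeds are a fixed affine map of the
#' global seed modulo the largest 32-bit prime.
#'
#' @param seed Integer global seed.
#' @param stage Integer stage offset (each caller uses a fixed constant).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(stage)) %% 2147483647)
}

# Numerically safe sigmoid.
sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax with -Inf support (masked entries get exactly zero).
softmax_rows <- function(e) {
  m <- apply(e, 1L, max)
  m[!is.finite(m)] <- 0 # all-masked row: avoid NaN, handled by caller
  z <- exp(e - m)
  z / pmax(rowSums(z), .Machine$double.eps)
}

# Validate that `x` is a single number in [lo, hi].
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  }
  invisible(x)
}
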