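# Pluggable per-residue embedding source. The contract: an embedder is a
# function(sequence) returning an n x dim numeric matrix, deterministic given
# its configuration. A language-model plugin can be dropped in through the
# same contract; the package ships a deterministic stub.

#' Deterministic stub residue embedder
#'
#' Returns an embedder function mapping a sequence to per-residue Gaussian
#' feature vectors. Each residue's vector is a hash-seeded draw keyed by
#' (token identity, position, seed): the same token at the same position maps
#' to the same vector in every call and every sequence, so shared prefixes
#' share embeddings. Stands behind the embedder interface that a protein
#' language model would otherwise fill.
#'
#' @param dim embedding dimension (>= 1).
#' @param seed integer key mixed into every per-residue draw.
#' @return function(sequence) -> n x dim matrix, with attributes
#'   \code{dim} and \code{seed}.
#' @export
stub_embedder <- function(dim = 32L, seed = 0L) {
  stopifnot(dim >= 1)
  dim <- as.integer(dim); seed <- as.integer(seed)
  f <- function(sequence) {
    sequence <- aa_seq(sequence)
    n <- length(sequence)
    out <- matrix(0, n, dim)
    alpha <- aa_alphabet()
    for (i in seq_len(n)) {
      tok <- match(unclass(sequence)[i], alpha)
      # deterministic key for (token, position, seed), kept below 2^31
      key <- (seed * 1000003L + tok * 7919L + i * 104729L) %% 2147483629L
      out[i, ] <- with_seed(key, stats::rnorm(dim))
    }
    out
  }
  attr(f, "embed_dim") <- dim
  attr(f, "embed_seed") <- seed
  f
}

#' Zero embedder (degenerate weights)
#'
#' An embedder whose output is identically zero; useful for isolating the
#' learned token embeddings in tests.
#' @param dim embedding dimension.
#' @return embedder function.
#' @export
zero_embedder <- function(dim = 32L) {
  f <- function(sequence) matrix(0, length(aa_seq(sequence)), dim)
  attr(f, "embed_dim") <- as.integer(dim)
  f
}
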