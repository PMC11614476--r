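#' Amino-acid token alphabet
#'
#' The 22-symbol alphabet used throughout: the 20 canonical amino acids in
#' one-letter code, an UNKNOWN symbol \code{"X"} for non-canonical residues,
#' and the \code{"-"} MASK symbol used by the stochastic masking scheme.
#'
#' @return character vector of length 22.
#' @export
aa_alphabet <- function() c(AA_CANONICAL, "X", "-")

AA_CANONICAL <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)
AA_MASK <- "-"
AA_UNKNOWN <- "X"

#' Construct an amino-acid sequence
#'
#' @param x character vector of single-letter tokens, or a single string.
#' @return character vector of class \code{aa_seq}; tokens outside the
#'   canonical alphabet (other than MASK) are mapped to UNKNOWN.
#' @export
aa_seq <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  x <- toupper(as.character(x))
  if (length(x) < 1L) stop("sequence must have length >= 1")
  x[!(x %in% aa_alphabet())] <- AA_UNKNOWN
  structure(x, class = "aa_seq")
}

#' @export
print.aa_seq <- function(x, ...) {
  cat(sprintf("<aa_seq[%d]> %s\n", length(x), paste(unclass(x), collapse = "")))
  invisible(x)
}

#' @method format aa_seq
#' @export
format.aa_seq <- function(x, ...) paste(unclass(x), collapse = "")

#' Stochastically mask a sequence
#'
#' Two-stage masking: an effective ratio is drawn uniformly from
#' \code{[0, mask_ratio]} (so the realized masking varies from none up to the
#' set ratio), then \code{round(effective_ratio * n)} positions chosen
#' uniformly without replacement are replaced by the MASK token. With
#' \code{fixed_ratio = TRUE} the first stage is skipped and the effective
#' ratio equals \code{mask_ratio} exactly.
#'
#' @param sequence an [aa_seq()] (or coercible).
#' @param mask_ratio upper bound on the masked fraction, in [0, 1].
#' @param seed optional integer for reproducibility.
#' @param fixed_ratio use \code{mask_ratio} itself rather than a uniform draw.
#' @return masked \code{aa_seq}.
#' @export
stochastic_mask <- function(sequence, mask_ratio, seed = NULL,
                            fixed_ratio = FALSE) {
  sequence <- aa_seq(sequence)
  if (mask_ratio < 0 || mask_ratio > 1) stop("mask_ratio must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(sequence)
  eff <- if (fixed_ratio) mask_ratio else stats::runif(1, 0, mask_ratio)
  k <- round(eff * n)
  if (k > 0) {
    idx <- sample.int(n, k)
    sequence[idx] <- AA_MASK
  }
  sequence
}

#' Positions carrying the MASK token
#' @param sequence an \code{aa_seq}.
#' @return integer vector of masked positions (possibly empty).
#' @export
masked_positions <- function(sequence) which(unclass(aa_seq(sequence)) == AA_MASK)

#' Read sequences from a FASTA file
#'
#' @param path FASTA file; may hold several records.
#' @param index which record to return; by default the first.
#' @return an \code{aa_seq} named after the record.
#' @export
read_fasta <- function(path, index = 1L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) < 1L) stop("no FASTA records in ", path)
  if (index > length(set)) stop("FASTA record index out of range")
  s <- aa_seq(as.character(set[[index]]))
  attr(s, "name") <- names(set)[index]
  s
}

#' Write a sequence as FASTA
#'
#' @param sequence an \code{aa_seq} or string.
#' @param path output file.
#' @param name record header.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(sequence, path, name = "design") {
  sequence <- aa_seq(sequence)
  writeLines(c(paste0(">", name), paste(unclass(sequence), collapse = "")), path)
  invisible(path)
}
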