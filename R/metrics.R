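#' Sequence diversity: mean pairwise edit distance
#'
#' \eqn{\frac{1}{\binom{n}{2}} \sum_{i<j} d(S_i, S_j)} where \eqn{d} is the
#' Levenshtein distance with unit insertion, deletion and substitution costs.
#' Larger values mean the design ensemble explores more of sequence space.
#'
#' @param sequences list of \code{aa_seq} objects or plain strings
#'   (at least two).
#' @return scalar mean pairwise edit distance.
#' @export
diversity_score <- function(sequences) {
  if (length(sequences) < 2L) stop("diversity needs at least two sequences")
  strs <- vapply(
    sequences,
    function(s) paste(unclass(aa_seq(s)), collapse = ""),
    character(1)
  )
  d <- utils::adist(strs)
  mean(d[upper.tri(d)])
}

#' Optimal rigid superposition (Kabsch) and RMSD
#'
#' Minimizes \eqn{\sqrt{\frac{1}{N}\sum_i \|p_i - (R p'_i + t)\|^2}} over
#' proper rotations \eqn{R \in SO(3)} and translations \eqn{t}: centroids are
#' aligned and the rotation comes from the SVD of the cross-covariance with
#' the usual determinant sign correction.
#'
#' @param p,p_prime N x 3 coordinate matrices in 1:1 correspondence.
#' @return list with \code{rmsd}, \code{rotation} (3 x 3, det +1),
#'   \code{translation} (length 3) such that \code{p_prime \%*\% t(rotation) +
#'   translation} best matches \code{p}.
#' @export
kabsch_rmsd <- function(p, p_prime) {
  p <- as.matrix(p); q <- as.matrix(p_prime)
  if (!all(dim(p) == dim(q))) stop("coordinate sets must have equal shape")
  n <- nrow(p)
  cp <- colMeans(p); cq <- colMeans(q)
  P <- sweep(p, 2L, cp); Q <- sweep(q, 2L, cq)
  H <- t(Q) %*% P
  if (all(abs(H) < 1e-14)) {
    # degenerate (e.g. all points coincident): identity by convention
    R <- diag(3)
  } else {
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  aligned <- Q %*% t(R)
  rmsd <- sqrt(mean(rowSums((P - aligned)^2)))
  translation <- as.numeric(cp - cq %*% t(R))
  list(rmsd = rmsd, rotation = R, translation = translation)
}

#' TM-score of two corresponding structures
#'
#' \eqn{\max_{R,t} \frac{1}{N} \sum_i \frac{1}{1 + d_i^2/d_0^2}} with
#' \eqn{d_i} the residual after the rigid motion and the usual length-dependent
#' scale \eqn{d_0 = \max(1.24 (N - 15)^{1/3} - 1.8,\ 0.5)} angstrom. The
#' maximization starts from the Kabsch superposition and then iterates
#' TM-weighted superpositions (weights \eqn{1/(1 + d_i^2/d_0^2)^2}) to
#' convergence, which shifts the alignment toward the well-matching core.
#'
#' @param p,p_prime N x 3 coordinate matrices.
#' @param d0 scale in angstrom, or \code{"auto"}.
#' @param max_iter iteration cap for the reweighting loop.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(p, p_prime, d0 = "auto", max_iter = 50L) {
  p <- as.matrix(p); q <- as.matrix(p_prime)
  if (!all(dim(p) == dim(q))) stop("coordinate sets must have equal shape")
  n <- nrow(p)
  if (identical(d0, "auto")) d0 <- max(1.24 * sign(n - 15) * abs(n - 15)^(1 / 3) - 1.8, 0.5)
  score_of <- function(R, tr) {
    d2 <- rowSums((p - (q %*% t(R) + matrix(tr, n, 3, byrow = TRUE)))^2)
    mean(1 / (1 + d2 / d0^2))
  }
  fit <- kabsch_rmsd(p, q)
  R <- fit$rotation; tr <- fit$translation
  best <- score_of(R, tr)
  w <- rep(1, n)
  for (it in seq_len(max_iter)) {
    d2 <- rowSums((p - (q %*% t(R) + matrix(tr, n, 3, byrow = TRUE)))^2)
    w_new <- 1 / (1 + d2 / d0^2)^2
    if (max(abs(w_new - w)) < 1e-10) break
    w <- w_new
    wf <- weighted_superposition(p, q, w)
    sc <- score_of(wf$rotation, wf$translation)
    if (sc > best) {
      best <- sc; R <- wf$rotation; tr <- wf$translation
    } else {
      break
    }
  }
  best
}

# weighted Kabsch: minimizes sum_i w_i ||p_i - (R q_i + t)||^2
weighted_superposition <- function(p, q, w) {
  w <- w / sum(w)
  cp <- colSums(p * w); cq <- colSums(q * w)
  P <- sweep(p, 2L, cp); Q <- sweep(q, 2L, cq)
  H <- t(Q * w) %*% P
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(cp - cq %*% t(R)))
}

#' Contact set of a structure
#'
#' All unordered index pairs closer than the cutoff (strict inequality),
#' excluding self-pairs; an optional sequence-separation filter can drop
#' trivially adjacent pairs.
#'
#' @param p N x 3 coordinates.
#' @param r_c contact cutoff in angstrom.
#' @param min_separation keep only pairs with \code{|i - j| >=} this value
#'   (default 1, i.e. all non-self pairs).
#' @return two-column integer matrix of pairs with \code{i < j}.
#' @export
contact_set <- function(p, r_c, min_separation = 1L) {
  p <- as.matrix(p)
  n <- nrow(p)
  d <- as.matrix(stats::dist(p))
  idx <- which(upper.tri(d) & d < r_c, arr.ind = TRUE)
  if (min_separation > 1L) {
    idx <- idx[abs(idx[, 1] - idx[, 2]) >= min_separation, , drop = FALSE]
  }
  colnames(idx) <- c("i", "j")
  idx
}

#' Contact overlap (Jaccard) between two structures
#'
#' \eqn{|C \cap C'| / |C \cup C'|} over the contact sets of the two
#' structures under a shared cutoff. Both sets empty is defined as perfect
#' (vacuous) agreement, 1.
#'
#' @param p,p_prime N x 3 coordinate matrices (N >= 2).
#' @param r_c contact cutoff in angstrom (default 8).
#' @param min_separation optional sequence-separation filter, see
#'   [contact_set()].
#' @return Jaccard index in [0, 1].
#' @export
contact_overlap <- function(p, p_prime, r_c = 8, min_separation = 1L) {
  p <- as.matrix(p); q <- as.matrix(p_prime)
  if (!all(dim(p) == dim(q))) stop("coordinate sets must have equal shape")
  if (nrow(p) < 2L) stop("contact overlap needs at least two tokens")
  key <- function(m) if (nrow(m) == 0L) character(0) else paste(m[, 1], m[, 2], sep = "-")
  a <- key(contact_set(p, r_c, min_separation))
  b <- key(contact_set(q, r_c, min_separation))
  u <- union(a, b)
  if (length(u) == 0L) return(1)
  length(intersect(a, b)) / length(u)
}
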