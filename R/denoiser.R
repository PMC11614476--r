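# Equivariant denoiser: the final pair representation is symmetrized and
# pushed through a per-entry MLP into a scalar weight matrix W; the noise
# prediction for token i is the W-weighted sum of unit relative differences
# (z_i - z_j)/||z_i - z_j||, with the centroid subtracted afterwards. W
# depends on the pair features only (distances, positions, time), so the
# whole map commutes with rotations and ignores translations.

# AD path: pair node -> symmetrized -> MLP -> r x r weight node
weights_node <- function(z, P, r) {
  # transpose permutation on pair rows: (i,j) -> (j,i)
  i_of <- rep(seq_len(r), each = r)
  j_of <- rep(seq_len(r), times = r)
  perm <- (j_of - 1L) * r + i_of
  zsym <- ad_scale(ad_add(z, ad_permute_rows(z, perm)), 0.5)
  h <- ad_relu(ad_add_rowvec(ad_matmul(zsym, P[["den.w1"]]), P[["den.b1"]]))
  w <- ad_add_rowvec(ad_matmul(h, P[["den.w2"]]), P[["den.b2"]])
  ad_reshape_sq(w, r)
}

# constant unit-difference directions D[i, j, ] = (z_i - z_j)/(||.|| + delta)
unit_differences <- function(coords, delta = 1e-6) {
  coords <- as.matrix(coords)
  r <- nrow(coords)
  D <- array(0, c(r, r, 3L))
  for (axis in 1:3) {
    diff <- outer(coords[, axis], coords[, axis], `-`)
    D[, , axis] <- diff
  }
  nrm <- sqrt(D[, , 1]^2 + D[, , 2]^2 + D[, , 3]^2)
  for (axis in 1:3) D[, , axis] <- D[, , axis] / (nrm + delta)
  D
}

eps_hat_node <- function(W, coords, delta) {
  D <- unit_differences(coords, delta)
  ad_center_rows(ad_weighted_field(W, D))
}

logits_node <- function(m, P, n_res) {
  res <- ad_gather_rows(m, seq_len(n_res))
  ad_add_rowvec(ad_matmul(res, P[["head.W"]]), P[["head.b"]])
}

#' Pair representation to symmetric weight matrix
#'
#' Symmetrizes the pair tensor over its token axes,
#' \code{z <- (z + t(z))/2}, then applies a small per-entry MLP producing one
#' scalar per pair. The result is exactly symmetric.
#'
#' @param pair r^2 x c_z matrix (row-major pairs).
#' @param model a [new_model()].
#' @return r x r numeric weight matrix.
#' @export
pair_to_weights <- function(pair, model) {
  r2 <- nrow(pair)
  r <- as.integer(round(sqrt(r2)))
  if (r * r != r2) stop("pair tensor is not square")
  P <- wrap_params(model$params)
  weights_node(ad_const(unclass_mat(pair)), P, r)$value
}

#' Equivariant noise prediction from a weight matrix
#'
#' \eqn{\hat\epsilon_i = \sum_{j \ne i} W_{ij} (z_i - z_j)/(\|z_i - z_j\| +
#' \delta)} followed by subtraction of the mean over tokens, so the output
#' always has zero centroid. Coincident tokens contribute nothing (the
#' regularized denominator sends their term to zero). For any rotation R and
#' translation t, \code{predict_noise(W, R z + t) = R predict_noise(W, z)}
#' provided W was built from rigid-motion-invariant features.
#'
#' @param W r x r weight matrix.
#' @param coords r x 3 current coordinates.
#' @param delta denominator regularizer (angstrom).
#' @return r x 3 matrix with zero column means.
#' @export
predict_noise <- function(W, coords, delta = 1e-6) {
  W <- as.matrix(W)
  coords <- as.matrix(coords)
  if (nrow(W) != nrow(coords)) stop("W/coords token mismatch")
  out <- eps_hat_node(ad_const(W), coords, delta)$value
  if (any(!is.finite(out))) stop("NaN in noise prediction")
  out
}

#' Amino-acid logits from the single representation
#'
#' A linear head on the residue rows only: c_m -> 20 classes. Ligand-atom
#' rows are ignored.
#'
#' @param single r x c_m matrix with attribute \code{n_res}, or a plain
#'   matrix plus explicit \code{n_res}.
#' @param model a [new_model()].
#' @param n_res number of residue rows (defaults to the attribute).
#' @return n_res x 20 logits matrix.
#' @export
predict_sequence_logits <- function(single, model, n_res = NULL) {
  n_res <- n_res %||% attr(single, "n_res")
  if (is.null(n_res)) stop("n_res not given and not carried by `single`")
  P <- wrap_params(model$params)
  logits_node(ad_const(unclass_mat(single)), P, n_res)$value
}

# Full differentiable forward pass: constants + coords + time -> eps_hat and
# sequence logits (as AD nodes when grad = TRUE).
forward_pass <- function(model, feat, coords, t, grad = FALSE) {
  cfg <- model$cfg
  P <- wrap_params(model$params, grad = grad)
  m0 <- single_init_node(P, feat)
  z0 <- pair_init_node(P, feat, coords, t, cfg)
  tk <- trunk_nodes(m0, z0, P, cfg, feat$r)
  W <- weights_node(tk$pair, P, feat$r)
  eps_hat <- eps_hat_node(W, coords, cfg$delta)
  logits <- logits_node(tk$single, P, feat$n_res)
  list(
    eps_hat = eps_hat, logits = logits, W = W,
    single = tk$single, pair = tk$pair, param_nodes = P
  )
}

#' Run the noise-prediction model on a complex state
#'
#' Convenience wrapper: featurizes the masked sequence and ligand, runs the
#' trunk and the equivariant denoiser at the given latent coordinates and
#' time, and returns numeric outputs.
#'
#' @param model a [new_model()].
#' @param masked_seq an [aa_seq()] (possibly masked).
#' @param ligand a [featurize_ligand()] graph.
#' @param coords tokens x 3 latent coordinates.
#' @param t diffusion time in [0, 1].
#' @return list with \code{eps_hat} (tokens x 3, zero centroid),
#'   \code{logits} (n_res x 20), \code{W} (tokens x tokens, symmetric).
#' @export
predict_complex_noise <- function(model, masked_seq, ligand, coords, t) {
  feat <- featurize_complex(masked_seq, ligand, model$embedder, model$cfg)
  if (nrow(as.matrix(coords)) != feat$r) {
    stop("coords/token count mismatch: ", nrow(as.matrix(coords)), " vs ", feat$r)
  }
  fw <- forward_pass(model, feat, as.matrix(coords), t, grad = FALSE)
  list(eps_hat = fw$eps_hat$value, logits = fw$logits$value, W = fw$W$value)
}
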