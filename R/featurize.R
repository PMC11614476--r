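# Input featurization: a (possibly masked) sequence plus a ligand graph
# become the initial single (token) and pair (token-pair) representations.
# Token order is residues first, then ligand heavy atoms, everywhere.
#
# All featurization inputs are assembled as constant one-hot / basis
# matrices here; the learned part (embedding tables and linear maps) lives
# in the parameter list, so the same constants serve the numeric and the
# differentiable paths.

#' Radial-basis embedding of inter-token distances
#'
#' Gaussian bank with \code{n_rbf} centers evenly spaced on
#' [0, \code{rbf_max}] angstrom and width equal to the spacing:
#' \code{exp(-(d - mu_k)^2 / (2 w^2))}. A pair at distance exactly
#' \code{mu_k} scores 1 on basis k. Depends on distances only, hence
#' invariant under any rigid motion of the coordinates.
#'
#' @param coords tokens x 3 matrix, or NULL for an all-zero block.
#' @param r token count (required when \code{coords} is NULL).
#' @param cfg a [model_config()].
#' @return r^2 x n_rbf matrix, row-major over pairs (i, j).
#' @export
rbf_features <- function(coords, cfg = model_config(), r = NULL) {
  if (is.null(coords)) {
    stopifnot(!is.null(r))
    return(matrix(0, r * r, cfg$n_rbf))
  }
  coords <- as.matrix(coords)
  r <- nrow(coords)
  centers <- seq(0, cfg$rbf_max, length.out = cfg$n_rbf)
  w <- centers[2] - centers[1]
  d <- as.matrix(stats::dist(coords))
  dvec <- as.numeric(t(d))  # row-major (i-1)*r + j
  exp(-outer(dvec, centers, `-`)^2 / (2 * w^2))
}

#' Sinusoidal embedding of the diffusion time
#'
#' \code{[sin(omega_k t), cos(omega_k t)]} for geometrically spaced
#' frequencies \code{omega_k = pi 2^(k-1)}; at \code{t = 0} all sine
#' channels are exactly 0 and all cosine channels exactly 1.
#'
#' @param t scalar time in [0, 1].
#' @param cfg a [model_config()].
#' @return numeric vector of length \code{2 * time_dim} (sines then cosines).
#' @export
time_features <- function(t, cfg = model_config()) {
  omega <- pi * 2^(seq_len(cfg$time_dim) - 1L)
  c(sin(omega * t), cos(omega * t))
}

onehot <- function(values, levels) {
  m <- matrix(0, length(values), length(levels))
  idx <- match(values, levels)
  idx[is.na(idx)] <- length(levels)  # out-of-vocabulary bucket = last level
  m[cbind(seq_along(values), idx)] <- 1
  m
}

#' Assemble the constant featurization inputs of a complex
#'
#' Builds every input feature that does not depend on the diffusion state:
#' token one-hots, normalized embedder output (computed on the masked
#' sequence), ligand atom-field one-hots, bond-field one-hots injected
#' symmetrically at the (i, j) and (j, i) ligand-pair entries, and the
#' clipped relative-position one-hot (residue-residue offsets clamped to
#' +/- r_max; any pair involving a ligand atom falls in a separate bin).
#'
#' @param masked_seq an [aa_seq()] (possibly containing MASK tokens).
#' @param ligand a [featurize_ligand()] graph.
#' @param embedder residue embedder closure.
#' @param cfg a [model_config()].
#' @return list of constant matrices plus token bookkeeping.
#' @export
featurize_complex <- function(masked_seq, ligand, embedder, cfg = model_config()) {
  masked_seq <- aa_seq(masked_seq)
  n_res <- length(masked_seq)
  n_lig <- n_ligand_atoms(ligand)
  r <- n_res + n_lig
  lv <- ligand_field_levels()

  tok <- matrix(0, r, 22L)
  tok[seq_len(n_res), ] <- onehot(unclass(masked_seq), aa_alphabet())

  emb <- embedder(masked_seq)
  if (nrow(emb) != n_res) stop("embedder output length mismatch: got ",
                               nrow(emb), " rows for ", n_res, " residues")
  if (ncol(emb) != cfg$embed_dim) stop("embedder dimension mismatch: got ",
                                       ncol(emb), ", configured ", cfg$embed_dim)
  # per-residue normalization of the embedder output
  sd0 <- apply(emb, 1L, stats::sd)
  emb_n <- (emb - rowMeans(emb)) / ifelse(sd0 > 1e-12, sd0, 1)
  esm <- matrix(0, r, cfg$embed_dim)
  esm[seq_len(n_res), ] <- emb_n
  res_ind <- matrix(0, r, 1L)
  res_ind[seq_len(n_res), 1L] <- 1

  atom_oh <- lapply(names(lv$atom), function(f) {
    m <- matrix(0, r, length(lv$atom[[f]]))
    if (n_lig > 0) {
      m[n_res + seq_len(n_lig), ] <- onehot(ligand$atoms[[f]], lv$atom[[f]])
    }
    m
  })
  names(atom_oh) <- names(lv$atom)

  field_map <- c(bond_type = "bond_type", bond_stereo = "stereochemistry",
                 is_conjugated = "is_conjugated")
  bond_oh <- lapply(names(lv$bond), function(f) {
    m <- matrix(0, r * r, length(lv$bond[[f]]))
    if (nrow(ligand$bonds) > 0) {
      oh <- onehot(ligand$bonds[[field_map[[f]]]], lv$bond[[f]])
      gi <- n_res + ligand$bonds$atom_i
      gj <- n_res + ligand$bonds$atom_j
      # symmetric injection at (i, j) and (j, i)
      m[(gi - 1L) * r + gj, ] <- m[(gi - 1L) * r + gj, , drop = FALSE] + oh
      m[(gj - 1L) * r + gi, ] <- m[(gj - 1L) * r + gi, , drop = FALSE] + oh
    }
    m
  })
  names(bond_oh) <- names(lv$bond)

  # relative positions: residue-residue offsets clipped to +/- r_max,
  # one extra bin for any pair touching a ligand atom
  n_bins <- 2L * cfg$r_max + 2L
  i_of <- rep(seq_len(r), each = r)
  j_of <- rep(seq_len(r), times = r)
  bin <- rep(n_bins, r * r)
  rr <- i_of <= n_res & j_of <= n_res
  off <- pmax(pmin(i_of[rr] - j_of[rr], cfg$r_max), -cfg$r_max)
  bin[rr] <- off + cfg$r_max + 1L
  relpos <- matrix(0, r * r, n_bins)
  relpos[cbind(seq_len(r * r), bin)] <- 1

  list(
    n_res = n_res, n_lig = n_lig, r = r,
    token_kinds = c(rep("residue", n_res), rep("ligand_atom", n_lig)),
    masked_seq = masked_seq,
    tok = tok, esm = esm, res_ind = res_ind,
    atom_oh = atom_oh, bond_oh = bond_oh, relpos = relpos
  )
}

# initial single representation as an AD node given wrapped parameter nodes
single_init_node <- function(P, feat) {
  s <- ad_matmul(ad_const(feat$tok), P[["feat.tok_embed"]])
  s <- ad_add(s, ad_matmul(ad_const(feat$esm), P[["feat.esm_W"]]))
  s <- ad_add(s, ad_matmul(ad_const(feat$res_ind), P[["feat.esm_b"]]))
  for (f in names(feat$atom_oh)) {
    s <- ad_add(s, ad_matmul(ad_const(feat$atom_oh[[f]]), P[[paste0("feat.atom.", f)]]))
  }
  s
}

# initial pair representation as an AD node; coords may be NULL
pair_init_node <- function(P, feat, coords, t, cfg) {
  z <- ad_matmul(ad_const(feat$relpos), P[["feat.relpos_W"]])
  for (f in names(feat$bond_oh)) {
    z <- ad_add(z, ad_matmul(ad_const(feat$bond_oh[[f]]), P[[paste0("feat.bond.", f)]]))
  }
  rbf <- rbf_features(coords, cfg, r = feat$r)
  z <- ad_add(z, ad_matmul(ad_const(rbf), P[["feat.rbf_W"]]))
  tf <- matrix(time_features(t, cfg), feat$r^2, 2L * cfg$time_dim, byrow = TRUE)
  ad_add(z, ad_matmul(ad_const(tf), P[["feat.time_W"]]))
}

wrap_params <- function(params, grad = FALSE) {
  lapply(params, if (grad) ad_param else ad_const)
}

#' Build the initial single representation
#'
#' Residue rows are the learned token embedding plus the linearly mapped,
#' per-residue-normalized embedder output; ligand-atom rows are the sum of
#' the per-field atom-feature embeddings. Token order is residues first.
#'
#' @param masked_seq an [aa_seq()].
#' @param ligand a [featurize_ligand()] graph.
#' @param embedder residue embedder closure (defaults to the model's).
#' @param model a [new_model()].
#' @return r x c_m numeric matrix of class \code{single_rep} with attributes
#'   \code{token_kinds}, \code{n_res}, \code{ligand}, \code{masked_seq}.
#' @export
build_single_representation <- function(masked_seq, ligand, embedder = NULL,
                                        model) {
  embedder <- embedder %||% model$embedder
  feat <- featurize_complex(masked_seq, ligand, embedder, model$cfg)
  P <- wrap_params(model$params)
  s <- single_init_node(P, feat)$value
  structure(s,
    class = "single_rep", token_kinds = feat$token_kinds,
    n_res = feat$n_res, ligand = ligand, masked_seq = feat$masked_seq
  )
}

#' Build the initial pair representation
#'
#' All token pairs receive the clipped relative-position encoding (offset
#' one-hot, linearly mapped; ligand-involved pairs use a dedicated bin),
#' symmetric bond-feature embeddings on bonded ligand pairs, RBF embeddings
#' of the current inter-token distances (zeros when no coordinates are
#' given), and a broadcast sinusoidal embedding of the diffusion time.
#'
#' @param single a [build_single_representation()] result (carries the token
#'   bookkeeping).
#' @param coords tokens x 3 matrix of current coordinates, or NULL.
#' @param time scalar diffusion time in [0, 1].
#' @param model a [new_model()].
#' @return r^2 x c_z numeric matrix of class \code{pair_rep} (row-major over
#'   pairs), attribute \code{r}.
#' @export
build_pair_representation <- function(single, coords, time, model) {
  feat <- featurize_complex(
    attr(single, "masked_seq"), attr(single, "ligand"),
    model$embedder, model$cfg
  )
  if (!is.null(coords) && nrow(as.matrix(coords)) != feat$r) {
    stop("coords/token count mismatch: ", nrow(as.matrix(coords)),
         " vs ", feat$r)
  }
  P <- wrap_params(model$params)
  z <- pair_init_node(P, feat, coords, time, model$cfg)$value
  structure(z, class = "pair_rep", r = feat$r)
}
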