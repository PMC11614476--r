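# The residual feature update trunk: gated single-representation attention
# with pair bias (SRA), the outer-product update (OPU) lifting token features
# to pair features, and outgoing/incoming triangle multiplicative updates.
# Every sub-module is applied residually. Row index convention for pair
# tensors: p = (i-1)*r + j.

# -- SRA: gated multi-head attention over tokens with additive pair bias ----
sra_node <- function(m, z, P, pre, cfg, r) {
  ml <- ad_layernorm_rows(m, P[[paste0(pre, "sra.ln_m.g")]], P[[paste0(pre, "sra.ln_m.b")]])
  q <- ad_matmul(ml, P[[paste0(pre, "sra.q")]])
  k <- ad_matmul(ml, P[[paste0(pre, "sra.k")]])
  v <- ad_matmul(ml, P[[paste0(pre, "sra.v")]])
  zl <- ad_layernorm_rows(z, P[[paste0(pre, "sra.ln_z.g")]], P[[paste0(pre, "sra.ln_z.b")]])
  bias <- ad_matmul(zl, P[[paste0(pre, "sra.bias")]])  # r^2 x n_head
  gate <- ad_sigmoid(ad_add_rowvec(
    ad_matmul(ml, P[[paste0(pre, "sra.gate_W")]]), P[[paste0(pre, "sra.gate_b")]]
  ))
  heads <- vector("list", cfg$n_head)
  attn <- vector("list", cfg$n_head)
  for (h in seq_len(cfg$n_head)) {
    cols <- (h - 1L) * cfg$c_head + seq_len(cfg$c_head)
    qh <- ad_slice_cols(q, cols)
    kh <- ad_slice_cols(k, cols)
    vh <- ad_slice_cols(v, cols)
    scores <- ad_scale(ad_matmul(qh, ad_transpose(kh)), 1 / sqrt(cfg$c_head))
    bh <- ad_reshape_sq(ad_slice_cols(bias, h), r)
    a <- ad_rowsoftmax(ad_add(scores, bh))
    attn[[h]] <- a
    o <- ad_matmul(a, vh)
    heads[[h]] <- ad_mul(ad_slice_cols(gate, cols), o)
  }
  out <- ad_add_rowvec(
    ad_matmul(ad_concat_cols(heads), P[[paste0(pre, "sra.out_W")]]),
    P[[paste0(pre, "sra.out_b")]]
  )
  list(delta = out, attention = attn)
}

# -- OPU: pairwise Kronecker lift of two token projections -----------------
opu_node <- function(m, P, pre, cfg, r) {
  ml <- ad_layernorm_rows(m, P[[paste0(pre, "opu.ln.g")]], P[[paste0(pre, "opu.ln.b")]])
  a <- ad_add_rowvec(ad_matmul(ml, P[[paste0(pre, "opu.a_W")]]), P[[paste0(pre, "opu.a_b")]])
  b <- ad_add_rowvec(ad_matmul(ml, P[[paste0(pre, "opu.b_W")]]), P[[paste0(pre, "opu.b_b")]])
  o <- ad_outer_pairs(a, b, r)
  ad_add_rowvec(ad_matmul(o, P[[paste0(pre, "opu.out_W")]]), P[[paste0(pre, "opu.out_b")]])
}

# -- triangle multiplicative update (outgoing or incoming) -----------------
tri_node <- function(z, P, pre_dir, cfg, r, direction) {
  zl <- ad_layernorm_rows(z, P[[paste0(pre_dir, "ln.g")]], P[[paste0(pre_dir, "ln.b")]])
  a <- ad_mul(
    ad_sigmoid(ad_add_rowvec(ad_matmul(zl, P[[paste0(pre_dir, "a_g")]]),
                             P[[paste0(pre_dir, "a_gb")]])),
    ad_add_rowvec(ad_matmul(zl, P[[paste0(pre_dir, "a_p")]]),
                  P[[paste0(pre_dir, "a_pb")]])
  )
  b <- ad_mul(
    ad_sigmoid(ad_add_rowvec(ad_matmul(zl, P[[paste0(pre_dir, "b_g")]]),
                             P[[paste0(pre_dir, "b_gb")]])),
    ad_add_rowvec(ad_matmul(zl, P[[paste0(pre_dir, "b_p")]]),
                  P[[paste0(pre_dir, "b_pb")]])
  )
  u <- ad_triangle_mix(a, b, r, direction)
  ul <- ad_layernorm_rows(u, P[[paste0(pre_dir, "ln_u.g")]], P[[paste0(pre_dir, "ln_u.b")]])
  proj <- ad_add_rowvec(ad_matmul(ul, P[[paste0(pre_dir, "out_W")]]),
                        P[[paste0(pre_dir, "out_b")]])
  gate <- ad_sigmoid(ad_add_rowvec(ad_matmul(zl, P[[paste0(pre_dir, "out_g")]]),
                                   P[[paste0(pre_dir, "out_gb")]]))
  ad_mul(gate, proj)
}

# full trunk as AD nodes; returns final single/pair nodes (+ attention maps)
trunk_nodes <- function(m, z, P, cfg, r) {
  attn <- list()
  for (b in seq_len(cfg$n_blocks)) {
    pre <- sprintf("blk%d.", b)
    sra <- sra_node(m, z, P, pre, cfg, r)
    m <- ad_add(m, sra$delta)
    attn[[b]] <- sra$attention
    z <- ad_add(z, opu_node(m, P, pre, cfg, r))
    z <- ad_add(z, tri_node(z, P, paste0(pre, "tri_out."), cfg, r, "outgoing"))
    z <- ad_add(z, tri_node(z, P, paste0(pre, "tri_in."), cfg, r, "incoming"))
    if (any(!is.finite(m$value))) stop("non-finite single representation in block ", b)
    if (any(!is.finite(z$value))) stop("non-finite pair representation in block ", b)
  }
  list(single = m, pair = z, attention = attn)
}

check_trunk_shapes <- function(single, pair, cfg) {
  if (ncol(single) != cfg$c_m) stop("single representation has ", ncol(single),
                                    " channels, config expects c_m = ", cfg$c_m)
  if (ncol(pair) != cfg$c_z) stop("pair representation has ", ncol(pair),
                                  " channels, config expects c_z = ", cfg$c_z)
  r <- nrow(single)
  if (nrow(pair) != r * r) stop("pair representation rows (", nrow(pair),
                                ") are not the square of the token count (", r, ")")
  r
}

#' One single-representation attention block
#'
#' Gated multi-head self-attention over tokens with an additive bias derived
#' from the (layer-normalized) pair representation, applied residually:
#' LayerNorm, no-bias q/k/v per head, pair bias, sigmoid gate,
#' \code{softmax_j(q k' / sqrt(C) + b)}, gated weighted sum of values,
#' concatenation over heads, output projection.
#'
#' @param single r x c_m matrix.
#' @param pair r^2 x c_z matrix (row-major pairs).
#' @param model a [new_model()].
#' @param block which trunk block's weights to use.
#' @return list with \code{single} (updated, residual) and
#'   \code{attention} (list over heads of r x r row-stochastic matrices).
#' @export
sra_block <- function(single, pair, model, block = 1L) {
  cfg <- model$cfg
  r <- check_trunk_shapes(single, pair, cfg)
  P <- wrap_params(model$params)
  out <- sra_node(ad_const(unclass_mat(single)), ad_const(unclass_mat(pair)),
                  P, sprintf("blk%d.", block), cfg, r)
  list(
    single = unclass_mat(single) + out$delta$value,
    attention = lapply(out$attention, ad_value)
  )
}

#' Outer-product update
#'
#' Lifts the single representation to a pair-representation increment:
#' LayerNorm, two linear projections \code{a, b} of width \code{c_opu}, the
#' flattened pairwise Kronecker product \code{a_i (x) b_j}, and a linear map
#' to c_z. No averaging over any axis. Returned as the residual delta plus
#' the updated pair tensor.
#'
#' @inheritParams sra_block
#' @return list with \code{pair} (updated) and \code{delta}.
#' @export
outer_product_update <- function(single, pair, model, block = 1L) {
  cfg <- model$cfg
  r <- check_trunk_shapes(single, pair, cfg)
  P <- wrap_params(model$params)
  delta <- opu_node(ad_const(unclass_mat(single)), P, sprintf("blk%d.", block),
                    cfg, r)$value
  list(pair = unclass_mat(pair) + delta, delta = delta)
}

#' Triangle multiplicative update
#'
#' Multiplicative pair update over the third node k: gated projections
#' \code{a, b} from LayerNorm(z); outgoing mixes edges (i, k) and (j, k),
#' incoming mixes (k, i) and (k, j); the mixed tensor is layer-normalized,
#' projected back to c_z and sigmoid-gated, then added residually.
#'
#' @param pair r^2 x c_z matrix.
#' @param direction \code{"outgoing"} or \code{"incoming"}.
#' @inheritParams sra_block
#' @return updated pair matrix.
#' @export
triangle_update <- function(pair, direction = c("outgoing", "incoming"),
                            model, block = 1L) {
  direction <- match.arg(direction)
  cfg <- model$cfg
  r2 <- nrow(pair)
  r <- as.integer(round(sqrt(r2)))
  if (r * r != r2) stop("pair tensor is not square")
  P <- wrap_params(model$params)
  pre_dir <- sprintf("blk%d.%s.", block, if (direction == "outgoing") "tri_out" else "tri_in")
  unclass_mat(pair) + tri_node(ad_const(unclass_mat(pair)), P, pre_dir, cfg, r, direction)$value
}

#' Run the full trunk
#'
#' \code{n_blocks} repetitions of SRA, OPU, outgoing triangle, incoming
#' triangle, all residual. \code{n_blocks = 0} is the identity.
#'
#' @inheritParams sra_block
#' @return list with final \code{single} and \code{pair} matrices.
#' @export
run_trunk <- function(single, pair, model) {
  cfg <- model$cfg
  r <- check_trunk_shapes(single, pair, cfg)
  P <- wrap_params(model$params)
  out <- trunk_nodes(ad_const(unclass_mat(single)), ad_const(unclass_mat(pair)),
                     P, cfg, r)
  list(single = out$single$value, pair = out$pair$value)
}

unclass_mat <- function(x) {
  attrs <- attributes(x)
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  m
}
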