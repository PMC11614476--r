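# shared test helpers: tiny cached models, random rotations, reference
# implementations used as independent oracles

.helper_cache <- new.env(parent = emptyenv())

tiny_cfg <- function(...) {
  args <- list(
    c_m = 16L, c_z = 8L, n_blocks = 1L, c_head = 4L, n_head = 2L,
    c_opu = 3L, w_hidden = 8L, embed_dim = 8L, T = 16L
  )
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(model_config, args)
}

tiny_model <- function() {
  if (is.null(.helper_cache$tiny)) {
    .helper_cache$tiny <- new_model(tiny_cfg(), seed = 7L)
  }
  .helper_cache$tiny
}

small_model <- function() {
  if (is.null(.helper_cache$small)) {
    .helper_cache$small <- new_model(small_config(T = 16L), seed = 3L)
  }
  .helper_cache$small
}

toy_cx <- function(n_res = 8L, smiles = "CCO", seed = 5L) {
  key <- paste0("cx_", n_res, "_", smiles, "_", seed)
  if (is.null(.helper_cache[[key]])) {
    .helper_cache[[key]] <- generate_toy_complex(n_res, smiles, seed = seed)
  }
  .helper_cache[[key]]
}

# uniform random rotation matrix from a unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3)
}

apply_rigid <- function(x, R, tr) sweep(x %*% t(R), 2L, tr, `+`)

# independent dynamic-programming Levenshtein oracle
dp_levenshtein <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(a) + 1L, length(b) + 1L)
  d[, 1] <- 0:length(a)
  d[1, ] <- 0:length(b)
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1L, d[i + 1, j] + 1L,
        d[i, j] + (a[i] != b[j])
      )
    }
  }
  d[length(a) + 1L, length(b) + 1L]
}

# straight-line independent transcription of the gated pair-bias attention
# block (the oracle for sra_block); works on one head set at a time
oracle_sra <- function(m, z, par, pre, cfg) {
  r <- nrow(m)
  ln <- function(x, g, b, eps = 1e-5) {
    t(apply(x, 1L, function(row) {
      (row - mean(row)) / sqrt(mean((row - mean(row))^2) + eps) * g + b
    }))
  }
  ml <- ln(m, par[[paste0(pre, "sra.ln_m.g")]], par[[paste0(pre, "sra.ln_m.b")]])
  zl <- ln(z, par[[paste0(pre, "sra.ln_z.g")]], par[[paste0(pre, "sra.ln_z.b")]])
  q <- ml %*% par[[paste0(pre, "sra.q")]]
  k <- ml %*% par[[paste0(pre, "sra.k")]]
  v <- ml %*% par[[paste0(pre, "sra.v")]]
  bias <- zl %*% par[[paste0(pre, "sra.bias")]]
  gate <- 1 / (1 + exp(-sweep(ml %*% par[[paste0(pre, "sra.gate_W")]], 2L,
                              par[[paste0(pre, "sra.gate_b")]], `+`)))
  heads <- NULL
  for (h in seq_len(cfg$n_head)) {
    cols <- (h - 1L) * cfg$c_head + seq_len(cfg$c_head)
    o <- matrix(0, r, cfg$c_head)
    for (i in seq_len(r)) {
      sc <- numeric(r)
      for (j in seq_len(r)) {
        sc[j] <- sum(q[i, cols] * k[j, cols]) / sqrt(cfg$c_head) +
          bias[(i - 1L) * r + j, h]
      }
      a <- exp(sc - max(sc))
      a <- a / sum(a)
      for (j in seq_len(r)) o[i, ] <- o[i, ] + a[j] * v[j, cols]
      o[i, ] <- gate[i, cols] * o[i, ]
    }
    heads <- cbind(heads, o)
  }
  sweep(heads %*% par[[paste0(pre, "sra.out_W")]], 2L,
        par[[paste0(pre, "sra.out_b")]], `+`)
}

# independent double-loop transcription of the outer-product update
oracle_opu <- function(m, par, pre, cfg, r) {
  ln <- function(x, g, b, eps = 1e-5) {
    t(apply(x, 1L, function(row) {
      (row - mean(row)) / sqrt(mean((row - mean(row))^2) + eps) * g + b
    }))
  }
  ml <- ln(m, par[[paste0(pre, "opu.ln.g")]], par[[paste0(pre, "opu.ln.b")]])
  a <- sweep(ml %*% par[[paste0(pre, "opu.a_W")]], 2L, par[[paste0(pre, "opu.a_b")]], `+`)
  b <- sweep(ml %*% par[[paste0(pre, "opu.b_W")]], 2L, par[[paste0(pre, "opu.b_b")]], `+`)
  C <- cfg$c_opu
  out <- matrix(0, r * r, ncol(par[[paste0(pre, "opu.out_W")]]))
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      o <- as.numeric(outer(a[i, ], b[j, ]))  # flat index (u-1)*C + v
      flat <- numeric(C * C)
      for (u in seq_len(C)) for (vv in seq_len(C)) {
        flat[(u - 1L) * C + vv] <- a[i, u] * b[j, vv]
      }
      out[(i - 1L) * r + j, ] <- flat %*% par[[paste0(pre, "opu.out_W")]] +
        par[[paste0(pre, "opu.out_b")]]
    }
  }
  out
}
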