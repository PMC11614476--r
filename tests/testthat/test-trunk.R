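rand_reps <- function(cfg, r, seed = 1) {
  set.seed(seed)
  list(
    single = matrix(rnorm(r * cfg$c_m), r, cfg$c_m),
    pair = matrix(rnorm(r * r * cfg$c_z), r * r, cfg$c_z)
  )
}

test_that("attention is uniform when queries/keys vanish and the pair bias is zero", {
  model <- new_model(tiny_cfg(), seed = 1)
  model$params[["blk1.sra.q"]][] <- 0
  model$params[["blk1.sra.bias"]][] <- 0
  r <- 5L
  reps <- rand_reps(model$cfg, r)
  out <- sra_block(reps$single, reps$pair, model)
  for (a in out$attention) {
    expect_equal(a, matrix(1 / r, r, r), tolerance = 1e-12)
  }
})

test_that("attention rows are non-negative and sum to one", {
  model <- small_model()
  r <- 6L
  reps <- rand_reps(model$cfg, r, seed = 2)
  out <- sra_block(reps$single, reps$pair, model)
  for (a in out$attention) {
    expect_true(all(a >= 0))
    expect_lt(max(abs(rowSums(a) - 1)), 1e-6)
  }
})

test_that("a closed sigmoid gate makes the attention block the identity", {
  model <- new_model(tiny_cfg(), seed = 3)
  model$params[["blk1.sra.gate_W"]][] <- 0
  model$params[["blk1.sra.gate_b"]][] <- -40
  r <- 4L
  reps <- rand_reps(model$cfg, r, seed = 3)
  out <- sra_block(reps$single, reps$pair, model)
  expect_equal(out$single, reps$single, tolerance = 1e-12)
})

test_that("the attention block matches an independent straight-line transcription", {
  cfg <- model_config(c_m = 6L, c_z = 4L, n_blocks = 1L, c_head = 5L,
                      n_head = 1L, c_opu = 3L, w_hidden = 4L, embed_dim = 4L)
  model <- new_model(cfg, seed = 11)
  r <- 4L
  reps <- rand_reps(cfg, r, seed = 4)
  got <- sra_block(reps$single, reps$pair, model)$single - reps$single
  want <- oracle_sra(reps$single, reps$pair, model$params, "blk1.", cfg)
  expect_lt(max(abs(got - want)), 1e-6)
  # multi-head variant against the same oracle
  cfg2 <- tiny_cfg()
  model2 <- new_model(cfg2, seed = 12)
  reps2 <- rand_reps(cfg2, 5L, seed = 5)
  got2 <- sra_block(reps2$single, reps2$pair, model2)$single - reps2$single
  want2 <- oracle_sra(reps2$single, reps2$pair, model2$params, "blk1.", cfg2)
  expect_lt(max(abs(got2 - want2)), 1e-6)
})

test_that("annihilated outer product leaves only the output bias", {
  model <- new_model(tiny_cfg(), seed = 5)
  model$params[["blk1.opu.a_W"]][] <- 0
  model$params[["blk1.opu.a_b"]][] <- 0
  model$params[["blk1.opu.out_b"]][] <- 0.7
  r <- 4L
  reps <- rand_reps(model$cfg, r, seed = 6)
  out <- outer_product_update(reps$single, reps$pair, model)
  expect_equal(out$delta, matrix(0.7, r * r, model$cfg$c_z), tolerance = 1e-12)
})

test_that("the pairwise Kronecker product places basis vectors at the expected flat index", {
  r <- 3L; C <- 4L
  a <- matrix(rep(c(1, 0, 0, 0), each = r), r, C)  # a_i = e_1
  b <- matrix(rep(c(0, 1, 0, 0), each = r), r, C)  # b_j = e_2
  o <- pldiffuser:::ad_outer_pairs(
    pldiffuser:::ad_const(a), pldiffuser:::ad_const(b), r
  )$value
  expect_equal(ncol(o), C * C)
  nz <- which(colSums(abs(o)) > 0)
  expect_equal(nz, (1L - 1L) * C + 2L)  # flat index of (1, 2)
  expect_true(all(o[, nz] == 1))
})

test_that("the outer-product update matches an explicit double loop", {
  cfg <- model_config(c_m = 6L, c_z = 4L, n_blocks = 1L, c_head = 4L,
                      n_head = 1L, c_opu = 2L, w_hidden = 4L, embed_dim = 4L)
  model <- new_model(cfg, seed = 21)
  r <- 3L
  reps <- rand_reps(cfg, r, seed = 7)
  got <- outer_product_update(reps$single, reps$pair, model)$delta
  want <- oracle_opu(reps$single, model$params, "blk1.", cfg, r)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("triangle updates vanish on zero input with zero biases", {
  model <- new_model(tiny_cfg(), seed = 6)
  r <- 4L
  z0 <- matrix(0, r * r, model$cfg$c_z)
  for (dir in c("outgoing", "incoming")) {
    out <- triangle_update(z0, dir, model)
    expect_equal(out, z0, tolerance = 1e-12)
  }
})

test_that("the triangle k-sum matches its explicit 2x2 hand expansion", {
  model <- new_model(tiny_cfg(), seed = 7)
  cfg <- model$cfg
  r <- 2L
  set.seed(8)
  z <- matrix(rnorm(r * r * cfg$c_z), r * r, cfg$c_z)
  p <- model$params
  ln_vec <- function(x, g, b, eps = 1e-5) {
    (x - mean(x)) / sqrt(mean((x - mean(x))^2) + eps) * g + b
  }
  sig <- function(x) 1 / (1 + exp(-x))
  zl <- t(apply(z, 1, ln_vec, g = p[["blk1.tri_out.ln.g"]], b = p[["blk1.tri_out.ln.b"]]))
  a <- sig(sweep(zl %*% p[["blk1.tri_out.a_g"]], 2, p[["blk1.tri_out.a_gb"]], `+`)) *
    sweep(zl %*% p[["blk1.tri_out.a_p"]], 2, p[["blk1.tri_out.a_pb"]], `+`)
  b <- sig(sweep(zl %*% p[["blk1.tri_out.b_g"]], 2, p[["blk1.tri_out.b_gb"]], `+`)) *
    sweep(zl %*% p[["blk1.tri_out.b_p"]], 2, p[["blk1.tri_out.b_pb"]], `+`)
  idx <- function(i, j) (i - 1L) * r + j
  u <- matrix(0, r * r, cfg$tri_hidden)
  for (i in 1:r) for (j in 1:r) {
    u[idx(i, j), ] <- a[idx(i, 1), ] * b[idx(j, 1), ] + a[idx(i, 2), ] * b[idx(j, 2), ]
  }
  ul <- t(apply(u, 1, ln_vec, g = p[["blk1.tri_out.ln_u.g"]], b = p[["blk1.tri_out.ln_u.b"]]))
  proj <- sweep(ul %*% p[["blk1.tri_out.out_W"]], 2, p[["blk1.tri_out.out_b"]], `+`)
  gate <- sig(sweep(zl %*% p[["blk1.tri_out.out_g"]], 2, p[["blk1.tri_out.out_gb"]], `+`))
  want <- z + gate * proj
  got <- triangle_update(z, "outgoing", model)
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("outgoing on z equals incoming on t(z), transposed, when projections are tied", {
  model <- new_model(tiny_cfg(), seed = 9)
  # tie the two edge projections and share weights across directions
  for (suf in c("ln.g", "ln.b", "a_p", "a_pb", "a_g", "a_gb",
                "ln_u.g", "ln_u.b", "out_W", "out_b", "out_g", "out_gb")) {
    model$params[[paste0("blk1.tri_in.", suf)]] <-
      model$params[[paste0("blk1.tri_out.", suf)]]
  }
  for (suf in c("b_p", "b_pb", "b_g", "b_gb")) {
    model$params[[paste0("blk1.tri_out.", suf)]] <-
      model$params[[sub("b_", "a_", paste0("blk1.tri_out.", suf))]]
    model$params[[paste0("blk1.tri_in.", suf)]] <-
      model$params[[paste0("blk1.tri_out.", suf)]]
  }
  r <- 4L
  set.seed(10)
  z <- matrix(rnorm(r * r * model$cfg$c_z), r * r, model$cfg$c_z)
  i_of <- rep(seq_len(r), each = r)
  j_of <- rep(seq_len(r), times = r)
  tperm <- (j_of - 1L) * r + i_of
  out_z <- triangle_update(z, "outgoing", model) - z
  in_zt <- triangle_update(z[tperm, ], "incoming", model) - z[tperm, ]
  expect_lt(max(abs(out_z - in_zt[tperm, ])), 1e-9)
})

test_that("a zero-block trunk is the identity and the trunk is deterministic", {
  cfg <- tiny_cfg(n_blocks = 0L)
  model <- new_model(cfg, seed = 13)
  reps <- rand_reps(cfg, 5L, seed = 11)
  out <- run_trunk(reps$single, reps$pair, model)
  expect_identical(out$single, reps$single)
  expect_identical(out$pair, reps$pair)
  model2 <- small_model()
  reps2 <- rand_reps(model2$cfg, 5L, seed = 12)
  o1 <- run_trunk(reps2$single, reps2$pair, model2)
  o2 <- run_trunk(reps2$single, reps2$pair, model2)
  expect_identical(o1, o2)
})

test_that("the trunk is equivariant to token permutations", {
  model <- small_model()
  r <- 5L
  reps <- rand_reps(model$cfg, r, seed = 13)
  perm <- c(1, 2, 4, 5, 3)
  i_of <- rep(seq_len(r), each = r)
  j_of <- rep(seq_len(r), times = r)
  pair_perm <- (match(i_of, perm) - 1L) * r + match(j_of, perm)
  # permuted inputs
  sp <- reps$single[perm, ]
  zp <- reps$pair
  for (i in seq_len(r)) for (j in seq_len(r)) {
    zp[(i - 1L) * r + j, ] <- reps$pair[(perm[i] - 1L) * r + perm[j], ]
  }
  base <- run_trunk(reps$single, reps$pair, model)
  permed <- run_trunk(sp, zp, model)
  expect_equal(permed$single, base$single[perm, ], tolerance = 1e-10)
  for (i in seq_len(r)) for (j in seq_len(r)) {
    expect_equal(permed$pair[(i - 1L) * r + j, ],
                 base$pair[(perm[i] - 1L) * r + perm[j], ],
                 tolerance = 1e-10)
  }
})
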