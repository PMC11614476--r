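# Finite-difference verification of every reverse-mode primitive, plus the
# full-model gradient check.

fd_check <- function(build, inputs, tol = 1e-6, h = 1e-6) {
  # build: function(list of ad nodes) -> scalar node
  nodes <- lapply(inputs, pldiffuser:::ad_param)
  root <- build(nodes)
  pldiffuser:::ad_backward(root)
  for (k in seq_along(inputs)) {
    g <- nodes[[k]]$grad
    for (idx in seq_len(min(length(inputs[[k]]), 5L))) {
      plus <- inputs; minus <- inputs
      plus[[k]][idx] <- plus[[k]][idx] + h
      minus[[k]][idx] <- minus[[k]][idx] - h
      f_plus <- build(lapply(plus, pldiffuser:::ad_const))$value
      f_minus <- build(lapply(minus, pldiffuser:::ad_const))$value
      fd <- (f_plus - f_minus) / (2 * h)
      expect_equal(unname(g[idx]), unname(fd), tolerance = tol)
    }
  }
}

test_that("elementwise and matrix primitives backpropagate correctly", {
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(12), 3, 4)
  M <- matrix(rnorm(20), 4, 5)
  v <- rnorm(4)
  ad <- function(f) f  # readability
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_mul(n[[1]], n[[2]])), list(A, B))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_sub(n[[1]], n[[2]])), list(A, B))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_matmul(n[[1]], n[[2]])), list(A, M))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_add_rowvec(n[[1]], n[[2]])), list(A, v))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_sigmoid(n[[1]])), list(A))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_relu(n[[1]])), list(A + 0.3))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_log(pldiffuser:::ad_sigmoid(n[[1]]))), list(A))
  fd_check(function(n) pldiffuser:::ad_sqrt(pldiffuser:::ad_sum(pldiffuser:::ad_mul(n[[1]], n[[1]]))), list(A))
})

test_that("softmax, layernorm and structural primitives backpropagate correctly", {
  set.seed(2)
  A <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(12), 3, 4)
  g <- rnorm(4); b <- rnorm(4)
  fd_check(function(n) {
    pldiffuser:::ad_sum(pldiffuser:::ad_mul(
      pldiffuser:::ad_rowsoftmax(n[[1]]), pldiffuser:::ad_const(W)
    ))
  }, list(A), tol = 1e-5)
  fd_check(function(n) {
    pldiffuser:::ad_sum(pldiffuser:::ad_mul(
      pldiffuser:::ad_layernorm_rows(n[[1]], n[[2]], n[[3]]),
      pldiffuser:::ad_const(W)
    ))
  }, list(A, g, b), tol = 1e-5)
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_gather_rows(n[[1]], c(2, 2, 3))), list(A))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_mul(
    pldiffuser:::ad_permute_rows(n[[1]], c(3, 1, 2)), pldiffuser:::ad_const(W)
  )), list(A))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_mul(
    pldiffuser:::ad_center_rows(n[[1]]), pldiffuser:::ad_const(W)
  )), list(A))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_slice_cols(n[[1]], 2:3)), list(A))
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_mul(
    pldiffuser:::ad_transpose(n[[1]]), pldiffuser:::ad_const(t(W))
  )), list(A))
})

test_that("the pairwise Kronecker, triangle-mix and field primitives backpropagate correctly", {
  set.seed(3)
  r <- 3L
  a <- matrix(rnorm(r * 2), r, 2)
  b <- matrix(rnorm(r * 2), r, 2)
  Wq <- matrix(rnorm(r * r * 4), r * r, 4)
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_mul(
    pldiffuser:::ad_outer_pairs(n[[1]], n[[2]], r), pldiffuser:::ad_const(Wq)
  )), list(a, b), tol = 1e-5)
  e1 <- matrix(rnorm(r * r * 2), r * r, 2)
  e2 <- matrix(rnorm(r * r * 2), r * r, 2)
  msk <- matrix(rnorm(r * r * 2), r * r, 2)
  for (dir in c("outgoing", "incoming")) {
    fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_mul(
      pldiffuser:::ad_triangle_mix(n[[1]], n[[2]], r, dir), pldiffuser:::ad_const(msk)
    )), list(e1, e2), tol = 1e-5)
  }
  coords <- matrix(rnorm(r * 3), r, 3) * 3
  D <- pldiffuser:::unit_differences(coords)
  Wm <- matrix(rnorm(r * r), r, r)
  G <- matrix(rnorm(r * 3), r, 3)
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_mul(
    pldiffuser:::ad_weighted_field(n[[1]], D), pldiffuser:::ad_const(G)
  )), list(Wm), tol = 1e-5)
  w <- matrix(rnorm(r * r), r * r, 1)
  fd_check(function(n) pldiffuser:::ad_sum(pldiffuser:::ad_mul(
    pldiffuser:::ad_reshape_sq(n[[1]], r), pldiffuser:::ad_const(Wm)
  )), list(w))
})

test_that("the full training loss gradient matches finite differences", {
  model <- new_model(tiny_cfg(), seed = 42)
  cx <- toy_cx(6, "CCO", seed = 5)
  sched <- make_schedule(model$cfg$T, model$cfg$schedule)
  ln <- pldiffuser:::step_loss_nodes(model, cx, sched, step_seed = 99, grad = TRUE)
  pldiffuser:::ad_backward(ln$total)
  grads <- pldiffuser:::ad_grads(ln$param_nodes)
  loss_at <- function(params) {
    m2 <- model
    m2$params <- params
    pldiffuser:::step_loss_nodes(m2, cx, sched, step_seed = 99, grad = FALSE)$total$value
  }
  set.seed(8)
  checked <- 0L
  for (nm in sample(names(model$params), 10)) {
    p <- model$params
    idx <- sample(length(p[[nm]]), 1)
    h <- 1e-5
    p[[nm]][idx] <- p[[nm]][idx] + h
    up <- loss_at(p)
    p[[nm]][idx] <- p[[nm]][idx] - 2 * h
    dn <- loss_at(p)
    fd <- (up - dn) / (2 * h)
    an <- grads[[nm]][idx]
    if (abs(fd) > 1e-7 || abs(an) > 1e-7) {
      expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 3L)
})
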