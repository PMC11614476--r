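# Minimal tape-based reverse-mode automatic differentiation.
#
# Nodes are environments holding a numeric value (scalar, vector or matrix),
# their parent nodes and a backward closure mapping the upstream gradient to
# per-parent gradients. ad_backward() topologically sorts the graph from the
# scalar loss and accumulates gradients; ad_param leaves collect them.
# Every primitive's backward rule is finite-difference tested.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  .ad_env$counter <- .ad_env$counter + 1L
  e$id <- .ad_env$counter
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

#' @export
print.ad_node <- function(x, ...) {
  d <- dim(x$value)
  cat(sprintf(
    "<ad_node id=%d %s>\n", x$id,
    if (is.null(d)) sprintf("len=%d", length(x$value)) else paste(d, collapse = "x")
  ))
  invisible(x)
}

is_node <- function(x) inherits(x, "ad_node")
as_node <- function(x) if (is_node(x)) x else ad_node(x)

# leaf with gradient tracking
ad_param <- function(value) {
  n <- ad_node(value)
  n$is_param <- TRUE
  n
}
ad_const <- function(value) ad_node(value)

ad_value <- function(x) if (is_node(x)) x$value else x

acc_grad <- function(node, g) {
  if (is.null(node$backfn) && is.null(node$is_param)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# reverse pass from a scalar root
ad_backward <- function(root) {
  stopifnot(is_node(root), length(root$value) == 1L)
  order <- vector("list", 256L)
  n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
    }
  }
  root$grad <- 1
  for (k in rev(seq_len(n_ord))) {
    nd <- order[[k]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) acc_grad(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}

# ---- primitives ---------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ad_node(a$value + b$value, list(a, b), function(g) {
    list(
      if (length(a$value) == 1L && length(g) > 1L) sum(g) else g,
      if (length(b$value) == 1L && length(g) > 1L) sum(g) else g
    )
  })
}

ad_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ad_node(a$value - b$value, list(a, b), function(g) {
    list(
      if (length(a$value) == 1L && length(g) > 1L) sum(g) else g,
      if (length(b$value) == 1L && length(g) > 1L) -sum(g) else -g
    )
  })
}

ad_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ad_node(a$value * b$value, list(a, b), function(g) {
    list(
      if (length(a$value) == 1L && length(g) > 1L) sum(g * b$value) else g * b$value,
      if (length(b$value) == 1L && length(g) > 1L) sum(g * a$value) else g * a$value
    )
  })
}

# multiply by a plain constant (no gradient to the constant)
ad_scale <- function(a, s) {
  a <- as_node(a)
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  ad_node(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# add a length-c vector to every row of an r x c matrix
ad_add_rowvec <- function(a, v) {
  a <- as_node(a); v <- as_node(v)
  ad_node(sweep(a$value, 2L, as.numeric(v$value), `+`), list(a, v), function(g) {
    cg <- colSums(g)
    list(g, if (is.matrix(v$value)) matrix(cg, nrow = nrow(v$value)) else cg)
  })
}

ad_sigmoid <- function(a) {
  a <- as_node(a)
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_relu <- function(a) {
  a <- as_node(a)
  ad_node(pmax(a$value, 0), list(a), function(g) list(g * (a$value > 0)))
}

ad_log <- function(a) {
  a <- as_node(a)
  ad_node(log(a$value), list(a), function(g) list(g / a$value))
}

ad_sqrt <- function(a) {
  a <- as_node(a)
  s <- sqrt(a$value)
  ad_node(s, list(a), function(g) list(g / (2 * pmax(s, 1e-12))))
}

ad_sum <- function(a) {
  a <- as_node(a)
  ad_node(sum(a$value), list(a), function(g) {
    list(if (is.matrix(a$value)) matrix(g, nrow(a$value), ncol(a$value)) else rep(g, length(a$value)))
  })
}

# softmax over each row
ad_rowsoftmax <- function(a) {
  a <- as_node(a)
  x <- a$value
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  s <- e / rowSums(e)
  ad_node(s, list(a), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# layer normalization over the channel (column) axis of each row, with
# learned gain/bias vectors
ad_layernorm_rows <- function(a, gamma, beta, eps = 1e-5) {
  a <- as_node(a); gamma <- as_node(gamma); beta <- as_node(beta)
  x <- a$value
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gam <- as.numeric(gamma$value)
  out <- sweep(xhat, 2L, gam, `*`)
  out <- sweep(out, 2L, as.numeric(beta$value), `+`)
  ad_node(out, list(a, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gam, `*`)
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, dgamma, dbeta)
  })
}

# value a[idx, ]; backward scatter-adds into the gathered rows
ad_gather_rows <- function(a, idx) {
  a <- as_node(a)
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    for (k in seq_along(idx)) out[idx[k], ] <- out[idx[k], ] + g[k, ]
    list(out)
  })
}

ad_permute_rows <- function(a, perm) {
  a <- as_node(a)
  inv <- order(perm)
  ad_node(a$value[perm, , drop = FALSE], list(a), function(g) {
    list(g[inv, , drop = FALSE])
  })
}

ad_concat_cols <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ad_node(do.call(cbind, lapply(nodes, ad_value)), nodes, function(g) {
    out <- vector("list", length(nodes))
    at <- 0L
    for (k in seq_along(nodes)) {
      out[[k]] <- g[, at + seq_len(widths[k]), drop = FALSE]
      at <- at + widths[k]
    }
    out
  })
}

ad_slice_cols <- function(a, cols) {
  a <- as_node(a)
  ad_node(a$value[, cols, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$value), ncol(a$value))
    out[, cols] <- g
    list(out)
  })
}

# subtract the column means over rows (projection onto the zero-centroid
# subspace); the projection matrix is symmetric so backward is the same map
ad_center_rows <- function(a) {
  a <- as_node(a)
  ad_node(sweep(a$value, 2L, colMeans(a$value)), list(a), function(g) {
    list(sweep(g, 2L, colMeans(g)))
  })
}

# pairwise Kronecker lift: a, b are r x C; output is r^2 x C^2 with row
# p = (i-1)*r + j holding kron(a[i, ], b[j, ]) (flat index (u-1)*C + v)
ad_outer_pairs <- function(a, b, r) {
  a <- as_node(a); b <- as_node(b)
  C <- ncol(a$value)
  i_of <- rep(seq_len(r), each = r)
  j_of <- rep(seq_len(r), times = r)
  EA <- a$value[i_of, , drop = FALSE]
  EB <- b$value[j_of, , drop = FALSE]
  o <- EA[, rep(seq_len(C), each = C), drop = FALSE] *
    EB[, rep(seq_len(C), times = C), drop = FALSE]
  ad_node(o, list(a, b), function(g) {
    dEA <- matrix(0, r * r, C)
    dEB <- matrix(0, r * r, C)
    for (u in seq_len(C)) {
      dEA[, u] <- rowSums(g[, (u - 1L) * C + seq_len(C), drop = FALSE] * EB)
    }
    for (v in seq_len(C)) {
      dEB[, v] <- rowSums(g[, seq(v, C * C, by = C), drop = FALSE] * EA)
    }
    da <- rowsum(dEA, i_of, reorder = TRUE)
    db <- rowsum(dEB, j_of, reorder = TRUE)
    list(da, db)
  })
}

# triangle edge mixing over the shared node k; a, b are r^2 x c edge tensors
# (row p = (i-1)*r + j is edge i -> j)
#   outgoing: u_ij = sum_k a_ik * b_jk   (per channel: U = A B^T)
#   incoming: u_ij = sum_k a_ki * b_kj   (per channel: U = A^T B)
ad_triangle_mix <- function(a, b, r, direction = c("outgoing", "incoming")) {
  direction <- match.arg(direction)
  a <- as_node(a); b <- as_node(b)
  cch <- ncol(a$value)
  as_sq <- function(v) matrix(v, r, r, byrow = TRUE)
  u <- matrix(0, r * r, cch)
  for (ch in seq_len(cch)) {
    A <- as_sq(a$value[, ch]); B <- as_sq(b$value[, ch])
    U <- if (direction == "outgoing") A %*% t(B) else t(A) %*% B
    u[, ch] <- as.numeric(t(U))  # back to row-major (i-1)*r + j
  }
  ad_node(u, list(a, b), function(g) {
    da <- matrix(0, r * r, cch)
    db <- matrix(0, r * r, cch)
    for (ch in seq_len(cch)) {
      A <- as_sq(a$value[, ch]); B <- as_sq(b$value[, ch])
      G <- as_sq(g[, ch])
      if (direction == "outgoing") {
        dA <- G %*% B
        dB <- t(G) %*% A
      } else {
        dA <- B %*% t(G)
        dB <- A %*% G
      }
      da[, ch] <- as.numeric(t(dA))
      db[, ch] <- as.numeric(t(dB))
    }
    list(da, db)
  })
}

# equivariant weighted field: given scalar weights W (r x r, as a node) and
# constant unit-difference directions D (r x r x 3 array),
# out[i, ] = sum_j W[i, j] * D[i, j, ]
ad_weighted_field <- function(W, D) {
  W <- as_node(W)
  r <- nrow(W$value)
  out <- matrix(0, r, 3L)
  for (axis in 1:3) out[, axis] <- rowSums(W$value * D[, , axis])
  ad_node(out, list(W), function(g) {
    dW <- matrix(0, r, r)
    for (axis in 1:3) dW <- dW + g[, axis] * D[, , axis]
    list(dW)
  })
}

ad_transpose <- function(a) {
  a <- as_node(a)
  ad_node(t(a$value), list(a), function(g) list(t(g)))
}

# reshape an r^2 x 1 row-major edge vector into an r x r matrix
ad_reshape_sq <- function(a, r) {
  a <- as_node(a)
  ad_node(matrix(as.numeric(a$value), r, r, byrow = TRUE), list(a), function(g) {
    list(matrix(as.numeric(t(g)), r * r, 1L))
  })
}

# collect gradients for a named list of parameter nodes
ad_grads <- function(param_nodes) {
  lapply(param_nodes, function(n) {
    if (is.null(n$grad)) {
      if (is.matrix(n$value)) matrix(0, nrow(n$value), ncol(n$value)) else numeric(length(n$value))
    } else {
      n$grad
    }
  })
}
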