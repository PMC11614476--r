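# The composite training objective L = L_WS + L_KL + L_CE and a seeded
# desk-scale training step (Adam on the full parameter set, gradients from
# the package's reverse-mode tape).

#' Loss breakdown
#'
#' @param l_ws,l_kl,l_ce the three loss components.
#' @return object of class \code{loss_breakdown} with \code{total} equal to
#'   their exact sum.
#' @export
loss_breakdown <- function(l_ws, l_kl, l_ce) {
  parts <- c(l_ws = l_ws, l_kl = l_kl, l_ce = l_ce)
  if (any(!is.finite(parts))) {
    stop("non-finite loss component: ",
         paste(names(parts)[!is.finite(parts)], collapse = ", "))
  }
  structure(
    list(l_ws = l_ws, l_kl = l_kl, l_ce = l_ce, total = l_ws + l_kl + l_ce),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss total %.5f  (ws %.5f  kl %.5f  ce %.5f)\n",
              x$total, x$l_ws, x$l_kl, x$l_ce))
  invisible(x)
}

#' Noise-prediction loss (Euclidean norm of the residual)
#'
#' Per-sample Euclidean norm \eqn{\|\epsilon - \hat\epsilon\|} over all
#' token coordinates; the Monte-Carlo estimate of the diffusion-time sum
#' (one uniformly drawn time per sample per step). Rotation of both
#' arguments together leaves the value unchanged.
#'
#' @param eps true noise, tokens x 3.
#' @param eps_hat predicted noise, same shape.
#' @return non-negative scalar.
#' @export
ws_loss <- function(eps, eps_hat) {
  eps <- as.matrix(eps); eps_hat <- as.matrix(eps_hat)
  if (!all(dim(eps) == dim(eps_hat))) stop("shape mismatch between eps and eps_hat")
  sqrt(sum((eps - eps_hat)^2))
}

#' Sequence diffusion state
#'
#' Rows on the probability simplex (one per residue) together with the
#' diffusion time they refer to.
#'
#' @param probs residues x 20 matrix of non-negative rows summing to 1.
#' @param t diffusion time in [0, 1].
#' @return object of class \code{seq_diffusion_state}.
#' @export
seq_diffusion_state <- function(probs, t) {
  probs <- as.matrix(probs)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) stop("rows must sum to 1")
  structure(list(probs = probs, t = t), class = "seq_diffusion_state")
}

#' Schedule-weighted sequence KL loss
#'
#' Mean over residues of \eqn{KL(\mathrm{target}_i \| \mathrm{pred}_i)},
#' scaled by the discrete-diffusion step weight
#' \eqn{\beta(t) = 1 - \alpha(t)^2/\alpha(t - \Delta)^2} on the shared grid
#' (\eqn{\Delta = 1/T}). Zero iff the two distributions agree row-wise.
#' Predicted probabilities are floored at 1e-8 before the log.
#'
#' @param pred,target [seq_diffusion_state()] objects with equal shapes.
#' @param sched optional [make_schedule()]; when NULL the weight is 1.
#' @return non-negative scalar.
#' @export
kl_sequence_loss <- function(pred, target, sched = NULL) {
  stopifnot(inherits(pred, "seq_diffusion_state"),
            inherits(target, "seq_diffusion_state"))
  p <- target$probs
  q <- pmax(pred$probs, 1e-8)
  if (!all(dim(p) == dim(q))) stop("shape mismatch between pred and target")
  terms <- ifelse(p > 0, p * (log(p) - log(q)), 0)
  kl <- mean(rowSums(terms))
  beta <- 1
  if (!is.null(sched)) {
    t <- pred$t
    s <- max(t - 1 / sched$T, 0)
    beta <- 1 - sched$alpha(t)^2 / sched$alpha(s)^2
  }
  beta * kl
}

#' Masked-position cross-entropy loss
#'
#' Mean categorical cross-entropy of the predicted amino-acid logits against
#' the true residues over the given positions (by default the positions that
#' were masked). An empty position set yields 0 with a warning.
#'
#' @param logits n_res x 20 matrix.
#' @param truth the true (unmasked) sequence.
#' @param positions integer positions to score.
#' @return non-negative scalar.
#' @export
ce_loss <- function(logits, truth, positions) {
  truth <- aa_seq(truth)
  if (length(positions) == 0L) {
    warning("empty position set in cross-entropy loss; returning 0")
    return(0)
  }
  if (any(positions < 1L | positions > length(truth))) {
    stop("positions outside the residue range")
  }
  cls <- match(unclass(truth)[positions], AA_CANONICAL)
  if (any(is.na(cls))) stop("cross-entropy target contains non-canonical residues")
  rows <- logits[positions, , drop = FALSE]
  m <- apply(rows, 1L, max)
  lse <- m + log(rowSums(exp(rows - m)))
  mean(lse - rows[cbind(seq_along(cls), cls)])
}

# mixed sequence distribution of the forward process at signal level lam:
# lam * onehot + (1 - lam) * uniform
seq_forward_probs <- function(sequence, lam) {
  sequence <- aa_seq(sequence)
  cls <- match(unclass(sequence), AA_CANONICAL)
  oh <- matrix(0, length(sequence), 20L)
  ok <- !is.na(cls)
  oh[cbind(which(ok), cls[ok])] <- 1
  oh[!ok, ] <- 1 / 20  # non-canonical residues: uninformative row
  lam * oh + (1 - lam) / 20
}

# ---- Adam optimizer ------------------------------------------------------

adam_init <- function(params) {
  list(
    t = 0L,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
}

adam_update <- function(params, grads, state, lr = 1e-2,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# Build the three loss nodes for one complex at one drawn time step.
# Returns the AD nodes plus the parameter nodes (for gradient collection).
step_loss_nodes <- function(model, complex, sched, step_seed, grad = TRUE,
                            mask_ratio = NULL, fixed_t_index = NULL) {
  cfg <- model$cfg
  mask_ratio <- mask_ratio %||% cfg$mask_ratio
  draws <- with_seed(step_seed, {
    i <- if (is.null(fixed_t_index)) sample.int(sched$T, 1L) else fixed_t_index
    masked <- stochastic_mask(complex$sequence, mask_ratio)
    fwd_seed <- floor(stats::runif(1, 1, 2^30))
    list(i = i, masked = masked, fwd_seed = fwd_seed)
  })
  t <- draws$i / sched$T
  s <- (draws$i - 1L) / sched$T
  fs <- forward_sample(center(complex$coords), t, sched, seed = draws$fwd_seed)

  feat <- featurize_complex(draws$masked, complex$ligand, model$embedder, cfg)
  fw <- forward_pass(model, feat, fs$z, t, grad = grad)

  d <- ad_sub(ad_const(fs$eps), fw$eps_hat)
  l_ws <- ad_sqrt(ad_sum(ad_mul(d, d)))

  mpos <- masked_positions(draws$masked)
  if (length(mpos) > 0L) {
    rows <- ad_gather_rows(fw$logits, mpos)
    sm <- ad_rowsoftmax(rows)
    cls <- match(unclass(aa_seq(complex$sequence))[mpos], AA_CANONICAL)
    oh <- matrix(0, length(mpos), 20L)
    oh[cbind(seq_along(cls), cls)] <- 1
    l_ce <- ad_scale(ad_sum(ad_mul(ad_const(oh), ad_log(sm))), -1 / length(mpos))
  } else {
    l_ce <- ad_const(0)
  }

  lam <- sched$alpha(s)^2
  beta <- 1 - sched$alpha(t)^2 / sched$alpha(s)^2
  target <- seq_forward_probs(complex$sequence, lam)
  sm_all <- ad_rowsoftmax(fw$logits)
  pred <- ad_add(ad_scale(sm_all, lam), ad_const(matrix((1 - lam) / 20,
                                                        feat$n_res, 20L)))
  n <- feat$n_res
  l_kl <- ad_scale(
    ad_sub(ad_const(sum(target * log(target))),
           ad_sum(ad_mul(ad_const(target), ad_log(pred)))),
    beta / n
  )

  total <- ad_add(ad_add(l_ws, l_kl), l_ce)
  list(
    total = total, l_ws = l_ws, l_kl = l_kl, l_ce = l_ce,
    param_nodes = fw$param_nodes, t_index = draws$i,
    masked = draws$masked
  )
}

#' One training step
#'
#' Draws a diffusion time uniformly from the grid, re-draws the stochastic
#' sequence mask, forward-samples the coordinates, runs the trunk and
#' denoiser, computes the three losses and applies one Adam update on every
#' parameter. Fully reproducible from the seed.
#'
#' @param model a [new_model()].
#' @param batch list of toy complexes (see [generate_toy_complex()]).
#' @param opt_state Adam state from a previous call, or NULL to start.
#' @param seed integer seed for this step's draws.
#' @param lr learning rate.
#' @param sched optional schedule (defaults to the model configuration's).
#' @param mask_ratio optional override of the configured masking ratio.
#' @return list with updated \code{model}, \code{opt_state} and the batch-mean
#'   \code{losses} ([loss_breakdown()]).
#' @export
training_step <- function(model, batch, opt_state = NULL, seed = 1L,
                          lr = 1e-2, sched = NULL, mask_ratio = NULL) {
  sched <- sched %||% make_schedule(model$cfg$T, model$cfg$schedule)
  if (is.null(opt_state)) opt_state <- adam_init(model$params)
  acc <- NULL
  parts <- c(l_ws = 0, l_kl = 0, l_ce = 0)
  for (b in seq_along(batch)) {
    ln <- step_loss_nodes(model, batch[[b]], sched,
                          step_seed = derive_seed(seed, b),
                          grad = TRUE, mask_ratio = mask_ratio)
    ad_backward(ln$total)
    g <- ad_grads(ln$param_nodes)
    acc <- if (is.null(acc)) g else Map(`+`, acc, g)
    parts <- parts + c(ln$l_ws$value, ln$l_kl$value, ln$l_ce$value)
  }
  nb <- length(batch)
  acc <- lapply(acc, function(x) x / nb)
  upd <- adam_update(model$params, acc, opt_state, lr = lr)
  model$params <- upd$params
  parts <- unname(parts)
  losses <- loss_breakdown(parts[1] / nb, parts[2] / nb, parts[3] / nb)
  list(model = model, opt_state = upd$state, losses = losses)
}

#' Desk-scale training loop
#'
#' Repeated [training_step()]s with per-step derived seeds; optionally logs
#' the per-step loss breakdown as CSV.
#'
#' @param model a [new_model()].
#' @param complexes list of toy complexes used as the (tiny) training set.
#' @param steps number of steps.
#' @param lr learning rate.
#' @param seed base seed; step k uses a derived child seed.
#' @param csv optional path for a per-step loss CSV
#'   (columns step, l_ws, l_kl, l_ce, total).
#' @param mask_ratio optional masking-ratio override.
#' @param verbose print progress every 50 steps.
#' @return list with trained \code{model}, final \code{opt_state} and
#'   \code{history} (data.frame of per-step losses).
#' @export
train_toy <- function(model, complexes, steps = 100L, lr = 1e-2, seed = 1L,
                      csv = NULL, mask_ratio = NULL, verbose = FALSE) {
  opt <- NULL
  hist <- data.frame(step = integer(0), l_ws = numeric(0), l_kl = numeric(0),
                     l_ce = numeric(0), total = numeric(0))
  for (k in seq_len(steps)) {
    out <- training_step(model, complexes, opt, seed = derive_seed(seed, k),
                         lr = lr, mask_ratio = mask_ratio)
    model <- out$model
    opt <- out$opt_state
    hist[k, ] <- list(k, out$losses$l_ws, out$losses$l_kl, out$losses$l_ce,
                      out$losses$total)
    if (verbose && k %% 50L == 0L) {
      message(sprintf("step %d: total %.4f", k, out$losses$total))
    }
  }
  if (!is.null(csv)) utils::write.csv(hist, csv, row.names = FALSE)
  list(model = model, opt_state = opt, history = hist)
}
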