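# Model configuration, parameter initialization, and the full differentiable
# forward pass: featurized inputs -> trunk -> equivariant denoiser.

#' Model configuration
#'
#' Dimensions and knobs of the noise-prediction model. The attention head
#' width \code{c_head = 65}, head count \code{n_head = 4} and outer-product
#' width \code{c_opu = 32} are the architecture's stated defaults; the
#' remaining sizes are desk-scale choices and everything is configurable.
#'
#' @param c_m single-representation channels.
#' @param c_z pair-representation channels.
#' @param n_blocks trunk blocks (each: attention, outer-product update,
#'   outgoing + incoming triangle updates, all residual).
#' @param c_head per-head attention dimension C.
#' @param n_head attention heads.
#' @param c_opu outer-product projection width.
#' @param tri_hidden triangle-update hidden width (default \code{c_z}).
#' @param w_hidden hidden width of the pair-to-weight MLP.
#' @param embed_dim residue-embedder output dimension.
#' @param n_rbf,rbf_max radial-basis bank: \code{n_rbf} Gaussian centers
#'   evenly spaced on [0, \code{rbf_max}] angstrom, width = spacing.
#' @param r_max relative-position clip (offsets clamped to +/- r_max).
#' @param time_dim sinusoidal time-embedding frequency pairs (output has
#'   \code{2 * time_dim} channels).
#' @param T diffusion step count.
#' @param schedule schedule kind, see [make_schedule()].
#' @param mask_ratio default sequence masking ratio upper bound.
#' @param delta denominator regularizer of the equivariant field (angstrom).
#' @return a \code{model_config} list.
#' @export
model_config <- function(c_m = 64L, c_z = 32L, n_blocks = 4L,
                         c_head = 65L, n_head = 4L, c_opu = 32L,
                         tri_hidden = NULL, w_hidden = 16L,
                         embed_dim = 16L, n_rbf = 16L, rbf_max = 20,
                         r_max = 32L, time_dim = 8L,
                         T = 64L, schedule = "cosine", mask_ratio = 0.15,
                         delta = 1e-6) {
  cfg <- list(
    c_m = as.integer(c_m), c_z = as.integer(c_z),
    n_blocks = as.integer(n_blocks), c_head = as.integer(c_head),
    n_head = as.integer(n_head), c_opu = as.integer(c_opu),
    tri_hidden = as.integer(tri_hidden %||% c_z), w_hidden = as.integer(w_hidden),
    embed_dim = as.integer(embed_dim), n_rbf = as.integer(n_rbf),
    rbf_max = rbf_max, r_max = as.integer(r_max), time_dim = as.integer(time_dim),
    T = as.integer(T), schedule = schedule, mask_ratio = mask_ratio,
    delta = delta
  )
  stopifnot(all(vapply(
    cfg[c("c_m", "c_z", "n_blocks", "c_head", "n_head", "c_opu",
          "tri_hidden", "w_hidden", "embed_dim", "n_rbf", "r_max",
          "time_dim", "T")],
    function(x) x >= 0, logical(1)
  )))
  class(cfg) <- "model_config"
  cfg
}

#' A small desk-scale configuration
#'
#' Convenience configuration used by the toy-training examples and tests:
#' two trunk blocks and narrow channels, so a full training step runs in
#' tens of milliseconds on one CPU.
#' @param ... overrides passed on to [model_config()].
#' @return a \code{model_config}.
#' @export
small_config <- function(...) {
  model_config(
    c_m = 24L, c_z = 12L, n_blocks = 2L, c_head = 8L, n_head = 2L,
    c_opu = 6L, w_hidden = 16L, embed_dim = 12L, ...
  )
}

xavier <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

ligand_field_levels <- function() {
  v <- ligand_vocab()
  list(
    atom = v[c("atomic_number", "chirality", "degree", "formal_charge",
               "attached_hydrogens", "radical_electrons", "hybridization",
               "is_aromatic", "in_ring")],
    bond = v[c("bond_type", "bond_stereo", "is_conjugated")]
  )
}

#' Initialize model parameters
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the random initialization.
#' @return named flat list of parameter arrays.
#' @export
init_params <- function(cfg, seed = 0L) {
  lv <- ligand_field_levels()
  with_seed(seed, {
    p <- list()
    # featurization
    p[["feat.tok_embed"]] <- xavier(22L, cfg$c_m)
    p[["feat.esm_W"]] <- xavier(cfg$embed_dim, cfg$c_m)
    p[["feat.esm_b"]] <- matrix(0, 1L, cfg$c_m)
    for (f in names(lv$atom)) {
      p[[paste0("feat.atom.", f)]] <- xavier(length(lv$atom[[f]]), cfg$c_m)
    }
    for (f in names(lv$bond)) {
      p[[paste0("feat.bond.", f)]] <- xavier(length(lv$bond[[f]]), cfg$c_z)
    }
    p[["feat.relpos_W"]] <- xavier(2L * cfg$r_max + 2L, cfg$c_z)
    p[["feat.rbf_W"]] <- xavier(cfg$n_rbf, cfg$c_z)
    p[["feat.time_W"]] <- xavier(2L * cfg$time_dim, cfg$c_z)
    # trunk blocks
    for (b in seq_len(cfg$n_blocks)) {
      pre <- sprintf("blk%d.", b)
      hc <- cfg$n_head * cfg$c_head
      p[[paste0(pre, "sra.ln_m.g")]] <- rep(1, cfg$c_m)
      p[[paste0(pre, "sra.ln_m.b")]] <- rep(0, cfg$c_m)
      p[[paste0(pre, "sra.q")]] <- xavier(cfg$c_m, hc)
      p[[paste0(pre, "sra.k")]] <- xavier(cfg$c_m, hc)
      p[[paste0(pre, "sra.v")]] <- xavier(cfg$c_m, hc)
      p[[paste0(pre, "sra.ln_z.g")]] <- rep(1, cfg$c_z)
      p[[paste0(pre, "sra.ln_z.b")]] <- rep(0, cfg$c_z)
      p[[paste0(pre, "sra.bias")]] <- xavier(cfg$c_z, cfg$n_head)
      p[[paste0(pre, "sra.gate_W")]] <- xavier(cfg$c_m, hc)
      p[[paste0(pre, "sra.gate_b")]] <- rep(0, hc)
      p[[paste0(pre, "sra.out_W")]] <- xavier(hc, cfg$c_m)
      p[[paste0(pre, "sra.out_b")]] <- rep(0, cfg$c_m)
      p[[paste0(pre, "opu.ln.g")]] <- rep(1, cfg$c_m)
      p[[paste0(pre, "opu.ln.b")]] <- rep(0, cfg$c_m)
      p[[paste0(pre, "opu.a_W")]] <- xavier(cfg$c_m, cfg$c_opu)
      p[[paste0(pre, "opu.a_b")]] <- rep(0, cfg$c_opu)
      p[[paste0(pre, "opu.b_W")]] <- xavier(cfg$c_m, cfg$c_opu)
      p[[paste0(pre, "opu.b_b")]] <- rep(0, cfg$c_opu)
      p[[paste0(pre, "opu.out_W")]] <- xavier(cfg$c_opu^2, cfg$c_z)
      p[[paste0(pre, "opu.out_b")]] <- rep(0, cfg$c_z)
      for (dir in c("tri_out", "tri_in")) {
        pd <- paste0(pre, dir, ".")
        ch <- cfg$tri_hidden
        p[[paste0(pd, "ln.g")]] <- rep(1, cfg$c_z)
        p[[paste0(pd, "ln.b")]] <- rep(0, cfg$c_z)
        p[[paste0(pd, "a_p")]] <- xavier(cfg$c_z, ch)
        p[[paste0(pd, "a_pb")]] <- rep(0, ch)
        p[[paste0(pd, "a_g")]] <- xavier(cfg$c_z, ch)
        p[[paste0(pd, "a_gb")]] <- rep(0, ch)
        p[[paste0(pd, "b_p")]] <- xavier(cfg$c_z, ch)
        p[[paste0(pd, "b_pb")]] <- rep(0, ch)
        p[[paste0(pd, "b_g")]] <- xavier(cfg$c_z, ch)
        p[[paste0(pd, "b_gb")]] <- rep(0, ch)
        p[[paste0(pd, "ln_u.g")]] <- rep(1, ch)
        p[[paste0(pd, "ln_u.b")]] <- rep(0, ch)
        p[[paste0(pd, "out_W")]] <- xavier(ch, cfg$c_z)
        p[[paste0(pd, "out_b")]] <- rep(0, cfg$c_z)
        p[[paste0(pd, "out_g")]] <- xavier(cfg$c_z, cfg$c_z)
        p[[paste0(pd, "out_gb")]] <- rep(0, cfg$c_z)
      }
    }
    # denoiser: pair -> scalar weight MLP, and the sequence head
    p[["den.w1"]] <- xavier(cfg$c_z, cfg$w_hidden)
    p[["den.b1"]] <- rep(0, cfg$w_hidden)
    p[["den.w2"]] <- xavier(cfg$w_hidden, 1L)
    p[["den.b2"]] <- rep(0, 1L)
    p[["head.W"]] <- xavier(cfg$c_m, 20L)
    p[["head.b"]] <- rep(0, 20L)
    p
  })
}

#' Construct a model
#'
#' Bundles a configuration, an initialized parameter set and a residue
#' embedder into one object used by featurization, training and sampling.
#'
#' @param cfg a [model_config()].
#' @param seed initialization seed.
#' @param embedder residue embedder closure; default [stub_embedder()] of the
#'   configured dimension.
#' @return object of class \code{pl_model}.
#' @export
new_model <- function(cfg = model_config(), seed = 0L, embedder = NULL) {
  structure(
    list(
      cfg = cfg,
      params = init_params(cfg, seed),
      embedder = embedder %||% stub_embedder(cfg$embed_dim, seed)
    ),
    class = "pl_model"
  )
}

#' @export
print.pl_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<pl_model: %d blocks, c_m=%d c_z=%d, %d parameters>\n",
    x$cfg$n_blocks, x$cfg$c_m, x$cfg$c_z, n_par
  ))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing list (format tag, configuration,
#' parameter arrays keyed by module path, embedder seed) serialized with
#' \code{saveRDS}.
#'
#' @param model a \code{pl_model}.
#' @param path checkpoint file.
#' @return \code{path} invisibly (save); the restored model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(
    format = "pldiffuser-checkpoint-v1",
    cfg = unclass(model$cfg),
    params = model$params,
    embedder_dim = attr(model$embedder, "embed_dim"),
    embedder_seed = attr(model$embedder, "embed_seed")
  ), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "pldiffuser-checkpoint-v1")) {
    stop("not a recognized checkpoint file: ", path)
  }
  cfg <- do.call(model_config, ck$cfg[setdiff(names(ck$cfg), character(0))])
  m <- new_model(cfg, seed = 0L,
                 embedder = stub_embedder(ck$embedder_dim %||% cfg$embed_dim,
                                          ck$embedder_seed %||% 0L))
  m$params <- ck$params
  m
}
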