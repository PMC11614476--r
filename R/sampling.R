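# Ancestral sampling: from the centered standard-Gaussian prior at t = 1
# down the grid s(i) = (i-1)/T, t(i) = i/T, re-running featurization (the
# RBF distance features follow the current latent) and the trunk + denoiser
# at every step, then decoding coordinates and masked residues.

#' Generate a redesigned complex by ancestral sampling
#'
#' Draws \eqn{z_1} from the zero-centered standard Gaussian prior, runs the
#' reverse diffusion over \code{T} grid steps (the noise-prediction model is
#' re-run at every step on the current latent), and decodes the final latent
#' as \eqn{x = z_0/\alpha_0} (the decoder mean; no final noise injection).
#' Masked residues are decoded from the last step's amino-acid logits, by
#' argmax or by sampling. Masked tokens stay masked in featurization
#' throughout the loop.
#'
#' @param model a [new_model()] (weights random or loaded from checkpoint).
#' @param sequence input sequence; positions already carrying MASK are kept,
#'   otherwise [stochastic_mask()] is applied with \code{mask_ratio}.
#' @param ligand a [featurize_ligand()] graph or a SMILES string
#'   (\code{"*"} = unspecified ligand).
#' @param T grid steps (default from the model configuration).
#' @param seed integer seed controlling every draw (mask, prior, step noise,
#'   sequence sampling).
#' @param mask_ratio masking-ratio upper bound applied when \code{sequence}
#'   has no MASK tokens yet.
#' @param sample_sequence sample residues from the softmax instead of argmax.
#' @param noise_fn optional override \code{function(z, t) -> eps_hat} used in
#'   place of the model's denoiser (e.g. an oracle in tests); the sequence
#'   is then returned as masked.
#' @return list with \code{coords} (tokens x 3, centered), \code{sequence}
#'   (designed \code{aa_seq}), \code{masked_seq}, \code{logits} (from the
#'   final step, or NULL under \code{noise_fn}).
#' @export
sample_complex <- function(model, sequence, ligand = "*", T = NULL,
                           seed = 1L, mask_ratio = NULL,
                           sample_sequence = FALSE, noise_fn = NULL) {
  cfg <- model$cfg
  T <- as.integer(T %||% cfg$T)
  sched <- make_schedule(T, cfg$schedule)
  if (is.character(ligand)) ligand <- featurize_ligand(ligand)
  sequence <- aa_seq(sequence)
  masked <- if (length(masked_positions(sequence)) > 0L) {
    sequence
  } else {
    stochastic_mask(sequence, mask_ratio %||% cfg$mask_ratio,
                    seed = derive_seed(seed, 1L))
  }
  r <- length(masked) + n_ligand_atoms(ligand)
  z <- with_seed(derive_seed(seed, 2L), centered_noise(r))
  logits <- NULL
  for (i in T:1) {
    t <- i / T
    s <- (i - 1L) / T
    if (is.null(noise_fn)) {
      pred <- predict_complex_noise(model, masked, ligand, z, t)
      eps_hat <- pred$eps_hat
      logits <- pred$logits
    } else {
      eps_hat <- noise_fn(z, t)
    }
    if (any(!is.finite(eps_hat))) stop("non-finite noise prediction at step ", i)
    st <- reverse_step(z, eps_hat, s, t, sched,
                       seed = derive_seed(seed, 100L + i))
    z <- st$z
    if (any(!is.finite(z))) stop("non-finite latent at step ", i)
  }
  coords <- z / sched$alpha(0)
  designed <- masked
  if (!is.null(logits)) {
    mpos <- masked_positions(masked)
    if (length(mpos) > 0L) {
      rows <- logits[mpos, , drop = FALSE]
      pick <- if (sample_sequence) {
        with_seed(derive_seed(seed, 3L), {
          apply(rows, 1L, function(l) {
            p <- exp(l - max(l)); sample.int(20L, 1L, prob = p / sum(p))
          })
        })
      } else {
        apply(rows, 1L, which.max)
      }
      designed[mpos] <- AA_CANONICAL[pick]
    }
  }
  list(
    coords = center(coords), sequence = designed, masked_seq = masked,
    logits = logits
  )
}
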