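# Synthetic toy protein-ligand complexes: deterministic generators that make
# every other module testable without any download. A toy complex is a
# random sequence, a chain-like self-avoiding C-alpha trace (step ~3.8 A),
# and ligand heavy atoms placed in a shell near a surface residue.

#' Generate a synthetic toy protein-ligand complex
#'
#' The C-alpha trace is a self-avoiding random walk with step length 3.8 A
#' perturbed by +/- 0.3 A (consecutive distances stay within the chain-like
#' band 3.0-4.5 A); non-consecutive residues are kept at least 2.5 A apart by
#' rejection sampling. Ligand heavy atoms (one point each) are placed within
#' a 4 A shell around a randomly chosen surface residue, with the same 2.5 A
#' clash rule. Coordinates are centered. Fully reproducible from the seed.
#'
#' @param n_res number of residues (4 to 200).
#' @param ligand_smiles SMILES string or \code{"*"} for a masked ligand.
#' @param seed integer seed.
#' @param max_tries rejection-sampling retry cap per placed point.
#' @return object of class \code{toy_complex}: list with \code{sequence}
#'   (aa_seq), \code{ligand} (ligand_graph), \code{coords} (tokens x 3,
#'   residues first, zero centroid), \code{n_res}, \code{seed}.
#' @export
generate_toy_complex <- function(n_res, ligand_smiles = "*", seed = 1L,
                                 max_tries = 200L) {
  if (n_res < 4 || n_res > 200) stop("n_res must lie in [4, 200]")
  ligand <- featurize_ligand(ligand_smiles)
  n_lig <- n_ligand_atoms(ligand)
  out <- with_seed(seed, {
    sequence <- aa_seq(sample(AA_CANONICAL, n_res, replace = TRUE))
    coords <- matrix(0, n_res + n_lig, 3L)
    for (i in 2:n_res) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        step <- stats::rnorm(3)
        step <- step / sqrt(sum(step^2)) * (3.8 + stats::runif(1, -0.3, 0.3))
        cand <- coords[i - 1L, ] + step
        prev <- coords[seq_len(max(1L, i - 2L)), , drop = FALSE]
        if (i == 2L || min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= 2.5) {
          coords[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("chain placement failed after ", max_tries, " tries")
    }
    if (n_lig > 0) {
      # surface residue = maximal distance from the chain centroid
      centroid <- colMeans(coords[seq_len(n_res), , drop = FALSE])
      dists <- sqrt(rowSums(sweep(coords[seq_len(n_res), , drop = FALSE], 2L, centroid)^2))
      anchor <- coords[sample(which(dists >= stats::quantile(dists, 0.75)), 1L), ]
      for (k in seq_len(n_lig)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          cand <- anchor + dir * stats::runif(1, 2.5, 4.0)
          if (k > 1L) {
            # chain ligand atoms loosely off the previous one
            cand <- coords[n_res + k - 1L, ] + dir * stats::runif(1, 1.3, 1.6)
          }
          others <- coords[seq_len(n_res + k - 1L), , drop = FALSE]
          if (min(sqrt(rowSums(sweep(others, 2L, cand)^2))) >= if (k > 1L) 1.2 else 2.5) {
            coords[n_res + k, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("ligand placement failed after ", max_tries, " tries")
      }
    }
    list(sequence = sequence, coords = center(coords))
  })
  structure(
    list(
      sequence = out$sequence, ligand = ligand, coords = out$coords,
      ligand_smiles = ligand_smiles, n_res = as.integer(n_res),
      seed = as.integer(seed)
    ),
    class = "toy_complex"
  )
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf(
    "<toy_complex: %d residues + %d ligand atoms ('%s'), seed %d>\n",
    x$n_res, n_ligand_atoms(x$ligand), x$ligand_smiles, x$seed
  ))
  invisible(x)
}

n_tokens <- function(complex) complex$n_res + n_ligand_atoms(complex$ligand)

#' Write a suite of toy fixtures to disk
#'
#' Writes \code{n} toy complexes as paired PDB and FASTA files plus one
#' SMILES list and a JSON manifest recording seeds, sizes and MD5 checksums,
#' so a suite can be regenerated and verified byte-for-byte.
#'
#' @param out_dir writable directory (created if missing).
#' @param n number of complexes.
#' @param seed base seed; complex k uses a derived child seed.
#' @param n_res residues per complex (recycled).
#' @param ligands SMILES menu cycled over the complexes.
#' @return the manifest, invisibly (also written as \code{manifest.json}).
#' @export
make_fixture_suite <- function(out_dir, n, seed = 1L,
                               n_res = 16L,
                               ligands = c("CCO", "c1ccccc1", "CC(=O)O", "*")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_res <- rep_len(n_res, n)
  smiles_list <- rep_len(ligands, n)
  entries <- vector("list", n)
  for (k in seq_len(n)) {
    child <- derive_seed(seed, k)
    cx <- generate_toy_complex(n_res[k], smiles_list[k], seed = child)
    pdb <- file.path(out_dir, sprintf("complex_%03d.pdb", k))
    fa <- file.path(out_dir, sprintf("complex_%03d.fasta", k))
    write_pdb(cx, pdb)
    write_fasta(cx$sequence, fa, name = sprintf("complex_%03d", k))
    entries[[k]] <- list(
      id = sprintf("complex_%03d", k), seed = child, n_res = n_res[k],
      smiles = smiles_list[k],
      md5_pdb = unname(tools::md5sum(pdb)), md5_fasta = unname(tools::md5sum(fa))
    )
  }
  writeLines(smiles_list, file.path(out_dir, "ligands.smi"))
  manifest <- list(base_seed = seed, n = n, complexes = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
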