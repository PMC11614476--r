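model <- small_model()

test_that("token ordering is residues first, then ligand atoms", {
  lig <- featurize_ligand("CCO")
  s <- build_single_representation(aa_seq("ACDEF"), lig, model = model)
  expect_equal(nrow(s), 8L)
  expect_equal(attr(s, "token_kinds"),
               c(rep("residue", 5), rep("ligand_atom", 3)))
})

test_that("degenerate weights reduce every row to the MASK embedding", {
  cfg <- tiny_cfg()
  m <- new_model(cfg, seed = 2, embedder = zero_embedder(cfg$embed_dim))
  seq_all_mask <- aa_seq(rep("-", 6))
  s <- build_single_representation(seq_all_mask, featurize_ligand("*"), model = m)
  mask_row <- m$params[["feat.tok_embed"]][match("-", aa_alphabet()), ]
  for (i in 1:6) expect_equal(unname(s[i, ]), unname(mask_row))
})

test_that("featurization is deterministic", {
  lig <- featurize_ligand("CCO")
  s1 <- build_single_representation(aa_seq("ACDEF"), lig, model = model)
  s2 <- build_single_representation(aa_seq("ACDEF"), lig, model = model)
  expect_identical(unclass(s1), unclass(s2))
  z1 <- build_pair_representation(s1, NULL, 0.3, model)
  z2 <- build_pair_representation(s2, NULL, 0.3, model)
  expect_identical(unclass(z1), unclass(z2))
})

test_that("the time embedding is exactly (0, 1) pairs at t = 0", {
  tf <- time_features(0, model$cfg)
  K <- model$cfg$time_dim
  expect_equal(tf[seq_len(K)], rep(0, K))
  expect_equal(tf[K + seq_len(K)], rep(1, K))
})

test_that("an RBF basis scores 1 at its own center and is rigid-motion invariant", {
  cfg <- model$cfg
  centers <- seq(0, cfg$rbf_max, length.out = cfg$n_rbf)
  coords <- rbind(c(0, 0, 0), c(centers[4], 0, 0))
  rbf <- rbf_features(coords, cfg)
  expect_equal(rbf[2, 4], 1)  # pair (1,2) at distance mu_4
  set.seed(1)
  x <- matrix(rnorm(15), 5, 3)
  R <- random_rotation()
  expect_equal(rbf_features(x, cfg),
               rbf_features(apply_rigid(x, R, c(3, -1, 2)), cfg),
               tolerance = 1e-9)
  # symmetry: RBF(i, j) = RBF(j, i)
  r <- 5
  f <- rbf_features(x, cfg)
  for (i in 1:r) for (j in 1:r) {
    expect_equal(f[(i - 1) * r + j, ], f[(j - 1) * r + i, ])
  }
})

test_that("relative-position offsets clip at r_max", {
  cfg <- model$cfg
  n <- 101L
  feat <- featurize_complex(aa_seq(rep("A", n)), featurize_ligand("*"),
                            model$embedder, cfg)
  # offset -100 and offset -r_max land in the same bin
  row_far <- feat$relpos[(1 - 1) * n + 101, ]
  row_clip <- feat$relpos[(1 - 1) * n + (1 + cfg$r_max), ]
  expect_equal(row_far, row_clip)
  # unclipped offsets use distinct bins
  row_near <- feat$relpos[(1 - 1) * n + 2, ]
  expect_false(isTRUE(all.equal(row_near, row_clip)))
})

test_that("ligand-involved pairs use the dedicated relative-position bin", {
  feat <- featurize_complex(aa_seq("ACD"), featurize_ligand("CCO"),
                            model$embedder, model$cfg)
  n_bins <- 2L * model$cfg$r_max + 2L
  r <- feat$r
  expect_equal(feat$relpos[(4 - 1) * r + 1, n_bins], 1)  # ligand-residue
  expect_equal(feat$relpos[(1 - 1) * r + 2, n_bins], 0)  # residue-residue
})

test_that("permuting ligand atoms permutes single rows and pair rows/columns consistently", {
  # two hand-built featurizations of the same 2-atom ligand, atom order swapped
  base <- featurize_ligand("CO")  # C-O single bond
  swapped <- base
  swapped$atoms <- base$atoms[c(2, 1), ]
  rownames(swapped$atoms) <- NULL
  swapped$bonds$atom_i <- 1L
  swapped$bonds$atom_j <- 2L  # same bond, endpoints relabeled
  seqq <- aa_seq("ACD")
  s1 <- build_single_representation(seqq, base, model = model)
  s2 <- build_single_representation(seqq, swapped, model = model)
  # ligand rows 4, 5 swap
  expect_equal(unclass(s1)[c(1, 2, 3, 5, 4), ], unclass(s2)[, ])
  z1 <- build_pair_representation(s1, NULL, 0.2, model)
  z2 <- build_pair_representation(s2, NULL, 0.2, model)
  r <- 5L
  perm <- c(1, 2, 3, 5, 4)
  idx <- function(i, j) (i - 1L) * r + j
  for (i in 1:r) for (j in 1:r) {
    expect_equal(unclass(z1)[idx(i, j), ], unclass(z2)[idx(perm[i], perm[j]), ])
  }
})

test_that("embedder contract violations are caught", {
  bad <- function(sequence) matrix(0, 2, model$cfg$embed_dim)
  expect_error(
    build_single_representation(aa_seq("ACDEF"), featurize_ligand("*"),
                                embedder = bad, model = model),
    "length mismatch"
  )
  expect_error(
    build_pair_representation(
      build_single_representation(aa_seq("ACD"), featurize_ligand("*"), model = model),
      coords = matrix(0, 7, 3), time = 0.1, model
    ),
    "mismatch"
  )
})

test_that("the stub embedder is deterministic and keyed by (token, position)", {
  e <- stub_embedder(8, seed = 4)
  a <- e(aa_seq("ACDEFG"))
  b <- e(aa_seq("ACDEFG"))
  expect_identical(a, b)
  # shared prefix -> identical rows on the prefix
  c2 <- e(aa_seq("ACDWWW"))
  expect_identical(a[1:3, ], c2[1:3, ])
  expect_false(isTRUE(all.equal(a[4, ], c2[4, ])))
  # declared Gaussian draw: squared norms average to the dimension
  big <- e(aa_seq(paste(sample(c("A","C","D","E","F","G","H","I"), 400,
                               replace = TRUE), collapse = "")))
  expect_equal(mean(rowSums(big^2)), 8, tolerance = 0.35)
})
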