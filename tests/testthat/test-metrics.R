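test_that("diversity is the mean pairwise Levenshtein distance", {
  expect_equal(diversity_score(list("AAA", "AAA")), 0)
  expect_equal(diversity_score(list("kitten", "sitting")), 3)
  expect_equal(dp_levenshtein("kitten", "sitting"), 3)
  expect_equal(diversity_score(list("AA", "AB", "BB")), 4 / 3)
  expect_error(diversity_score(list("AA")), "two sequences")
  # symmetric in argument order; cross-checked against the DP oracle
  set.seed(1)
  seqs <- replicate(5, paste(sample(c("A", "C", "D", "G"), 8, replace = TRUE),
                             collapse = ""))
  expect_equal(diversity_score(as.list(seqs)),
               diversity_score(as.list(rev(seqs))))
  dp_mean <- mean(combn(seqs, 2, function(p) dp_levenshtein(p[1], p[2])))
  expect_equal(diversity_score(as.list(seqs)), dp_mean)
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(2)
  p <- matrix(rnorm(30), 10, 3) * 5
  expect_equal(kabsch_rmsd(p, p)$rmsd, 0, tolerance = 1e-10)
  for (k in 1:10) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 8)
    fit <- kabsch_rmsd(p, apply_rigid(p, R, tr))
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
  # symmetry of the minimized distance
  q <- p + matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(p, q)$rmsd, kabsch_rmsd(q, p)$rmsd, tolerance = 1e-9)
  # degenerate all-identical points: identity rotation by convention
  z <- matrix(1, 4, 3)
  fit0 <- kabsch_rmsd(z, z)
  expect_equal(fit0$rotation, diag(3))
})

test_that("Kabsch matches a fine rotation-grid brute force on a perturbed toy", {
  p <- rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0), c(0, 3, 0))
  q <- p
  q[4, 1] <- q[4, 1] + 1  # displace one coordinate by 1 A
  got <- kabsch_rmsd(p, q)$rmsd
  # brute force: random-rotation search with local axis-angle refinement
  # (optimal translation applied in closed form at every candidate)
  rmsd_at <- function(R) {
    qr <- q %*% t(R)
    qr <- sweep(qr, 2, colMeans(qr) - colMeans(p))
    sqrt(mean(rowSums((p - qr)^2)))
  }
  axis_rot <- function(axis, angle) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  }
  set.seed(3)
  best_R <- diag(3); best <- rmsd_at(best_R)
  for (k in 1:1000) {
    R <- random_rotation()
    v <- rmsd_at(R)
    if (v < best) { best <- v; best_R <- R }
  }
  scale <- 0.5
  for (k in 1:600) {
    R <- axis_rot(rnorm(3), rnorm(1, sd = scale)) %*% best_R
    v <- rmsd_at(R)
    if (v < best) { best <- v; best_R <- R } else scale <- max(scale * 0.99, 1e-4)
  }
  expect_lte(got, best + 1e-9)
  expect_lt(abs(got - best), 1e-3)
})

test_that("Kabsch agrees with the bio3d reference superposition", {
  set.seed(4)
  p <- matrix(rnorm(24), 8, 3) * 4
  q <- p + matrix(rnorm(24), 8, 3) * 0.6
  got <- kabsch_rmsd(p, q)$rmsd
  xyz_p <- as.numeric(t(p))
  xyz_q <- as.numeric(t(q))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz_p, mobile = xyz_q))
  ref <- sqrt(mean(colSums(matrix((xyz_p - fitted)^2, 3))))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("TM-score is 1 for superposable structures and beats a grid oracle", {
  set.seed(5)
  p <- matrix(rnorm(60), 20, 3) * 4
  expect_equal(tm_score(p, p), 1, tolerance = 1e-9)
  R <- random_rotation()
  expect_equal(tm_score(p, apply_rigid(p, R, c(4, -2, 7))), 1, tolerance = 1e-6)
  # optimizer must not fall below a coarse rotation-grid brute force
  q <- p + matrix(rnorm(60), 20, 3) * 2
  got <- tm_score(p, q)
  d0 <- max(1.24 * (20 - 15)^(1 / 3) - 1.8, 0.5)
  best <- 0
  for (k in 1:2000) {
    R <- random_rotation()
    qr <- q %*% t(R)
    qr <- sweep(qr, 2, colMeans(qr) - colMeans(p))
    best <- max(best, mean(1 / (1 + rowSums((p - qr)^2) / d0^2)))
  }
  expect_gte(got, best - 1e-6)
  expect_gt(got, 0)
  expect_lte(got, 1)
})

test_that("TM-score does not decrease for the Kabsch-aligned copy and d0 floors at 0.5", {
  set.seed(6)
  p <- matrix(rnorm(30), 10, 3) * 3
  q <- p + matrix(rnorm(30), 10, 3)
  fit <- kabsch_rmsd(p, q)
  q_aligned <- sweep(q %*% t(fit$rotation), 2, fit$translation, `+`)
  expect_gte(tm_score(p, q_aligned) + 1e-12, tm_score(p, q) - 1e-9)
  # tiny N: the auto scale parameter uses its 0.5 A floor and stays valid
  small <- matrix(rnorm(12), 4, 3)
  expect_gt(tm_score(small, small + 0.1), 0)
})

test_that("contact overlap counts conserved contacts as a Jaccard index", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.5, 0, 0), c(10, 0, 0))
  expect_equal(contact_overlap(p, p, r_c = 2), 1)
  # hand case: C = {(1,2),(1,3),(2,3)} at r_c = 2; move atom 3 away so
  # C' = {(1,2)}: intersection 1, union 3
  q <- p
  q[3, 1] <- 8
  expect_equal(contact_overlap(p, q, r_c = 2), 1 / 3)
  # a two-contact vs one-contact construction giving exactly 1/2
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0))
  b <- rbind(c(0, 0, 0), c(1, 0, 0), c(9, 0, 0))
  expect_equal(contact_overlap(a, b, r_c = 1.5), 1 / 2)
  # disjoint contact sets
  d1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0))
  d2 <- rbind(c(0, 0, 0), c(4, 0, 0), c(5, 0, 0))
  expect_equal(contact_overlap(d1, d2, r_c = 1.5), 0)
  # both sets empty: vacuous agreement
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(contact_overlap(far, far + 5, r_c = 1), 1)
})

test_that("structural metrics are invariant under rigid motion of either argument", {
  set.seed(7)
  p <- matrix(rnorm(36), 12, 3) * 4
  q <- p + matrix(rnorm(36), 12, 3) * 0.8
  R <- random_rotation()
  tr <- c(3, -6, 1)
  expect_equal(kabsch_rmsd(p, apply_rigid(q, R, tr))$rmsd,
               kabsch_rmsd(p, q)$rmsd, tolerance = 1e-9)
  expect_equal(tm_score(p, apply_rigid(q, R, tr)), tm_score(p, q),
               tolerance = 1e-6)
  expect_equal(contact_overlap(p, apply_rigid(q, R, tr)),
               contact_overlap(p, q), tolerance = 1e-12)
})
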