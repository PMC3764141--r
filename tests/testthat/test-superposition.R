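test_that("a model matches itself completely; deletions shrink the match", {
  m <- fixture("hairpin", stem = 3, loop = "GAAA")
  corr <- match_residues(m, m)
  expect_equal(nrow(corr$pairs), nrow(m$nucleotides))
  expect_equal(corr$pairs$res_a, corr$pairs$res_b)

  m2 <- m
  drop <- m2$nucleotides$resid[c(4, 5)]
  m2$nucleotides <- m2$nucleotides[!m2$nucleotides$resid %in% drop, ]
  m2$atoms <- m2$atoms[!m2$atoms$resid %in% drop, ]
  corr2 <- match_residues(m, m2)
  expect_equal(nrow(corr2$pairs), nrow(m$nucleotides) - 2)
})

test_that("identical and rigidly moved copies superpose to zero RMSD", {
  m <- fixture("hairpin", stem = 3, loop = "GAAA")
  sp <- superpose_structures(m, m)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)

  set.seed(31)
  for (rep in 1:3) {
    tr <- ribomotifs:::.random_rigid()
    m2 <- transform_structure(m, tr$R, tr$t)
    sp <- superpose_structures(m, m2)
    expect_lt(sp$rmsd, 1e-6)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
    expect_equal(sp$rotation, tr$R, tolerance = 1e-6)
  }
})

test_that("the fitted rotation is always proper (determinant +1)", {
  set.seed(57)
  for (rep in 1:10) {
    P <- matrix(stats::rnorm(15), 5, 3)
    Q <- matrix(stats::rnorm(15), 5, 3)
    fit <- ribomotifs:::.kabsch(P, Q)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("closed-form fit beats 10,000 random rotations on random point sets", {
  rmsd_for <- function(P, Q, R) {
    # optimal translation for a fixed rotation aligns centroids
    Pr <- P %*% t(R)
    Pr <- sweep(Pr, 2, colMeans(Pr))
    Q0 <- sweep(Q, 2, colMeans(Q))
    sqrt(mean(rowSums((Pr - Q0)^2)))
  }
  rand_rot <- function() {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(
      1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
      2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
      2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
    ), 3, 3, byrow = TRUE)
  }
  set.seed(123)
  for (trial in 1:3) {
    P <- matrix(stats::rnorm(15), 5, 3)
    Q <- matrix(stats::rnorm(15), 5, 3)
    fit <- ribomotifs:::.kabsch(P, Q)
    best <- rmsd_for(P, Q, fit$rotation)
    mc <- min(vapply(seq_len(10000), function(i) rmsd_for(P, Q, rand_rot()),
      numeric(1)))
    expect_lte(best, mc + 1e-12)
  }
})

test_that("the closed-form fit agrees with an independent reference implementation", {
  skip_if_not_installed("bio3d")
  m <- fixture("hairpin", stem = 3, loop = "GAAA")
  set.seed(8)
  tr <- ribomotifs:::.random_rigid()
  m2 <- transform_structure(m, tr$R, tr$t)
  # perturb to make the fit non-trivial
  m2$atoms$x <- m2$atoms$x + stats::rnorm(nrow(m2$atoms), sd = 0.3)
  sp <- superpose_structures(m, m2, prune_cutoff = NULL)
  corr <- match_residues(m, m2)
  xyz1 <- c(); xyz2 <- c()
  for (k in seq_len(nrow(corr$pairs))) {
    for (at in corr$atoms[[k]]$a) {
      xyz1 <- c(xyz1, ribomotifs:::.residue_coord(m, corr$pairs$res_a[k], at))
    }
    for (at in corr$atoms[[k]]$b) {
      xyz2 <- c(xyz2, ribomotifs:::.residue_coord(m2, corr$pairs$res_b[k], at))
    }
  }
  ref <- suppressWarnings(bio3d::fit.xyz(fixed = xyz2, mobile = xyz1))
  ref_rmsd <- sqrt(mean(colSums(matrix((ref - xyz2)^2, nrow = 3))))
  expect_equal(sp$rmsd, ref_rmsd, tolerance = 1e-6)
})

test_that("pruning discards outlier residues and never raises the RMSD", {
  m <- fixture("hairpin", stem = 3, loop = "GAAA")
  m2 <- m
  # displace one residue far away
  sel <- m2$atoms$resid == "A:5"
  m2$atoms$x[sel] <- m2$atoms$x[sel] + 15
  sp_full <- superpose_structures(m, m2, prune_cutoff = NULL)
  sp_pruned <- superpose_structures(m, m2, prune_cutoff = 2)
  expect_equal(sp_pruned$pruned$res_a, "A:5")
  expect_lt(sp_pruned$rmsd, sp_full$rmsd)
  expect_lt(sp_pruned$rmsd, 1e-6)
})

test_that("RMSD is invariant under rigid pre-transforms of either input", {
  m <- fixture("hairpin", stem = 3, loop = "GAAA")
  m2 <- m
  set.seed(14)
  m2$atoms$x <- m2$atoms$x + stats::rnorm(nrow(m2$atoms), sd = 0.2)
  base_rmsd <- superpose_structures(m, m2, prune_cutoff = NULL)$rmsd
  tr <- ribomotifs:::.random_rigid()
  expect_equal(
    superpose_structures(transform_structure(m, tr$R, tr$t), m2,
      prune_cutoff = NULL)$rmsd,
    base_rmsd, tolerance = 1e-6
  )
  expect_equal(
    superpose_structures(m, transform_structure(m2, tr$R, tr$t),
      prune_cutoff = NULL)$rmsd,
    base_rmsd, tolerance = 1e-6
  )
})

test_that("fewer than three correspondences is an error", {
  m <- fixture("triple")
  corr <- match_residues(m, m)
  corr$pairs <- corr$pairs[1:2, ]
  corr$atoms <- corr$atoms[1:2]
  expect_error(superpose(corr, m, m), "at least 3")
})
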