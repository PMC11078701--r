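test_that("kabsch recovers exact rigid motions", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1.7), 4, 3, byrow = TRUE)
  sp <- kabsch_superpose(P, P)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)

  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(Rz), 2, c(5, 5, 5), "+")
  sp <- kabsch_superpose(P, Q)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  # recovered rotation inverts the applied one
  expect_equal(sp$rotation %*% Rz, diag(3), tolerance = 1e-8)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "3 points")
  sp <- kabsch_superpose(matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3,
                                byrow = TRUE),
                         matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3,
                                byrow = TRUE))
  expect_true(sp$degenerate)
})

test_that("kabsch equals the dense rotation-grid oracle on a 3-point case", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0.001), 3, 3, byrow = TRUE)
  Q <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3, byrow = TRUE)
  sp <- kabsch_superpose(P, Q)
  oracle <- oracle_min_rmsd(P, Q)
  expect_lte(sp$rmsd, oracle + 1e-6)
  expect_equal(sp$rmsd, oracle, tolerance = 1e-3)
})

test_that("kabsch rmsd is optimal over random rotations and rigid-invariant", {
  set.seed(42)
  P <- matrix(rnorm(15), 5, 3)
  Q <- P + matrix(rnorm(15, sd = 0.3), 5, 3)
  best <- kabsch_superpose(P, Q)$rmsd
  Qc <- sweep(Q, 2, colMeans(Q))
  Pc <- sweep(P, 2, colMeans(P))
  for (k in 1:1000) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    expect_gte(sqrt(mean(rowSums((Pc - Qc %*% t(R))^2))), best - 1e-9)
  }
  # invariance of the optimum under rigid motion of either set
  for (k in 1:5) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    Q2 <- sweep(Q %*% t(R), 2, rnorm(3, sd = 10), "+")
    expect_equal(kabsch_superpose(P, Q2)$rmsd, best, tolerance = 1e-6)
  }
})

test_that("kabsch agrees with an independent superposition library", {
  set.seed(7)
  P <- matrix(rnorm(30, sd = 4), 10, 3)
  noisy <- as.data.frame(P + matrix(rnorm(30, sd = 0.4), 10, 3))
  names(noisy) <- c("x", "y", "z")
  Q <- as.matrix(rigid_move(noisy, angle = 62, axis = c(1, 3, -1),
                            shift = c(7, 0, -5))[, c("x", "y", "z")])
  ours <- kabsch_superpose(P, Q)$rmsd
  fitted <- bio3d::fit.xyz(fixed = as.numeric(t(P)),
                           mobile = as.numeric(t(Q)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  ref <- bio3d::rmsd(as.numeric(t(P)), fitted)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("axis fitting finds direction, sign and helical rise", {
  line <- cbind(seq(0, 10), 0, 0)
  ax <- fit_axis(line)
  expect_equal(abs(ax$direction), c(1, 0, 0), tolerance = 1e-9)
  expect_gt(ax$direction[1], 0)        # N -> C sign
  expect_equal(ax$linearity, 1, tolerance = 1e-9)

  h <- build_ideal_chain(list(list(kind = "helix", length = 12,
                                   phi = -57, psi = -47)))
  ca <- as.matrix(h[h$elety == "CA", c("x", "y", "z")])
  ax <- fit_axis(ca)
  # rise per residue of an ideal alpha-helix is about 1.5 A
  proj <- (ca %*% ax$direction)
  rise <- mean(diff(as.numeric(proj)))
  expect_equal(rise, 1.5, tolerance = 0.1)
  # direction invariant (up to sign handled by N->C) under global rotation
  h2 <- rigid_move(h)
  ax2 <- fit_axis(as.matrix(h2[h2$elety == "CA", c("x", "y", "z")]))
  expect_equal(abs(sum(ax$direction * ax$direction)), 1, tolerance = 1e-9)
  expect_equal(ax2$linearity, ax$linearity, tolerance = 1e-9)

  expect_error(fit_axis(line[1:3, ]), "4 points")
})

test_that("angles fold correctly between directed and undirected", {
  a <- fit_axis(cbind(0:4, 0, 0))
  b <- fit_axis(cbind(4:0, 0, 0))   # opposite direction
  expect_equal(angle_between(a, a, directed = TRUE), 0)
  expect_equal(angle_between(a, b, directed = TRUE), 180)
  expect_equal(angle_between(a, b, directed = FALSE), 0)
})

test_that("structure_align aligns a chain to itself and to a moved copy", {
  atoms <- fx_monomer()$atoms
  n_res <- sum(atoms$elety == "CA")
  sp <- structure_align(atoms, atoms)
  expect_equal(sp$rmsd, 0, tolerance = 1e-6)
  expect_equal(sp$n_aligned, n_res)

  # rigidly moved copy with 5 residues deleted
  moved <- rigid_move(atoms)
  drop_res <- sort(unique(moved$resno))[c(30, 55, 70, 95, 110)]
  moved <- moved[!(moved$resno %in% drop_res), ]
  sp <- structure_align(atoms, moved)
  expect_equal(sp$rmsd, 0, tolerance = 1e-4)
  expect_equal(sp$n_aligned, n_res - 5)

  # symmetry: A->B and B->A rmsd agree
  spAB <- structure_align(atoms, moved)
  spBA <- structure_align(moved, atoms)
  expect_lt(abs(spAB$rmsd - spBA$rmsd), 0.05)
})
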