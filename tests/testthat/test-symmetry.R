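test_that("space-group operators form a group and invert cleanly", {
  for (sg in c("P 1", "P 1 21 1", "C 1 2 1", "P 21 21 21", "P 43 21 2")) {
    ops <- space_group_operators(sg)
    # identity present
    expect_true(any(vapply(ops, function(o)
      all(o$R == diag(3)) && all(o$t == 0), logical(1))))
    for (o in ops) {
      expect_equal(abs(det(o$R)), 1, tolerance = 1e-12)
      # inverse round-trip in fractional coordinates
      x <- c(0.13, 0.27, 0.81)
      y <- as.numeric(o$R %*% x + o$t)
      back <- as.numeric(solve(o$R) %*% (y - o$t))
      expect_equal(back, x, tolerance = 1e-9)
    }
    # closure: any composition equals a group operator modulo lattice
    # translation
    for (o1 in ops) for (o2 in ops) {
      Rc <- o1$R %*% o2$R
      tc <- as.numeric(o1$R %*% o2$t + o1$t)
      hit <- any(vapply(ops, function(o) {
        all(o$R == Rc) && all(abs((tc - o$t) %% 1) < 1e-9 |
                                abs((tc - o$t) %% 1 - 1) < 1e-9)
      }, logical(1)))
      expect_true(hit)
    }
  }
  expect_error(space_group_operators("P 61"), "not in the built-in table")
})

test_that("applying a P212121 operator twice is a pure lattice translation", {
  ops <- space_group_operators("P 21 21 21")
  cell <- c(40, 50, 60, 90, 90, 90)
  for (o in ops) {
    R2 <- o$R %*% o$R
    t2 <- as.numeric(o$R %*% o$t + o$t)
    expect_equal(R2, diag(3), ignore_attr = TRUE)
    expect_equal(t2, round(t2), tolerance = 1e-9)
  }
})

test_that("an isolated molecule in an oversized P1 cell has no mates", {
  atoms <- fx_monomer()$atoms
  atoms$x <- atoms$x + 100; atoms$y <- atoms$y + 100; atoms$z <- atoms$z + 100
  crystal <- list(space_group = "P 1", cell = c(200, 200, 200, 90, 90, 90),
                  operators = space_group_operators("P 1"))
  s <- pascreen:::.new_structure(atoms, crystal = crystal)
  expect_length(expand_symmetry(s, radius = 5), 0)
  bur <- crystal_contact_burial(s, "A", radius = 5, n_points = 240)
  expect_equal(bur$chain_fraction, 0, tolerance = 1e-12)
  expect_equal(bur$n_mates, 0)
})

test_that("a tight crystal packs mates that bury surface", {
  atoms <- fx_monomer()$atoms
  # center the molecule in a snug orthorhombic cell
  for (ax in c("x", "y", "z")) {
    atoms[[ax]] <- atoms[[ax]] - min(atoms[[ax]]) + 3
  }
  cell <- c(max(atoms$x) + 4, max(atoms$y) + 4, max(atoms$z) + 4, 90, 90, 90)
  crystal <- list(space_group = "P 21 21 21", cell = cell,
                  operators = space_group_operators("P 21 21 21"))
  s <- pascreen:::.new_structure(atoms, crystal = crystal)
  mates <- expand_symmetry(s, radius = 5)
  expect_gt(length(mates), 0)
  # each mate round-trips through the inverse operator to the original
  M <- pascreen:::.orth_matrix(cell)
  for (m in mates[seq_len(min(3, length(mates)))]) {
    op <- crystal$operators[[m$op_index]]
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")])
    frac <- xyz %*% t(solve(M))
    back <- sweep(frac, 2, op$t + m$shift) %*% t(solve(op$R)) %*% t(M)
    expect_equal(back, as.matrix(atoms[, c("x", "y", "z")]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  bur <- crystal_contact_burial(s, "A", radius = 5, n_points = 240)
  expect_gt(bur$chain_fraction, 0.05)
  expect_lte(bur$chain_fraction, 1)
  # the range reading reports the requested residues only
  rng <- range(atoms$resno)
  sub <- crystal_contact_burial(s, "A",
                                resno_range = c(rng[1], rng[1] + 20),
                                radius = 5, n_points = 240)
  expect_true(sub$range_fraction >= 0 && sub$range_fraction <= 1)
})
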