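test_that("hydrogen-bond energy follows the electrostatic model", {
  # symmetric geometry where all four distances are equal: terms cancel
  e <- pascreen:::.ks_energy(N = c(0, 0, 0), H = c(2, 0, 0),
                             C = c(1, -1, 0), O = c(1, 1, 0))
  expect_equal(e, 0, tolerance = 1e-12)

  # i -> i+4 pair inside a generated ideal helix is a solid bond
  h <- build_ideal_chain(list(list(kind = "helix", length = 12,
                                   phi = -57, psi = -47)))
  res <- function(i) h[h$resno == i, ]
  e <- hbond_energy(res(5), res(1), donor_prev = res(4))
  expect_lt(e, -0.5)

  # 1/r decay: residues 50 A apart contribute nothing
  far <- res(5)
  far[, c("x", "y", "z")] <- far[, c("x", "y", "z")] + 50
  e <- hbond_energy(far, res(1), donor_prev = NULL)
  expect_lt(abs(e), 0.05)

  # missing backbone atom gives the undefined sentinel
  noO <- res(1)[res(1)$elety != "O", ]
  expect_true(is.na(hbond_energy(res(5), noO, donor_prev = res(4))))
})

test_that("assignment labels helices, strands and degenerate chains", {
  h <- build_ideal_chain(list(list(kind = "helix", length = 12,
                                   phi = -57, psi = -47)))
  a <- assign_secondary_structure(h)
  expect_true(all(a$labels[3:10] == "H"))
  # every H residue takes part in an i+/-4 helical bond below the cutoff
  hres <- names(a$labels)[a$labels == "H"]
  for (k in hres) {
    dres <- as.integer(sub("\\|.*", "", a$hbonds$donor))
    ares <- as.integer(sub("\\|.*", "", a$hbonds$acceptor))
    i <- as.integer(sub("\\|.*", "", k))
    expect_true(any((dres == i & ares == i - 4) | (ares == i & dres == i + 4)))
  }

  # two-strand antiparallel pairing labels strand residues E
  frag <- pascreen:::.canonical_fragment(build_ideal_chain(list(
    list(kind = "strand", length = 7, phi = -139, psi = 135))))
  partner <- pascreen:::.place_fragment(frag, translate = c(2, 0, 4.5),
                                        flip = "z")
  partner$resno <- partner$resno + 20
  hp <- rbind(frag, partner)
  a2 <- assign_secondary_structure(hp)
  expect_gte(sum(a2$labels == "E"), 6)

  # tiny chains are all coil with a warning
  tri <- build_ideal_chain(list(list(kind = "coil", length = 3,
                                     phi = -70, psi = 150)))
  expect_warning(a3 <- assign_secondary_structure(tri), "fewer than 5")
  expect_true(all(a3$labels == "C"))
})

test_that("assignment is invariant under rigid motion", {
  atoms <- fx_monomer()$atoms
  a1 <- assign_secondary_structure(atoms)
  a2 <- assign_secondary_structure(rigid_move(atoms, angle = 71,
                                              axis = c(2, -1, 1),
                                              shift = c(-20, 4, 9)))
  expect_identical(a1$labels, a2$labels)
})

test_that("segmentation applies minimum element lengths and partitions", {
  mk_assign <- function(labels, keys) {
    structure(list(labels = stats::setNames(labels, keys),
                   hbonds = data.frame()), class = "SSAssignment")
  }
  h <- build_ideal_chain(list(list(kind = "helix", length = 8,
                                   phi = -57, psi = -47)))
  keys <- paste0(1:8, "|")
  els <- segment_elements(mk_assign(c("C", rep("H", 6), "C"), keys), h)
  expect_length(els, 1)
  expect_equal(els[[1]]$kind, "helix")
  expect_equal(els[[1]]$sequence_index, 1)

  # an H run of 3 is below the minimum helix length
  els <- segment_elements(mk_assign(c(rep("C", 3), rep("H", 3), "C", "C"),
                                    keys), h)
  expect_length(els, 0)

  # elements never overlap on the monomer fixture
  mono <- fx_monomer()
  ann <- annotate_pas(mono$atoms)
  all_keys <- unlist(lapply(ann$elements, `[[`, "residue_keys"))
  expect_equal(anyDuplicated(all_keys), 0)
  expect_equal(length(Filter(function(e) e$kind == "helix", ann$elements)), 3)
  expect_equal(length(Filter(function(e) e$kind == "strand", ann$elements)), 5)
})

test_that("polar contacts respect distance cutoff and symmetry", {
  mk <- function(chain, resno, elety, elesy, x, y = 0, z = 0) {
    data.frame(chain = chain, resno = resno, insert = "", resid = "ASN",
               elety = elety, elesy = elesy, alt = "", x = x, y = y, z = z,
               o = 1, b = 0, is_het = FALSE, stringsAsFactors = FALSE)
  }
  a <- mk("A", 10, "ND2", "N", 0)
  b <- mk("B", 55, "O", "O", 2.9)
  hits <- find_polar_contacts(a, b, d_max = 3.5)
  expect_equal(nrow(hits), 1)
  expect_true(hits$inter_chain)
  expect_equal(hits$distance, 2.9, tolerance = 1e-9)

  b_far <- mk("B", 55, "O", "O", 4.5)
  expect_equal(nrow(find_polar_contacts(a, b_far, 3.5)), 0)

  # symmetric up to role swap
  swapped <- find_polar_contacts(b, a, 3.5)
  expect_equal(swapped$distance, hits$distance)
  expect_equal(swapped$chainA, hits$chainB)

  expect_error(find_polar_contacts(a[0, ], b, 3.5), "empty")

  # a carbon pair is never a polar contact
  c1 <- mk("A", 1, "CB", "C", 0)
  c2 <- mk("B", 2, "CB", "C", 2.9)
  expect_equal(nrow(find_polar_contacts(c1, c2, 3.5)), 0)
})

test_that("the planted N-cap forms a detectable polar link into the helix", {
  mono <- fx_monomer()
  s <- pascreen:::.new_structure(mono$atoms)
  ncap_res <- mono$truth$ncap$ncap_resno
  selA <- select_atoms(s, resno = ncap_res, scope = "sidechain")
  selB <- select_atoms(s, resno = ncap_res + 1:4, scope = "backbone")
  hits <- find_polar_contacts(selA, selB, d_max = 3.5)
  expect_gte(nrow(hits), 1)
  expect_true(any(hits$atomA == "OG" & hits$atomB == "N"))
})
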