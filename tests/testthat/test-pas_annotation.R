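test_that("sheet order is computed and orientation-normalized", {
  mono <- fx_monomer()
  ann <- annotate_pas(mono$atoms)
  expect_equal(ann$sheet_order, "2-5-1-4-3")

  # a string and its reversal normalize identically
  expect_equal(pascreen:::.normalize_order("2-5-1-4-3"),
               pascreen:::.normalize_order("3-4-1-5-2"))
  expect_equal(pascreen:::.normalize_order("1-2"),
               pascreen:::.normalize_order("2-1"))

  # a two-strand sheet orders trivially
  frag <- pascreen:::.canonical_fragment(build_ideal_chain(list(
    list(kind = "strand", length = 7, phi = -139, psi = 135))))
  partner <- pascreen:::.place_fragment(frag, translate = c(2, 0, 4.5),
                                        flip = "z")
  partner$resno <- partner$resno + 20
  hp <- rbind(frag, partner)
  a <- assign_secondary_structure(hp)
  strands <- Filter(function(e) e$kind == "strand", segment_elements(a, hp))
  expect_length(strands, 2)
  expect_equal(order_sheet_strands(strands, hp, a), "1-2")
  expect_error(order_sheet_strands(strands[1], hp, a), "at least 2")
})

test_that("monomer fixtures annotate to their construction ground truth", {
  mono <- fx_monomer()
  ann <- annotate_pas(mono$atoms)
  expect_true(ann$is_pas)
  tr <- mono$truth$element_ranges
  for (nm in c("alpha1", "alpha2", "alpha3")) {
    el <- ann$alpha[[nm]]
    expect_false(is.null(el))
    # the detected element lies inside the constructed span (termini may
    # be trimmed by the hydrogen-bond pattern)
    expect_gte(el$start, tr[[nm]][1] - 1)
    expect_lte(el$end, tr[[nm]][2] + 1)
    expect_gte(el$end - el$start + 1, 5)
  }
  for (k in 1:5) {
    el <- ann$beta[[paste0("beta", k)]]
    tk <- tr[[paste0("beta", k)]]
    expect_gte(el$start, tk[1] - 1)
    expect_lte(el$end, tk[2] + 1)
  }
})

test_that("four-strand controls are rejected as PAS folds", {
  m4 <- build_pas_monomer(fixture_spec("pas_monomer", n_strands = 4))
  ann <- annotate_pas(m4$atoms)
  expect_false(ann$is_pas)
})

test_that("annotation is invariant under rigid motion and chain renaming", {
  mono <- fx_monomer()
  moved <- rigid_move(mono$atoms, angle = 113, axis = c(1, 0, 2),
                      shift = c(8, 40, -7))
  moved$chain <- "Q"
  ann1 <- annotate_pas(mono$atoms)
  ann2 <- annotate_pas(moved)
  expect_equal(ann2$is_pas, ann1$is_pas)
  expect_equal(ann2$sheet_order, ann1$sheet_order)
  expect_equal(ann2$alpha$alpha1$start, ann1$alpha$alpha1$start)
  expect_equal(ann2$ncap$ncap_class, ann1$ncap$ncap_class)
})

test_that("the planted Ser N-cap is detected with its capping bond", {
  mono <- fx_monomer()
  ann <- annotate_pas(mono$atoms)
  nc <- ann$ncap
  expect_equal(nc$ncap_class, "capping_box")
  expect_true(nc$capping_hbond)
  expect_equal(nc$preceding_residue, "L")
  expect_equal(nc$preceding_class, "LI")
  expect_equal(nc$ncap_resno, mono$truth$ncap$ncap_resno)
})

test_that("N-cap classing follows the rule table and flags missing atoms", {
  mono <- fx_monomer()
  atoms <- mono$atoms
  ncap_res <- mono$truth$ncap$ncap_resno
  # mutate the Ser N' to Ala: no capping class, no side-chain acceptor
  atoms$resid[atoms$resno == ncap_res] <- "ALA"
  atoms <- atoms[!(atoms$resno == ncap_res & atoms$elety == "OG"), ]
  ann <- annotate_pas(atoms)
  expect_equal(ann$ncap$ncap_class, "absent")
  expect_false(isTRUE(ann$ncap$capping_hbond))

  # non-traditional N' residue
  atoms2 <- mono$atoms
  atoms2$resid[atoms2$resno == ncap_res] <- "GLN"
  ann2 <- annotate_pas(atoms2)
  expect_equal(ann2$ncap$ncap_class, "non_traditional")

  # capping bond is never reported without both partner atoms present:
  # strip all side chains of N' and N1
  atoms3 <- mono$atoms
  h1 <- ann2$alpha$alpha1$start
  drop <- atoms3$resno %in% c(ncap_res, h1) &
    !(atoms3$elety %in% c("N", "CA", "C", "O"))
  atoms3 <- atoms3[!drop, ]
  ann3 <- annotate_pas(atoms3)
  expect_true(is.na(ann3$ncap$capping_hbond))
})

test_that("a helix at the chain terminus has no N-cap by definition", {
  h <- build_ideal_chain(list(list(kind = "helix", length = 12,
                                   phi = -57, psi = -47)))
  a <- assign_secondary_structure(h)
  els <- segment_elements(a, h)
  # detected helix may start at residue 2; shift keys so it starts at the
  # first residue of the chain
  helix <- els[[1]]
  if (helix$residue_keys[1] != "1|") {
    helix$residue_keys <- c("1|", helix$residue_keys)
  }
  nc <- detect_ncap(h, helix)
  expect_equal(nc$ncap_class, "absent")
  expect_equal(nc$reason, "terminal")
})
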