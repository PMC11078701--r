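test_that("minimal PDB and mmCIF parse to the same hierarchy", {
  fp <- tempfile(fileext = ".pdb")
  writeLines(minimal_pdb_text(), fp)
  s <- read_structure(fp)
  expect_length(structure_chains(s), 1)
  expect_equal(nrow(s$atoms), 4)
  expect_equal(unique(s$atoms$resno), 1)
  expect_equal(sort(s$atoms$elety), sort(c("N", "CA", "C", "O")))

  fc <- tempfile(fileext = ".cif")
  writeLines(minimal_cif_text(), fc)
  sc <- read_structure(fc)
  expect_equal(nrow(sc$atoms), 4)
  ord_p <- order(s$atoms$elety)
  ord_c <- order(sc$atoms$elety)
  expect_equal(s$atoms[ord_p, c("x", "y", "z")],
               sc$atoms[ord_c, c("x", "y", "z")],
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(sc$atoms$resno, s$atoms$resno)
})

test_that("PDB round-trip preserves coordinates, numbering and B-factors", {
  mono <- fx_monomer()
  atoms <- mono$atoms
  atoms$b <- 90
  crystal <- list(space_group = "P 21 21 21", cell = c(60, 70, 80, 90, 90, 90),
                  operators = space_group_operators("P 21 21 21"))
  p <- write_tmp_pdb(atoms, crystal = crystal)
  s2 <- read_structure(p)
  expect_equal(nrow(s2$atoms), nrow(atoms))
  expect_equal(s2$atoms$resno, atoms$resno)
  expect_equal(s2$atoms$chain, atoms$chain)
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_true(all(s2$atoms$b == 90))
  expect_equal(s2$crystal$space_group, "P 21 21 21")
  expect_length(s2$crystal$operators, 4)
})

test_that("writing an empty structure errors", {
  s <- pascreen:::.new_structure(fx_monomer()$atoms[0, ])
  expect_error(write_structure(s, tempfile(fileext = ".pdb")), "empty")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  base <- fx_monomer()$atoms[1:4, ]
  altA <- base[2, ]; altA$alt <- "A"; altA$o <- 0.4; altA$x <- 10
  altB <- base[2, ]; altB$alt <- "B"; altB$o <- 0.6; altB$x <- 20
  got <- pascreen:::.resolve_altloc(rbind(base[1, ], altA, altB, base[3:4, ]))
  ca <- got[got$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 20)
  # occupancy tie: alphabetically first altloc wins
  altB$o <- 0.4
  got <- pascreen:::.resolve_altloc(rbind(base[1, ], altA, altB, base[3:4, ]))
  expect_equal(got[got$elety == "CA", ]$x, 10)
})

test_that("pLDDT profile averages CA B-factors and flags out-of-range", {
  atoms <- fx_monomer()$atoms
  atoms$b <- 90
  s <- pascreen:::.new_structure(atoms)
  pr <- extract_plddt_profile(s)
  expect_equal(pr$mean, 90)
  n_res <- length(unique(atoms$resno))
  expect_length(pr$values, n_res)
  # {80, 100} averages to 90
  atoms2 <- atoms
  ca <- which(atoms2$elety == "CA")
  atoms2$b[ca] <- rep_len(c(80, 100), length(ca))
  atoms2$b[ca[seq(2, length(ca), by = 2)]] <- 100
  atoms2$b[ca[seq(1, length(ca), by = 2)]] <- 80
  pr2 <- extract_plddt_profile(pascreen:::.new_structure(atoms2))
  expect_equal(pr2$mean, mean(atoms2$b[ca]))
  # crystal structures can exceed 100: values returned with a warning
  atoms$b <- 150
  expect_warning(pr3 <- extract_plddt_profile(pascreen:::.new_structure(atoms)),
                 "outside")
  expect_true(all(pr3$values == 150))
})

test_that("Dali hit parsing applies a strict Z threshold and keeps order", {
  f <- tempfile()
  writeLines(c("1abcA 8.1", "2xyzB 2.0", "3defC 1.4"), f)
  hits <- parse_dali_hits(f, z_min = 2)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pdb_chain_id, "1abcA")

  writeLines(character(0), f)
  expect_equal(nrow(parse_dali_hits(f, 2)), 0)

  writeLines(sprintf("hit%d %0.1f", 1:5, 5 + 1:5), f)
  hits <- parse_dali_hits(f, 2)
  expect_equal(hits$pdb_chain_id, paste0("hit", 1:5))

  writeLines(c("good 5.0", "bad-line", "also bad Z"), f)
  expect_warning(hits <- parse_dali_hits(f, 2), "malformed")
  expect_equal(nrow(hits), 1)
  expect_equal(attr(hits, "n_malformed"), 2)
  # z_min = -Inf keeps every well-formed line
  writeLines(c("a 1.0", "b -3.0", "c 0.0"), f)
  expect_equal(nrow(parse_dali_hits(f, -Inf)), 3)
})
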