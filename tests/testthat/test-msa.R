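test_that("alignment readers handle FASTA, Stockholm and ragged input", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACD-G", ">b", "ACE-G", ">c", "AAAAG"), f)
  m <- read_msa(f)
  expect_length(m$ids, 3)
  expect_equal(m$n_columns, 5)

  # round-trip through the writer
  f2 <- tempfile(fileext = ".fasta")
  write_msa(m, f2)
  m2 <- read_msa(f2)
  expect_identical(m2$seqs, m$seqs)

  writeLines(c(">a", "ACD-G", ">b", "ACEG"), f)
  expect_error(read_msa(f), "ragged.*'b'")

  st <- tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID test", "a ACD-G", "b ACE-G",
               "#=GC SS_cons xxxxx", "//"), st)
  ms <- read_msa(st)
  expect_equal(unname(ms$seqs["a"]), "ACD-G")
  expect_equal(length(ms$ids), 2)
})

test_that("pairwise identity follows the stated denominator convention", {
  expect_equal(pairwise_identity("ACDEF", "ACDEF"), 100)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  # 3 identities over 4 comparable columns
  expect_equal(pairwise_identity("ACD-G", "ACE-G"), 75)
  expect_equal(pairwise_identity("ACD-G", "ACE-G", mode = "aligned"), 75)
  expect_equal(pairwise_identity("AC--G", "ACE-G", mode = "longest"), 75)
  # symmetry
  expect_equal(pairwise_identity("ACD-G", "ACE-G"),
               pairwise_identity("ACE-G", "ACD-G"))
  expect_error(pairwise_identity("---", "---"), "comparable")
})

test_that("redundancy filtering is greedy, certified and idempotent", {
  m <- new_msa(c("a", "b", "c"), c("ACDEF", "ACDEF", "GHIKL"))
  r <- remove_redundancy(m, 98)
  expect_length(r$ids, 2)

  # all-distinct records below the threshold are all retained
  m2 <- new_msa(c("a", "b", "c"), c("AAAAA", "CCCCC", "DDDDD"))
  expect_length(remove_redundancy(m2, 98)$ids, 3)

  # 50-record synthetic alignment with planted duplicate clusters: the
  # retained set matches an independent greedy replay on the full
  # pairwise-identity matrix
  built <- build_msa(fixture_spec("msa", n = 50, identity = 97.5,
                                  rng_seed = 7))
  m3 <- built$msa
  filt <- remove_redundancy(m3, 96)
  # independent oracle: full matrix + same greedy order
  seqs <- m3$seqs
  lens <- nchar(gsub("-", "", seqs))
  ord <- order(-lens, seq_along(seqs))
  idm <- outer(seq_along(seqs), seq_along(seqs),
               Vectorize(function(i, j) pairwise_identity(seqs[i], seqs[j])))
  kept <- integer(0)
  for (i in ord) {
    if (all(idm[i, kept] < 96)) kept <- c(kept, i)
  }
  expect_setequal(filt$ids, m3$ids[kept])
  # certification: every retained pair is below the threshold
  fs <- filt$seqs
  for (i in seq_along(fs)) for (j in seq_len(i - 1)) {
    expect_lt(pairwise_identity(fs[i], fs[j]), 96)
  }
  # idempotence
  again <- remove_redundancy(filt, 96)
  expect_identical(again$ids, filt$ids)
})

test_that("column-to-query mapping degaps correctly", {
  m <- new_msa(c("q", "s"), c("M-KL", "MAK-"), query_id = "q")
  mp <- map_columns_to_query(m)
  expect_equal(mp, c(1L, NA, 2L, 3L))
  mp5 <- map_columns_to_query(m, offset = 5)
  expect_equal(mp5, c(5L, NA, 6L, 7L))
  # degapping the query row reproduces the ungapped sequence
  q <- strsplit(m$seqs[["q"]], "")[[1]]
  expect_equal(paste(q[!is.na(mp)], collapse = ""), "MKL")
  m_nog <- new_msa(c("q", "s"), c("----", "MAKL"), query_id = "q")
  expect_error(map_columns_to_query(m_nog), "all gaps")
})

test_that("conservation profile scores columns and ignores record order", {
  m <- new_msa(c("a", "b", "c", "d"),
               c("NNAA", "NDAC", "NDA-", "NNAG"))
  pr <- conservation_profile(m)
  expect_equal(pr$score[1], 1)
  expect_equal(pr$score[2], 0.5)
  expect_equal(pr$score[3], 1)
  expect_equal(pr$gap_fraction[4], 0.25)
  # permutation invariance
  m_perm <- new_msa(c("d", "b", "a", "c"),
                    c("NNAG", "NDAC", "NNAA", "NDA-"))
  pr2 <- conservation_profile(m_perm)
  expect_equal(pr2$score, pr$score)
  expect_error(conservation_profile(new_msa("a", "AAAA")), "at least 2")
})

test_that("the N-cap census recovers planted frequencies exactly", {
  built <- build_msa(fixture_spec("msa", n = 100, rng_seed = 11,
                                  freq = c(capping_box = 0.9,
                                           non_traditional = 0.06,
                                           pre_LI = 0.85, pre_MV = 0.1)))
  cen <- ncap_census(built$msa, built$truth$ncap_col, built$truth$pre_col)
  expect_equal(cen$n_capping_box, built$truth$counts$capping_box)
  expect_equal(cen$n_capping_box, 90)
  expect_equal(cen$n_non_traditional, built$truth$counts$non_traditional)
  expect_equal(cen$n_preceding_LI, built$truth$counts$pre_LI)
  expect_equal(cen$n_preceding_MV, built$truth$counts$pre_MV)
  expect_equal(cen$frac_capping_box, 0.90)

  # all-Leu preceding column
  m <- new_msa(c("a", "b"), c("LS", "LT"))
  cen2 <- ncap_census(m, 2, 1)
  expect_equal(cen2$frac_preceding_LI, 1)

  # permutation of records leaves fractions unchanged
  m3 <- built$msa
  perm <- rev(seq_along(m3$ids))
  m3p <- new_msa(m3$ids[perm], unname(m3$seqs[perm]))
  cen3 <- ncap_census(m3p, built$truth$ncap_col, built$truth$pre_col)
  expect_equal(cen3$frac_capping_box, cen$frac_capping_box)

  expect_error(ncap_census(m, 99, 1), "out of range")
})
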