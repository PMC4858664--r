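test_that("FASTA parsing normalises case and validates the alphabet", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACDE", ">y desc", "acde", ">z", "MKV", "LLQ"), fa)
  seqs <- read_fasta(fa)
  expect_length(seqs, 3)
  expect_identical(seqs[[1]]$residues, c("A", "C", "D", "E"))
  expect_identical(seqs[[2]]$residues, c("A", "C", "D", "E"))
  expect_identical(paste(seqs[[3]]$residues, collapse = ""), "MKVLLQ")
  expect_match(seqs[[1]]$id, "^x")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">b", "BCD"), bad)
  err <- expect_error(read_fasta(bad), class = "aggscape_format_error")
  expect_match(conditionMessage(err), "position 1")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), class = "aggscape_input_error")
})

test_that("PDB write -> read round trip preserves structure", {
  pair <- test_pair()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(pair$A, f)
  back <- read_pdb(f)
  expect_length(back, length(pair$A))
  expect_equal(back$weights, rep(1 / 4, 4))
  for (m in seq_along(back$structures)) {
    a0 <- pair$A$structures[[m]]$atoms
    a1 <- back$structures[[m]]$atoms
    expect_identical(nrow(a1), nrow(a0))
    expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                      as.matrix(a0[, c("x", "y", "z")]))), 1e-3)
  }
  expect_identical(extract_sequence(back$structures[[1]])$residues,
                   pair$sequence$residues)
  expect_length(read_pdb(f, model_policy = "first"), 1)
})

test_that("altloc records resolve to the highest occupancy, ties to file order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  C  AALA A   1       2.000   1.000   0.000  0.50  0.00           C",
    "ATOM      5  C  BALA A   1       8.000   1.000   0.000  0.50  0.00           C",
    "ATOM      6  O   ALA A   1       2.500   2.000   0.000  1.00  0.00           O",
    "HETATM    7  O   HOH A 101       5.000   5.000   5.000  1.00  0.00           O",
    "END"), f)
  ens <- read_pdb(f)
  at <- ens$structures[[1]]$atoms
  expect_identical(nrow(at), 4L)                       # water dropped, alts resolved
  expect_equal(at$x[at$elety == "CA"], 1.0)            # occupancy 0.6 wins
  expect_equal(at$x[at$elety == "C"], 2.0)             # tie -> first in file
})

test_that("non-standard residues are rejected at sequence extraction", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   MSE A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  MSE A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END"), f)
  ens <- read_pdb(f)
  expect_error(extract_sequence(ens$structures[[1]]),
               class = "aggscape_format_error")
})

test_that("original PDB numbering is kept as metadata after renumbering", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  55       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A  60       3.800   0.000   0.000  1.00  0.00           C",
    "END"), f)
  st <- read_pdb(f)$structures[[1]]
  expect_equal(st$atoms$resno, c(1L, 2L))
  expect_equal(st$atoms$orig_resno, c(55, 60))
})

test_that("profile tables round-trip through TSV to 1e-6", {
  set.seed(1)
  s <- as_sequence("ACDEFGHIKL")
  prof <- intrinsic_profile(s, profile_params(window = 3))
  prof$values <- prof$values + rnorm(10) * 0.123456789
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_table(prof, f)
  back <- read_profile_table(f)
  expect_identical(nrow(back), 10L)
  expect_identical(back$code, s$residues)
  expect_lt(max(abs(back$score - prof$values)), 1e-6)

  prof$values <- numeric(0)
  expect_error(write_profile_table(prof, f), class = "aggscape_input_error")
})

test_that("weight normalization is idempotent and validates input", {
  w <- normalize_weights(c(2, 2, 4))
  expect_equal(sum(w), 1)
  expect_equal(normalize_weights(w), w)
  expect_error(normalize_weights(c(-1, 2)), class = "aggscape_input_error")
  expect_error(normalize_weights(c(0, 0)), class = "aggscape_input_error")

  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1", "3"), f)
  expect_equal(read_weights(f), c(0.25, 0.75))
  expect_error(read_weights(f, n = 3), class = "aggscape_input_error")
})

test_that("ensembles enforce a shared residue composition", {
  a <- build_chain("VVV")
  b <- build_chain("VVT")
  expect_error(as_ensemble(list(a, b)), class = "aggscape_input_error")
  e <- as_ensemble(list(a, a, a))
  expect_equal(e$weights, rep(1 / 3, 3))
})
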