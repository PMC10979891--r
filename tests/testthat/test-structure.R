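lysozyme_pdb <- file.path(system.file("examples", package = "bio3d"), "1hel.pdb")
lysozyme_dssp <- test_path("fixtures", "1hel.dssp")

toy_pdb <- function(residues = c("GLY", "ALA", "SER"), chain = "A",
                    path = withr::local_tempfile(fileext = ".pdb",
                                                 .local_envir = parent.frame())) {
  n <- length(residues)
  writeLines(c(
    sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            seq_len(n), residues, chain, seq_len(n), 3.8 * seq_len(n),
            rep(0, n), rep(0, n), rep(1, n), rep(77.5, n)),
    "END"
  ), path)
  path
}

test_that("structure parsing extracts residues, coordinates and pLDDT", {
  m <- parse_structure(toy_pdb())
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$residues), 3L)
  expect_equal(m$residues$residue, c("G", "A", "S"))
  expect_equal(m$residues$plddt, rep(77.5, 3))
  expect_true(all(is.finite(m$atoms$x)))

  big <- parse_structure(lysozyme_pdb)
  expect_equal(nrow(big$residues), 129L)
  expect_equal(big$residues$residue[1:3], c("K", "V", "F"))
})

test_that("structures without protein residues or without a chain selector fail", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"
  ), p)
  expect_error(parse_structure(p), class = "tagsite_input_error")

  two_chain <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  ALA B   1       9.000   0.000   0.000  1.00 10.00           C",
    "END"
  ), two_chain)
  expect_error(parse_structure(two_chain), "chain", class = "tagsite_input_error")
  m <- parse_structure(two_chain, chain = "B")
  expect_equal(m$residues$residue, "A")
})

test_that("structure residues map onto the query with identity checking", {
  m <- parse_structure(toy_pdb())
  q <- validate_sequence("GAS")
  mapped <- map_structure_to_query(m, q)
  expect_equal(mapped$residues$query_position, 1:3)

  err <- expect_error(map_structure_to_query(m, validate_sequence("GWS")),
                      class = "tagsite_input_error")
  expect_match(conditionMessage(err), "position 2")
})

test_that("classic DSSP output parses with canonicalized codes", {
  d <- parse_dssp(lysozyme_dssp)
  expect_equal(nrow(d), 129L)
  expect_equal(d$residue[1:3], c("K", "V", "F"))
  # loop lines have a blank structure column, canonicalized to C
  expect_equal(d$ss_code[1], "C")
  expect_equal(d$ss_code[5], "H")
  expect_equal(d$sasa[1], 79)
  expect_true(all(d$sasa >= 0))

  p <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "==== header ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    paste0("    1    1 A a  -", strrep(" ", 17), "  10"),
    "    2        !",
    paste0("    3    2 A M  T ", strrep(" ", 16), "  25")
  ), p)
  d2 <- parse_dssp(p)
  # lowercase letters are cystine-bridge cysteines; "-" becomes coil;
  # chain-break records are skipped
  expect_equal(d2$residue, c("C", "M"))
  expect_equal(d2$ss_code, c("C", "T"))
  expect_equal(d2$sasa, c(10, 25))

  writeLines(c("no residue table here"), p)
  expect_error(parse_dssp(p), "header", class = "tagsite_input_error")
})

test_that("secondary-structure binning covers the full DSSP alphabet", {
  expect_equal(ss_score(c("H", "G", "I", "E")), c(0, 0, 0, 0))
  expect_equal(ss_score(c("C", " ", "", "-")), c(1, 1, 1, 1))
  expect_equal(ss_score(c("B", "T", "S", "P")), c(0.5, 0.5, 0.5, 0.5))
  err <- expect_error(ss_score(c("H", "Z")), class = "tagsite_input_error")
  expect_match(conditionMessage(err), "\"Z\"")
})

test_that("RSA normalization divides by the residue maximum and clamps", {
  q <- validate_sequence("GAXW")
  mx <- max_sa_table()
  expect_equal(length(mx), 20L)
  expect_true(all(mx > 0))
  sasa <- tibble::tibble(
    position = 1:4,
    sasa = c(0, mx[["A"]], 50, 1.2 * mx[["W"]])
  )
  tr <- rsa_track(sasa, q)
  expect_equal(tr$value[1], 0)
  expect_equal(tr$value[2], 1)
  expect_true(is.na(tr$value[3]))   # X has no maximum
  expect_equal(tr$value[4], 1)      # clamped
  # monotone in SASA before clamping
  expect_lt(rsa_track(tibble::tibble(position = 1, sasa = 10),
                      validate_sequence("W"))$value,
            rsa_track(tibble::tibble(position = 1, sasa = 20),
                      validate_sequence("W"))$value)
})

test_that("Shrake-Rupley SASA matches an independent implementation", {
  m <- parse_structure(lysozyme_pdb)
  s <- shrake_rupley_sasa(m)
  # per-residue values frozen from an independent Shrake-Rupley run
  # (probe 1.4 A, 960 sphere points) on the same coordinates
  oracle <- c(78.63, 100.36, 17.25, 32.61, 80.62, 44.27, 88.89, 0.50, 0.00,
              41.44, 21.30, 1.89, 86.37, 192.29, 36.73, 36.03, 0.00, 62.57,
              89.19, 65.29)
  expect_lt(max(abs(s$sasa[1:20] - oracle)), 3)
  expect_true(all(s$sasa >= 0))
})

test_that("Shrake-Rupley SASA on a free glycine matches the independent oracle", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1      -0.525   1.362   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       1.526   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       2.153  -1.062   0.000  1.00  0.00           O",
    "END"
  ), p)
  s <- shrake_rupley_sasa(parse_structure(p))
  expect_equal(s$sasa, 187.472, tolerance = 0.10)
})

test_that("an atom buried in a cage has zero accessible area", {
  p <- withr::local_tempfile(fileext = ".pdb")
  # central CA surrounded by an octahedral cage of tightly packed atoms
  cage <- rbind(
    c(2.2, 0, 0), c(-2.2, 0, 0), c(0, 2.2, 0), c(0, -2.2, 0),
    c(0, 0, 2.2), c(0, 0, -2.2),
    c(1.6, 1.6, 0), c(-1.6, 1.6, 0), c(1.6, -1.6, 0), c(-1.6, -1.6, 0),
    c(1.6, 0, 1.6), c(-1.6, 0, 1.6), c(1.6, 0, -1.6), c(-1.6, 0, -1.6),
    c(0, 1.6, 1.6), c(0, -1.6, 1.6), c(0, 1.6, -1.6), c(0, -1.6, -1.6)
  )
  lines <- sprintf(
    "ATOM  %5d  %-3s GLY A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    1:19, c("CA", rep("CB", 18)), c(1, rep(2, 18)),
    c(0, cage[, 1]), c(0, cage[, 2]), c(0, cage[, 3]), rep(1, 19), rep(0, 19)
  )
  writeLines(c(lines, "END"), p)
  s <- shrake_rupley_sasa(parse_structure(p))
  expect_equal(s$sasa[1], 0)
})

test_that("SASA converges as the sphere lattice is refined", {
  m <- parse_structure(toy_pdb(c("TRP", "GLY", "LYS")))
  s1 <- shrake_rupley_sasa(m, n_points = 960)
  s2 <- shrake_rupley_sasa(m, n_points = 1920)
  expect_true(all(abs(s2$sasa - s1$sasa) / pmax(s1$sasa, 1) < 0.02))
  # and is deterministic
  expect_identical(s1$sasa, shrake_rupley_sasa(m, n_points = 960)$sasa)
})

test_that("DSSP-derived and internal RSA agree on the reference structure", {
  q <- validate_sequence(paste(parse_dssp(lysozyme_dssp)$residue, collapse = ""),
                         id = "1HEL_A")
  d <- parse_dssp(lysozyme_dssp)
  rsa_ref <- rsa_track(d, q)
  m <- map_structure_to_query(parse_structure(lysozyme_pdb), q)
  s <- shrake_rupley_sasa(m)
  s$position <- m$residues$query_position
  rsa_int <- rsa_track(s, q)
  expect_true(all(abs(rsa_ref$value - rsa_int$value) <= 0.15))
})

test_that("geometric secondary structure broadly tracks DSSP helix assignments", {
  m <- parse_structure(lysozyme_pdb)
  g <- assign_ss_geometric(m)
  d <- parse_dssp(lysozyme_dssp)
  helix_ref <- d$ss_code %in% c("H", "G", "I")
  expect_gt(mean((g$ss_code == "H") == helix_ref), 0.8)
  expect_true(all(g$ss_code %in% c("H", "E", "C")))
})
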