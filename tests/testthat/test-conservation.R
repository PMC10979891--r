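test_that("column entropy matches closed forms and handles gaps", {
  expect_equal(column_entropy(c("A", "A", "A", "A")), 0)
  expect_equal(column_entropy(c("A", "A", "G", "G")), 1)
  expect_equal(column_entropy(c("A", "C", "D", "E", "F", "G", "H", "I")), 3)
  expect_equal(column_entropy(AA_20), log2(20))
  # gaps are excluded and probabilities renormalized
  expect_equal(column_entropy(c("A", "A", "-", "-")), 0)
  expect_equal(column_entropy(c("A", "G", "-", "-")), 1)
  expect_true(is.na(column_entropy(c("-", "-", "-"))))
  expect_error(column_entropy(character(0)), class = "tagsite_input_error")
})

test_that("entropy is permutation- and count-scaling-invariant", {
  set.seed(11)
  for (rep in 1:25) {
    col <- sample(c(AA_20, "-"), 12, replace = TRUE)
    expect_equal(column_entropy(sample(col)), column_entropy(col))
    expect_equal(column_entropy(rep(col, 3)), column_entropy(col))
  }
})

test_that("entropy track maps alignment columns onto query positions", {
  dir <- withr::local_tempdir()
  msa_path <- file.path(dir, "msa.fasta")
  # query has a gap in column 3: that column feeds no query position
  write_fasta(c(q = "AC-DF", h1 = "ACWDF", h2 = "ACYD-"), msa_path)
  q <- validate_sequence("ACDF", id = "q")
  msa <- read_alignment(msa_path, query_id = "q", query = q)
  expect_equal(msa$n_columns, 5L)
  tr <- entropy_track(msa)
  expect_equal(nrow(tr), 4L)
  expect_equal(tr$value, c(0, 0, 0, 0))

  # a fully variable column carries log2(3) at the matching query position
  write_fasta(c(q = "ACD", h1 = "AWD", h2 = "AYD"), msa_path)
  q2 <- validate_sequence("ACD", id = "q")
  tr2 <- entropy_track(read_alignment(msa_path, query_id = "q", query = q2))
  expect_equal(tr2$value, c(0, log2(3), 0))

  # excluding the query from the column counts is available
  tr3 <- entropy_track(read_alignment(msa_path, query_id = "q", query = q2),
                       include_query = FALSE)
  expect_equal(tr3$value, c(0, 1, 0))
})

test_that("entropy track matches a brute-force oracle on random alignments", {
  dir <- withr::local_tempdir()
  set.seed(42)
  for (rep in 1:10) {
    n_seq <- 6
    n_col <- 30
    qres <- sample(AA_20, n_col, replace = TRUE)
    rows <- c(list(q = paste(qres, collapse = "")),
              setNames(lapply(1:(n_seq - 1), function(i) {
                paste(sample(c(AA_20, "-"), n_col, replace = TRUE), collapse = "")
              }), paste0("h", 1:(n_seq - 1))))
    msa_path <- file.path(dir, "rand.fasta")
    write_fasta(unlist(rows), msa_path)
    msa <- read_alignment(msa_path, query_id = "q")
    got <- entropy_track(msa)$value
    mat <- do.call(rbind, strsplit(unlist(rows), ""))
    want <- vapply(seq_len(n_col), function(j) brute_entropy(mat[, j]), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got / log2(20) <= 1 + 1e-12, na.rm = TRUE))
  }
})

test_that("alignment reading rejects ragged input and degap mismatches", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "a.fasta")

  write_fasta(c(q = "ACDEFGHIKL", h1 = "ACDEFGHIKL", h2 = "ACDEFGHIKL"), p)
  msa <- read_alignment(p, query_id = "q")
  expect_equal(msa$n_columns, 10L)
  expect_equal(msa$query_index, 1L)

  writeLines(c(">q", "ACDEFGHIKL", ">h1", "ACDEFGHIK"), p)
  expect_error(read_alignment(p, query_id = "q"), "Ragged",
               class = "tagsite_input_error")

  write_fasta(c(q = "ACDEFGHIKL", h1 = "ACDEFGHIKL"), p)
  expect_error(read_alignment(p, query_id = "nope"), class = "tagsite_input_error")

  err <- expect_error(
    read_alignment(p, query_id = "q", query = validate_sequence("ACDWFGHIKL")),
    class = "tagsite_input_error"
  )
  expect_match(conditionMessage(err), "position 4")
})

test_that("best-hit selection is by lowest E-value with deterministic tie-breaks", {
  hits <- function(...) {
    rows <- list(...)
    tibble::tibble(
      qseqid = "q", sseqid = vapply(rows, `[[`, "", 1),
      pident = 90, length = 100, mismatch = 1, gapopen = 0,
      qstart = 1, qend = 100, sstart = 1, send = 100,
      evalue = vapply(rows, function(r) as.numeric(r[[2]]), 1),
      bitscore = vapply(rows, function(r) as.numeric(r[[3]]), 1)
    )
  }
  sel <- select_homologs(list(
    cow = hits(list("accA", 1e-50, 200), list("accB", 1e-10, 300)),
    hen = hits(list("accC", 0, 850), list("accD", 0, 900)),
    dog = hits(list("accF", 0, 500), list("accE", 0, 500))
  ))
  expect_equal(sel$accession[sel$species == "cow"], "accA")
  expect_equal(sel$accession[sel$species == "hen"], "accD")
  expect_equal(sel$accession[sel$species == "dog"], "accE")

  expect_warning(
    sel2 <- select_homologs(list(cow = hits(list("accA", 1e-50, 200)),
                                 frog = hits()[0, ])),
    "frog"
  )
  expect_equal(sel2$species, "cow")
})

test_that("BLAST tabular files parse into the 12 standard columns", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "# comment",
    paste("q", "sub1", "95.5", "100", "4", "0", "1", "100", "1", "100",
          "1e-50", "190", sep = "\t")
  ), p)
  tab <- read_blast_tab(p)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$sseqid, "sub1")
  expect_equal(tab$evalue, 1e-50)
  expect_equal(tab$bitscore, 190)
  writeLines("q\tonly_three\t1.0", p)
  expect_error(read_blast_tab(p), class = "tagsite_input_error")
})
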