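# Synthetic fixture generator: internally consistent toy inputs (query
# FASTA, aligned MSA, classic DSSP file, CA-trace PDB, ANCHOR track) with a
# planted best insertion site, so the entire pipeline can be exercised with
# no downloads and no external tools. Fixtures satisfy the format and
# geometry contracts of the real inputs but are not physically realistic
# structures.

#' Generate a synthetic fixture bundle with a planted insertion site
#'
#' Writes a full set of pipeline inputs for a toy protein in which a single
#' 7-residue window centred on `peak_position` is the only region where all
#' four features simultaneously favour tagging:
#' * the MSA is identical to the query outside the window; inside it each of
#'   the 7 homologs carries a fixed residue rotation, so every window column
#'   holds 8 distinct residues and its entropy is exactly `log2(8) = 3` bits
#'   (outside the window entropy is 0, which pins the minimum score to 0);
#' * the DSSP file assigns helix (`H`) everywhere except coil (`C`) in the
#'   window, with ACC equal to the residue maximum inside the window;
#' * the ANCHOR track has `BR ~ 0.9` everywhere except `~ 0.05` in the
#'   window;
#' * a CA-trace extended-backbone PDB is written for format-level tests.
#'
#' By construction the smoothed minimum score has its unique maximum at
#' `peak_position` (for interior peaks; at the termini the window truncates
#' but the argmax stays at the planted position). The seed drives the random
#' query sequence, record identifiers and the cosmetic jitter of
#' out-of-window values; none of these move the planted peak.
#'
#' @param length Query length (default 60).
#' @param peak_position Planted best insertion site, in `1..length`.
#' @param seed Integer seed fixing all randomness.
#' @param dir Output directory (created; default a fresh temporary
#'   directory).
#' @return A list with `dir`, `query_id`, `sequence`, `peak`, `window`
#'   (the planted positions) and `paths` (named: `query_fasta`, `msa`,
#'   `dssp`, `pdb`, `anchor`).
#' @export
make_fixture <- function(length = 60, peak_position = 30, seed = 1,
                         dir = tempfile("tagsite_fixture")) {
  if (peak_position < 1 || peak_position > length) {
    abort(sprintf("peak_position must lie in 1..%d.", length),
          class = "tagsite_input_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  aa <- AA_ALPHABET
  residues <- sample(aa, length, replace = TRUE)
  win <- intersect((peak_position - 3L):(peak_position + 3L), seq_len(length))
  query_id <- sprintf("FIXQ%04d", seed %% 10000L)

  # MSA: fixed residue rotation inside the window -> 8 distinct symbols per
  # window column, entropy exactly log2(8) bits there and 0 elsewhere
  panel <- default_species_panel()
  rows <- list()
  rows[[query_id]] <- paste(residues, collapse = "")
  for (k in seq_along(panel)) {
    r <- residues
    idx <- match(r[win], aa)
    r[win] <- aa[((idx - 1L + k) %% 20L) + 1L]
    rows[[paste0(gsub(" ", "_", panel[k]), "_", seed)]] <- paste(r, collapse = "")
  }
  paths <- c(
    query_fasta = file.path(dir, "query.fasta"),
    msa = file.path(dir, "msa.fasta"),
    dssp = file.path(dir, "toy.dssp"),
    pdb = file.path(dir, "toy.pdb"),
    anchor = file.path(dir, "anchor.txt")
  )
  write_fasta(setNames(rows[[query_id]], query_id), paths["query_fasta"])
  write_fasta(unlist(rows), paths["msa"])

  # classic-format DSSP file: coil + maximal exposure in the window
  mx <- max_sa_table()
  acc <- round(stats::runif(length, 0.10, 0.35) * mx[residues])
  acc[win] <- round(mx[residues[win]])
  ss <- rep("H", length)
  ss[win] <- "C"
  dssp_lines <- c(
    "==== synthetic fixture in classic DSSP layout (tagsite::make_fixture) ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N",
    sprintf("%5d%5d A %s  %s%s%4d", seq_len(length), seq_len(length),
            residues, ss, strrep(" ", 17), acc)
  )
  writeLines(dssp_lines, paths["dssp"])

  # ANCHOR 4-column track: binding probability low only in the window
  br <- pmin(pmax(stats::runif(length, 0.87, 0.93), 0), 1)
  br[win] <- pmin(pmax(stats::runif(base::length(win), 0.03, 0.07), 0), 1)
  iup <- stats::runif(length, 0.4, 0.9)
  anchor_lines <- c(
    "# POS\tRES\tIUPRED2\tANCHOR2",
    sprintf("%d\t%s\t%.4f\t%.4f", seq_len(length), residues, iup, br)
  )
  writeLines(anchor_lines, paths["anchor"])

  # CA-trace extended backbone; B-factor column mimics pLDDT (low = window)
  plddt <- ifelse(seq_len(length) %in% win, 50.0, 90.0)
  x <- 3.8 * seq_len(length)
  y <- 1.9 * (seq_len(length) %% 2L)
  pdb_lines <- c(
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            seq_len(length), aa1to3(residues), seq_len(length), x, y,
            rep(0, length), rep(1, length), plddt),
    "END"
  )
  writeLines(pdb_lines, paths["pdb"])

  list(dir = dir, query_id = query_id,
       sequence = rows[[query_id]], peak = peak_position, window = win,
       paths = paths)
}

aa1to3 <- function(res) {
  map <- setNames(AA3, c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  unname(map[res])
}

#' Generate fixtures for the failure paths
#'
#' Writes a set of deliberately broken inputs, each exercising one
#' validation error: a ragged alignment, an out-of-range ANCHOR score, an
#' ANCHOR residue mismatch, an unknown secondary-structure code and a
#' structure whose sequence disagrees with the query.
#'
#' @param dir Output directory (default a fresh temporary directory).
#' @return A list with `query` (a valid `query_protein` the broken inputs
#'   refer to) and `paths` (named: `ragged_msa`, `anchor_bad_range`,
#'   `anchor_mismatch`, `dssp_bad_code`, `mismatch_pdb`).
#' @export
make_degenerate_fixtures <- function(dir = tempfile("tagsite_degenerate")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  query <- validate_sequence("MHSSAKGVLD", id = "DEGQ")
  paths <- c(
    ragged_msa = file.path(dir, "ragged_msa.fasta"),
    anchor_bad_range = file.path(dir, "anchor_bad_range.txt"),
    anchor_mismatch = file.path(dir, "anchor_mismatch.txt"),
    dssp_bad_code = file.path(dir, "dssp_bad_code.dssp"),
    mismatch_pdb = file.path(dir, "mismatch.pdb")
  )
  writeLines(c(">DEGQ", query$sequence, ">other", substr(query$sequence, 1, 9)),
             paths["ragged_msa"])
  writeLines(c("# POS\tRES\tIUPRED2\tANCHOR2",
               sprintf("%d\t%s\t0.5\t%s", seq_len(query$length), query$residues,
                       ifelse(seq_len(query$length) == 3, "1.3", "0.2"))),
             paths["anchor_bad_range"])
  wrong <- query$residues
  wrong[5] <- if (wrong[5] == "A") "G" else "A"
  writeLines(c("# POS\tRES\tIUPRED2\tANCHOR2",
               sprintf("%d\t%s\t0.5\t0.2", seq_len(query$length), wrong)),
             paths["anchor_mismatch"])
  ss <- rep("H", query$length)
  ss[4] <- "Z"
  writeLines(c(
    "==== synthetic degenerate fixture in classic DSSP layout ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    sprintf("%5d%5d A %s  %s%s%4d", seq_len(query$length), seq_len(query$length),
            query$residues, ss, strrep(" ", 17), rep(50L, query$length))
  ), paths["dssp_bad_code"])
  shifted <- c(query$residues[-1], query$residues[1])
  writeLines(c(
    sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            seq_len(query$length), aa1to3(shifted), seq_len(query$length),
            3.8 * seq_len(query$length), rep(0, query$length),
            rep(0, query$length), rep(1, query$length), rep(80, query$length)),
    "END"
  ), paths["mismatch_pdb"])
  list(query = query, paths = paths)
}
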