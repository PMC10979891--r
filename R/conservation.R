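# Sequence-conservation track: per-column Shannon entropy of a multiple
# sequence alignment, mapped onto query positions.

#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @param query_id Identifier of the query record (matched as in
#'   [read_query_fasta()]).
#' @param query Optional `query_protein`; when given, the query record with
#'   gaps removed must equal the query sequence exactly.
#' @return A `protein_msa` object: a list with `records` (tibble of `label`,
#'   `sequence`), `query_index` and `n_columns`.
#' @export
read_alignment <- function(path, query_id, query = NULL) {
  seqs <- read_fasta(path)
  if (length(seqs) < 2L) {
    abort("Alignment needs at least two records.", class = "tagsite_input_error")
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    abort(
      sprintf(
        "Ragged alignment: record \"%s\" has length %d but record \"%s\" has length %d.",
        names(seqs)[1], widths[1],
        names(seqs)[which(widths != widths[1])[1]], widths[widths != widths[1]][1]
      ),
      class = "tagsite_input_error"
    )
  }
  qi <- match_fasta_record(names(seqs), query_id)
  if (is.na(qi)) {
    abort(sprintf("Query id \"%s\" not found in the alignment.", query_id),
          class = "tagsite_input_error")
  }
  msa <- structure(
    list(
      records = tibble(label = names(seqs), sequence = toupper(unname(seqs))),
      query_index = unname(qi),
      n_columns = unname(widths[1])
    ),
    class = "protein_msa"
  )
  if (!is.null(query)) {
    degapped <- gsub("-", "", msa$records$sequence[qi], fixed = TRUE)
    if (degapped != query$sequence) {
      qa <- strsplit(degapped, "")[[1]]
      qb <- query$residues
      k <- min(length(qa), length(qb))
      diffpos <- which(qa[seq_len(k)] != qb[seq_len(k)])
      first <- if (length(diffpos)) diffpos[1] else k + 1L
      abort(
        sprintf(
          "Degapped query record does not match the query sequence; first difference at position %d.",
          first
        ),
        class = "tagsite_input_error"
      )
    }
  }
  msa
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf(
    "<protein_msa> %d records x %d columns (query: %s)\n",
    nrow(x$records), x$n_columns, x$records$label[x$query_index]
  ))
  invisible(x)
}

#' Shannon entropy of one alignment column
#'
#' Computes `H = -sum_a p(a) log2 p(a)` over the amino acids observed in the
#' column. Gap characters (`-` and `.`) are excluded and the probabilities
#' renormalized over the remaining residues, so a fully conserved column has
#' `H = 0` and a uniform 20-residue column has `H = log2(20)` bits. `X`
#' counts as its own symbol. An all-gap column yields `NA`.
#'
#' @param column Character vector of single characters (one per sequence).
#' @return Entropy in bits, or `NA` for an all-gap column.
#' @examples
#' column_entropy(c("A", "A", "G", "G")) # 1 bit
#' @export
column_entropy <- function(column) {
  if (length(column) == 0L) {
    abort("Column is empty.", class = "tagsite_input_error")
  }
  chars <- toupper(column)
  chars <- chars[!chars %in% c("-", ".")]
  if (length(chars) == 0L) return(NA_real_)
  p <- as.numeric(table(chars)) / length(chars)
  -sum(p * log2(p))
}

#' Per-residue conservation entropy track
#'
#' Maps each query residue to the alignment column it occupies and computes
#' the Shannon entropy of that column in bits. Columns where the query has a
#' gap contribute to no query position.
#'
#' @param msa A `protein_msa` from [read_alignment()].
#' @param include_query Include the query sequence itself in the column
#'   distribution (default `TRUE`; it is a member of the alignment).
#' @return A `tag_track` tibble (`name = "entropy"`, unnormalized, bits).
#' @export
entropy_track <- function(msa, include_query = TRUE) {
  stopifnot(inherits(msa, "protein_msa"))
  mat <- do.call(rbind, strsplit(msa$records$sequence, ""))
  qrow <- mat[msa$query_index, ]
  use <- if (include_query) seq_len(nrow(mat)) else setdiff(seq_len(nrow(mat)), msa$query_index)
  cols <- which(!qrow %in% c("-", "."))
  h <- vapply(cols, function(j) column_entropy(mat[use, j]), numeric(1))
  feature_track("entropy", h, normalized = FALSE)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Reads the 12 standard columns of BLAST `-outfmt 6` output.
#'
#' @param path Path to a tab-separated hit table (no header). Comment lines
#'   starting with `#` are skipped.
#' @return A tibble with the standard columns (`qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`).
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(as_tibble(setNames(
      c(rep(list(character()), 2), rep(list(numeric()), 10)), cols
    )))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad)) {
    abort(sprintf("Line %d of %s has fewer than 12 tab-separated fields.", bad[1], path),
          class = "tagsite_input_error")
  }
  mat <- do.call(rbind, lapply(parts, function(p) p[1:12]))
  out <- as_tibble(setNames(as.data.frame(mat, stringsAsFactors = FALSE), cols))
  for (nm in cols[3:12]) out[[nm]] <- as.numeric(out[[nm]])
  out
}

#' Select the best homolog per species from BLAST hit tables
#'
#' For each species, keeps the single hit with the lowest E-value; ties are
#' broken by higher bit score, then by lexicographically smallest subject
#' accession, so selection is deterministic. Species with no hits are
#' dropped with a warning.
#'
#' @param hit_tables Named list of tibbles as returned by
#'   [read_blast_tab()]; names are species labels.
#' @return A tibble with columns `species`, `accession`, `evalue`,
#'   `bitscore`.
#' @export
select_homologs <- function(hit_tables) {
  stopifnot(is.list(hit_tables), !is.null(names(hit_tables)))
  rows <- lapply(names(hit_tables), function(sp) {
    ht <- hit_tables[[sp]]
    if (is.null(ht) || nrow(ht) == 0L) {
      warn(sprintf("No BLAST hits for species \"%s\"; proceeding without it.", sp))
      return(NULL)
    }
    ht <- ht[order(ht$evalue, -ht$bitscore, ht$sseqid), ]
    tibble(species = sp, accession = ht$sseqid[1],
           evalue = ht$evalue[1], bitscore = ht$bitscore[1])
  })
  bind_rows(rows)
}

#' Default vertebrate species panel for homolog selection
#'
#' Seven diverse vertebrates used by default when building the conservation
#' alignment.
#'
#' @return Character vector of species names.
#' @export
default_species_panel <- function() {
  c("Bos taurus", "Canis lupus", "Gallus gallus", "Homo sapiens",
    "Mus musculus", "Takifugu rubripes", "Xenopus tropicalis")
}
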