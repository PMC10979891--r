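# Query protein: the anchor object all feature tracks are aligned to.
# Residue positions are 1-based throughout the package.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_EXTENDED <- c(AA_ALPHABET, "X")

#' Validate a raw amino-acid sequence
#'
#' Uppercases and validates a protein sequence against the 20-letter amino
#' acid alphabet (plus `X` for unknown residues) and wraps it as a
#' `query_protein`. All downstream feature tracks use 1-based positions on
#' this sequence.
#'
#' @param raw A character scalar holding the sequence. Whitespace is stripped.
#' @param id Accession or identifier for the protein (default `"query"`).
#' @return A `query_protein` object with fields `id`, `sequence`, `length`
#'   and `residues` (a character vector of single letters).
#' @examples
#' validate_sequence("mhss")
#' @export
validate_sequence <- function(raw, id = "query") {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    abort("`raw` must be a single character string.", class = "tagsite_input_error")
  }
  seq <- toupper(gsub("\\s+", "", raw))
  if (nchar(seq) == 0L) {
    abort("Sequence is empty after whitespace stripping.", class = "tagsite_input_error")
  }
  residues <- strsplit(seq, "")[[1]]
  bad <- which(!residues %in% AA_EXTENDED)
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "Illegal character \"%s\" at position %d (alphabet is ACDEFGHIKLMNPQRSTVWY plus X).",
        residues[bad[1]], bad[1]
      ),
      class = "tagsite_input_error"
    )
  }
  structure(
    list(id = id, sequence = seq, length = length(residues), residues = residues),
    class = "query_protein"
  )
}

#' @export
print.query_protein <- function(x, ...) {
  cat(sprintf("<query_protein> %s (%d residues)\n", x$id, x$length))
  shown <- if (x$length > 60) paste0(substr(x$sequence, 1, 60), "...") else x$sequence
  cat(" ", shown, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.query_protein <- function(x, ...) {
  tibble(position = seq_len(x$length), residue = x$residues)
}

#' Read a query protein from a FASTA file
#'
#' Reads a (possibly multi-record) FASTA file and returns one record as a
#' validated [validate_sequence()] `query_protein`.
#'
#' @param path Path to a FASTA file.
#' @param id Identifier of the record to use. Defaults to the first record.
#'   Matched against the first whitespace-separated token of each header,
#'   and also against UniProt-style `db|ACC|name` headers by accession.
#' @return A `query_protein`.
#' @export
read_query_fasta <- function(path, id = NULL) {
  seqs <- read_fasta(path)
  if (length(seqs) == 0L) {
    abort(sprintf("No sequences found in %s.", path), class = "tagsite_input_error")
  }
  labels <- names(seqs)
  if (is.null(id)) {
    pick <- 1L
    id <- fasta_accession(labels[1])
  } else {
    pick <- match_fasta_record(labels, id)
    if (is.na(pick)) {
      abort(sprintf("No record with id \"%s\" in %s.", id, path), class = "tagsite_input_error")
    }
  }
  validate_sequence(unname(seqs[pick]), id = id)
}

# first token of a FASTA header; UniProt-style sp|ACC|NAME collapses to ACC
fasta_accession <- function(label) {
  token <- strsplit(label, "\\s+")[[1]][1]
  parts <- strsplit(token, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2 && parts[1] %in% c("sp", "tr")) parts[2] else token
}

match_fasta_record <- function(labels, id) {
  tokens <- vapply(labels, function(l) strsplit(l, "\\s+")[[1]][1], character(1))
  accs <- vapply(labels, fasta_accession, character(1))
  hit <- which(tokens == id | accs == id | labels == id)
  if (length(hit) == 0L) NA_integer_ else hit[1]
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readBStringSet()] that tolerates gap
#' characters (for aligned FASTA) and returns plain character sequences.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "tagsite_input_error")
  }
  set <- Biostrings::readBStringSet(path, format = "fasta")
  setNames(as.character(set), names(set))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences (names become headers).
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
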