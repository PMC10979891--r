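# Disordered-binding-region track. The disorder predictor itself (ANCHOR2,
# served by IUPred2A) is consumed as an input text track, never reimplemented.

#' Parse IUPred2A/ANCHOR2 text output
#'
#' Reads the per-residue disordered-binding-region probability (the ANCHOR2
#' score, `BR`). Two dialects are auto-detected by column count: the served
#' 4-column "long" format (position, residue, IUPred score, ANCHOR score)
#' and a minimal 2-column format (position, ANCHOR score). Comment lines
#' start with `#`.
#'
#' @param path Path to the text file.
#' @param query Optional `query_protein`; residue letters (4-column dialect)
#'   are cross-checked against it.
#' @return A tibble with `position`, `anchor` (BR, in `[0,1]`) and, for the
#'   4-column dialect, `residue` and `iupred`.
#' @export
parse_iupred2a <- function(path, query = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("ANCHOR track file not found: %s", path), class = "tagsite_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("No data lines in %s.", path), class = "tagsite_input_error")
  }
  parts <- strsplit(trimws(lines), "\\s+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1L || !ncols %in% c(2L, 4L)) {
    abort(
      sprintf("%s: expected 2 or 4 whitespace-separated columns on every line (saw %s).",
              path, paste(sort(unique(lengths(parts))), collapse = ", ")),
      class = "tagsite_input_error"
    )
  }
  mat <- do.call(rbind, parts)
  pos <- suppressWarnings(as.integer(mat[, 1]))
  if (anyNA(pos)) {
    abort(sprintf("%s: non-integer position field on line %d.", path, which(is.na(pos))[1]),
          class = "tagsite_input_error")
  }
  if (!identical(pos, seq_len(length(pos)))) {
    abort(sprintf("%s: positions must be contiguous 1..n; first irregularity at line %d.",
                  path, which(pos != seq_along(pos))[1]),
          class = "tagsite_input_error")
  }
  anchor <- suppressWarnings(as.numeric(mat[, ncols]))
  if (anyNA(anchor)) {
    abort(sprintf("%s: non-numeric ANCHOR score on line %d.", path, which(is.na(anchor))[1]),
          class = "tagsite_input_error")
  }
  bad <- which(anchor < 0 | anchor > 1)
  if (length(bad)) {
    abort(sprintf("%s: ANCHOR score %.3g at position %d is outside [0, 1].",
                  path, anchor[bad[1]], pos[bad[1]]), class = "tagsite_input_error")
  }
  out <- tibble(position = pos, anchor = anchor)
  if (ncols == 4L) {
    out$residue <- toupper(mat[, 2])
    out$iupred <- suppressWarnings(as.numeric(mat[, 3]))
    if (!is.null(query)) check_residues(out, query, "ANCHOR track")
  }
  if (!is.null(query) && nrow(out) != query$length) {
    abort(sprintf("ANCHOR track has %d positions but the query has %d residues.",
                  nrow(out), query$length), class = "tagsite_length_error")
  }
  out
}

#' Complement of the disordered-binding-region probability
#'
#' Converts the ANCHOR2 binding probability `BR` into the tagging-suitability
#' feature `1 - BR`: positions likely to mediate disordered protein-protein
#' interactions are penalized. The result is already on the `[0, 1]` scale.
#'
#' @param track Tibble from [parse_iupred2a()] (or any tibble with
#'   `position` and `anchor` columns), or a bare numeric vector of BR values.
#' @return A normalized `tag_track` (`dbr_complement`).
#' @export
dbr_complement_track <- function(track) {
  br <- if (is.numeric(track)) track else {
    stopifnot(all(c("position", "anchor") %in% names(track)))
    track$anchor[order(track$position)]
  }
  if (any(br < 0 | br > 1, na.rm = TRUE)) {
    abort("BR values must lie in [0, 1].", class = "tagsite_input_error")
  }
  feature_track("dbr_complement", 1 - br, normalized = TRUE)
}
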