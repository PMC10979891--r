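# Feature tracks: per-residue score vectors aligned to the query.
# A track is a tibble with columns `position` and `value`, plus attributes
# `track` (name) and `normalized`. Missing data is an explicit NA, never a
# silent zero.

TRACK_NAMES <- c("entropy", "secondary_structure", "rsa", "dbr_complement")

#' Construct a per-residue feature track
#'
#' @param name One of `"entropy"`, `"secondary_structure"`, `"rsa"`,
#'   `"dbr_complement"`.
#' @param values Numeric vector, one value per query residue. `NA` marks
#'   missing data.
#' @param normalized Logical; when `TRUE` every non-missing value must lie
#'   in `[0, 1]`.
#' @return A tibble of class `tag_track` with columns `position`, `value`.
#' @export
feature_track <- function(name, values, normalized = TRUE) {
  name <- match.arg(name, TRACK_NAMES)
  if (!is.numeric(values) || length(values) == 0L) {
    abort("`values` must be a non-empty numeric vector.", class = "tagsite_input_error")
  }
  values <- as.numeric(values)
  if (normalized) {
    ok <- is.na(values) | (values >= -1e-9 & values <= 1 + 1e-9)
    if (!all(ok)) {
      abort(
        sprintf(
          "Normalized track \"%s\" has value %.4g outside [0, 1] at position %d.",
          name, values[which(!ok)[1]], which(!ok)[1]
        ),
        class = "tagsite_input_error"
      )
    }
    values <- pmin(pmax(values, 0), 1)
  }
  out <- tibble(position = seq_along(values), value = values)
  attr(out, "track") <- name
  attr(out, "normalized") <- isTRUE(normalized)
  class(out) <- c("tag_track", class(out))
  out
}

track_name <- function(x) attr(x, "track", exact = TRUE)

track_normalized <- function(x) isTRUE(attr(x, "normalized", exact = TRUE))

# Accept either a tag_track tibble or a bare numeric vector.
track_values <- function(x, n = NULL, what = "track") {
  v <- if (inherits(x, "data.frame")) {
    if (!all(c("position", "value") %in% names(x))) {
      abort(sprintf("%s must have columns `position` and `value`.", what),
            class = "tagsite_input_error")
    }
    x$value[order(x$position)]
  } else {
    as.numeric(x)
  }
  if (!is.null(n) && length(v) != n) {
    abort(
      sprintf("%s has %d values but the query has %d residues.", what, length(v), n),
      class = "tagsite_length_error"
    )
  }
  v
}
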