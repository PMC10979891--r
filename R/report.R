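# Report writers and the command-line entry point.

REPORT_PRECISION <- 6L

#' Write the per-residue and ranked-site reports
#'
#' Writes three text files into `dir`:
#' * `residue_scores.tsv` — one row per query residue with the raw and
#'   normalized feature values, the weighted sum score, the minimum tagging
#'   score and its smoothed version (numbers at 6 decimals; positions are
#'   1-based, and a reported site means "tag inserted immediately after this
#'   residue");
#' * `ranked_sites.tsv` — one row per reported site;
#' * `manifest.txt` — flat `key: value` run manifest (inputs with MD5
#'   checksums, parameters, package version).
#'
#' @param profile A `score_profile` (from [predict_tag_sites()] /
#'   [run_pipeline()], so the raw DSSP/SASA/BR columns are present).
#' @param sites A `site_ranking`.
#' @param dir Output directory (created if needed).
#' @param inputs Optional named character vector of input file paths to
#'   checksum into the manifest.
#' @param extra Optional named character vector of additional manifest
#'   entries.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(profile, sites, dir, inputs = character(), extra = character()) {
  stopifnot(inherits(profile, "score_profile"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.*f", REPORT_PRECISION, x))
  sc <- profile$scores
  res_tab <- tibble(
    position = sc$position,
    residue = sc$residue,
    entropy_bits = fmt(sc[["entropy_bits"]] %||% rep(NA_real_, nrow(sc))),
    entropy_norm = fmt(sc$entropy_norm),
    ss_code = sc[["ss_code"]] %||% rep(NA_character_, nrow(sc)),
    ss_score = fmt(sc$ss_score),
    sasa = fmt(sc[["sasa"]] %||% rep(NA_real_, nrow(sc))),
    rsa = fmt(sc$rsa),
    br = fmt(sc[["br"]] %||% rep(NA_real_, nrow(sc))),
    dbr_complement = fmt(sc$dbr_complement),
    sum_score = fmt(sc$sum_score),
    min_score = fmt(sc$min_score),
    min_score_smoothed = fmt(sc$min_score_smoothed)
  )
  residue_path <- file.path(dir, "residue_scores.tsv")
  hdr <- c(
    "# per-residue tagging suitability scores",
    "# positions are 1-based; a candidate site at position i means the tag is inserted immediately after residue i"
  )
  writeLines(hdr, residue_path)
  suppressMessages(readr::write_tsv(res_tab, residue_path, append = TRUE, col_names = TRUE))

  sites_path <- file.path(dir, "ranked_sites.tsv")
  st <- as_tibble(sites)
  for (nm in c("score", "entropy_norm", "ss_score", "rsa", "dbr_complement")) {
    st[[nm]] <- fmt(st[[nm]])
  }
  writeLines(hdr, sites_path)
  suppressMessages(readr::write_tsv(st, sites_path, append = TRUE, col_names = TRUE))

  manifest_path <- file.path(dir, "manifest.txt")
  w <- unclass(profile$weights)
  lines <- c(
    paste0("tool: tagsite ", as.character(packageVersion("tagsite"))),
    paste0("query_id: ", profile$query$id),
    paste0("query_length: ", profile$query$length),
    paste0("window: ", profile$window),
    paste0("smooth_features: ", isTRUE(profile$smooth_features)),
    paste0("weights: ", paste(sprintf("%s=%g", names(w), w), collapse = " ")),
    paste0("generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  )
  if (length(inputs)) {
    sums <- tools::md5sum(inputs[file.exists(inputs)])
    lines <- c(lines, sprintf("input_%s: %s md5=%s", names(inputs), inputs,
                              unname(sums[inputs])))
  }
  if (length(extra)) lines <- c(lines, sprintf("%s: %s", names(extra), extra))
  writeLines(lines, manifest_path)

  invisible(c(residue_scores = residue_path, ranked_sites = sites_path,
              manifest = manifest_path))
}

#' Read back a per-residue score report
#'
#' @param path Path to a `residue_scores.tsv` written by [write_report()].
#' @return A tibble with numeric score columns.
#' @export
read_residue_scores <- function(path) {
  suppressMessages(readr::read_tsv(path, comment = "#", na = "NA",
                                   show_col_types = FALSE))
}

#' Write ranked sites as protein-coordinate BED intervals
#'
#' BED uses 0-based half-open coordinates, so a site at 1-based residue
#' position `p` becomes the interval `[p-1, p)`. The name field carries the
#' rank and the BED score is `round(1000 * smoothed min score)`.
#'
#' @param sites A `site_ranking`.
#' @param query_id Sequence name for the first BED column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, query_id, path) {
  lines <- "# protein-coordinate BED (0-based half-open); 1-based residue p -> [p-1, p)"
  if (nrow(sites)) {
    lines <- c(lines, sprintf(
      "%s\t%d\t%d\t%s\t%d",
      query_id, sites$position - 1L, sites$position,
      paste0("rank", sites$rank), as.integer(round(1000 * sites$score))
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Command-line entry point
#'
#' Parses arguments, runs the offline pipeline and writes the reports.
#' Intended to be called from the thin wrapper script shipped in
#' `inst/scripts/tagsite.R`; returns instead of quitting so it is testable.
#'
#' Exit codes: 0 on success, 2 on configuration errors (bad flags, missing
#' inputs), 1 on runtime failures.
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit code, invisibly.
#' @export
cli_score <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--query", type = "character", help = "query FASTA file"),
    optparse::make_option("--query-id", type = "character", default = NULL,
                          dest = "query_id", help = "record id of the query inside --query"),
    optparse::make_option("--msa", type = "character", help = "aligned FASTA with homologs"),
    optparse::make_option("--dssp", type = "character", default = NULL,
                          help = "classic DSSP output file (reference structural path)"),
    optparse::make_option("--structure", type = "character", default = NULL,
                          help = "PDB/mmCIF structure (internal fallback path)"),
    optparse::make_option("--chain", type = "character", default = NULL),
    optparse::make_option("--anchor", type = "character",
                          help = "IUPred2A/ANCHOR2 text track"),
    optparse::make_option("--weights", type = "character", default = "1.5,1,1,1",
                          help = "comma-separated weights: entropy,ss,rsa,dbr [default %default]"),
    optparse::make_option("--window", type = "integer", default = 7,
                          help = "odd smoothing window [default %default]"),
    optparse::make_option("--top-k", type = "integer", default = 5, dest = "top_k"),
    optparse::make_option("--min-separation", type = "integer", default = 8,
                          dest = "min_separation"),
    optparse::make_option("--out-dir", type = "character", default = "tagsite_out",
                          dest = "out_dir"),
    optparse::make_option("--bed", action = "store_true", default = FALSE,
                          help = "also write ranked sites as protein-coordinate BED")
  )
  parser <- optparse::OptionParser(option_list = spec, prog = "tagsite")
  code <- tryCatch({
    opt <- optparse::parse_args(parser, args = args)
    if (is.null(opt$query) || is.null(opt$msa) || is.null(opt$anchor)) {
      abort("--query, --msa and --anchor are required.", class = "tagsite_config_error")
    }
    if (opt$window %% 2 != 1 || opt$window < 1) {
      abort("--window must be an odd positive integer.", class = "tagsite_config_error")
    }
    w <- suppressWarnings(as.numeric(strsplit(opt$weights, ",")[[1]]))
    if (length(w) != 4 || anyNA(w)) {
      abort("--weights must be four comma-separated numbers.", class = "tagsite_config_error")
    }
    config <- pipeline_config(
      query_fasta = opt$query, msa = opt$msa, anchor = opt$anchor,
      dssp = opt$dssp, structure = opt$structure, chain = opt$chain,
      query_id = opt$query_id,
      weights = tag_weights(w[1], w[2], w[3], w[4]),
      window = opt$window, top_k = opt$top_k,
      min_separation = opt$min_separation, out_dir = opt$out_dir
    )
    res <- run_pipeline(config)
    inputs <- c(query = opt$query, msa = opt$msa, anchor = opt$anchor)
    if (!is.null(opt$dssp)) inputs <- c(inputs, dssp = opt$dssp)
    if (!is.null(opt$structure)) inputs <- c(inputs, structure = opt$structure)
    paths <- write_report(res$profile, res$sites, opt$out_dir, inputs = inputs,
                          extra = c(structure_path = res$structure_path))
    if (isTRUE(opt$bed)) {
      write_bed(res$sites, res$profile$query$id,
                file.path(opt$out_dir, "ranked_sites.bed"))
    }
    top <- utils::head(res$sites, 3)
    inform(sprintf("top sites: %s",
                   paste(sprintf("%s%d (%.3f)", top$residue, top$position, top$score),
                         collapse = ", ")))
    0L
  },
  tagsite_config_error = function(e) {
    message("config error: ", conditionMessage(e))
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
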