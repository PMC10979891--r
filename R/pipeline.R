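# End-to-end orchestration: from input files to a score profile and ranked
# insertion sites. The file-based path needs no network and no external
# executables.

#' Score a protein and rank tag-insertion sites from parsed inputs
#'
#' High-level wrapper combining the four feature tracks into a profile and
#' ranking candidate sites.
#'
#' @param query A `query_protein`.
#' @param msa A `protein_msa` containing the query.
#' @param dssp Optional tibble from [parse_dssp()] (the reference path for
#'   secondary structure and SASA).
#' @param structure Optional `structure_model`; used when `dssp` is absent
#'   (internal Shrake-Rupley SASA and geometric secondary structure, labelled
#'   non-reference). One of `dssp`/`structure` is required; `dssp` wins when
#'   both are given.
#' @param anchor Tibble from [parse_iupred2a()].
#' @param weights A [tag_weights()] vector.
#' @param window Odd smoothing window (default 7).
#' @param top_k,min_separation Passed to [rank_sites()].
#' @param smooth_features Passed to [build_profile()].
#' @return A list with `profile` (a `score_profile`), `sites` (a
#'   `site_ranking`) and `structure_path` (`"dssp"` or `"internal"`).
#' @export
predict_tag_sites <- function(query, msa, dssp = NULL, structure = NULL,
                              anchor, weights = tag_weights(), window = 7,
                              top_k = 5, min_separation = 8,
                              smooth_features = FALSE) {
  stopifnot(inherits(query, "query_protein"))
  ent <- entropy_track(msa)
  if (!is.null(dssp)) {
    ss <- ss_track(dssp, query)
    rsa <- rsa_track(dssp, query)
    used <- "dssp"
  } else if (!is.null(structure)) {
    model <- map_structure_to_query(structure, query)
    inform("No DSSP file supplied: using internal Shrake-Rupley SASA and geometric secondary structure (non-reference).")
    sasa <- shrake_rupley_sasa(model)
    sasa$position <- model$residues$query_position
    ssrec <- assign_ss_geometric(model)
    ssrec$position <- model$residues$query_position
    ss <- ss_track(ssrec, query)
    rsa <- rsa_track(sasa, query)
    used <- "internal"
  } else {
    abort("Supply either a parsed DSSP table or a structure model.",
          class = "tagsite_config_error")
  }
  dbr <- dbr_complement_track(anchor)
  if (nrow(anchor) != query$length) {
    abort(sprintf("ANCHOR track length %d does not match query length %d.",
                  nrow(anchor), query$length), class = "tagsite_length_error")
  }
  profile <- build_profile(query, ent, ss, rsa, dbr, weights = weights,
                           window = window, smooth_features = smooth_features)
  # carry raw per-residue inputs for reporting
  raw <- if (!is.null(dssp)) dssp else {
    tibble(position = sasa$position, ss_code = ssrec$ss_code, sasa = sasa$sasa)
  }
  profile$scores$entropy_bits <- track_values(ent, query$length, "entropy")
  profile$scores$ss_code <- NA_character_
  profile$scores$ss_code[raw$position] <- raw$ss_code
  profile$scores$sasa <- NA_real_
  profile$scores$sasa[raw$position] <- raw$sasa
  profile$scores$br <- anchor$anchor[order(anchor$position)]
  sites <- rank_sites(profile, top_k = top_k, min_separation = min_separation)
  list(profile = profile, sites = sites, structure_path = used)
}

#' Run the full scoring pipeline from a configuration
#'
#' Executes the offline, file-based pipeline described by a
#' [pipeline_config()]: read the query, the alignment, the structural
#' features (DSSP file or structure model) and the ANCHOR track, score every
#' position and rank candidate insertion sites.
#'
#' @param config A `pipeline_config` (or a path to a YAML config file).
#' @return A list with `profile`, `sites`, `structure_path` and `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  query <- read_query_fasta(config$query_fasta, id = config$query_id)
  msa <- read_alignment(config$msa, query_id = query$id, query = query)
  dssp <- if (!is.null(config$dssp)) parse_dssp(config$dssp) else NULL
  model <- if (is.null(dssp) && !is.null(config$structure)) {
    parse_structure(config$structure, chain = config$chain)
  } else NULL
  anchor <- parse_iupred2a(config$anchor, query = query)
  res <- predict_tag_sites(
    query, msa, dssp = dssp, structure = model, anchor = anchor,
    weights = config$weights, window = config$window,
    top_k = config$top_k, min_separation = config$min_separation,
    smooth_features = isTRUE(config$smooth_features)
  )
  res$config <- config
  res
}
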