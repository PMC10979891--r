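# Optional online fetchers and external-tool orchestration. Everything here
# is opt-in: the default mode is strictly offline and file-based, and every
# fetched object is cached to a file that the offline path consumes.

#' Build a pipeline configuration
#'
#' Collects every input path and tuning parameter of the scoring pipeline.
#' The default configuration is strictly offline: no network fetches and no
#' external executables.
#'
#' @param query_fasta Path to the query FASTA file.
#' @param msa Path to the aligned FASTA multiple sequence alignment.
#' @param anchor Path to the IUPred2A/ANCHOR2 text track.
#' @param dssp Optional path to a classic DSSP output file (reference path
#'   for secondary structure and SASA).
#' @param structure Optional path to a PDB/mmCIF structure (internal
#'   fallback path when no DSSP file is given).
#' @param chain Optional chain selector for multi-chain structures.
#' @param query_id Optional record id of the query inside `query_fasta`.
#' @param accession Optional UniProt accession (used by the fetchers).
#' @param species Species panel for homolog selection (default
#'   [default_species_panel()]).
#' @param weights A [tag_weights()] vector.
#' @param window Odd smoothing window width (default 7).
#' @param top_k,min_separation Site-ranking parameters.
#' @param smooth_features Smooth features before the minimum (default FALSE).
#' @param online Allow network fetches (default FALSE).
#' @param tools Named list of external executables, e.g.
#'   `list(blast = "blastp", aligner = "muscle", dssp = "mkdssp")`; an empty
#'   list disables all external tools.
#' @param cache_dir Directory for fetched files (default `tempdir()`).
#' @param out_dir Directory for reports.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(query_fasta = NULL, msa = NULL, anchor = NULL,
                            dssp = NULL, structure = NULL, chain = NULL,
                            query_id = NULL, accession = NULL,
                            species = default_species_panel(),
                            weights = tag_weights(), window = 7,
                            top_k = 5, min_separation = 8,
                            smooth_features = FALSE,
                            online = FALSE, tools = list(),
                            cache_dir = tempdir(), out_dir = NULL) {
  structure(
    list(query_fasta = query_fasta, msa = msa, anchor = anchor, dssp = dssp,
         structure = structure, chain = chain, query_id = query_id,
         accession = accession, species = species, weights = weights,
         window = window, top_k = top_k, min_separation = min_separation,
         smooth_features = smooth_features, online = online, tools = tools,
         cache_dir = cache_dir, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [pipeline_config()]. `weights` may be a named mapping
#'   (`entropy`, `secondary_structure`, `rsa`, `dbr_complement`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "tagsite_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$weights)) raw$weights <- do.call(tag_weights, raw$weights)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "tagsite_config_error")
  }
  do.call(pipeline_config, raw)
}

validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!inherits(config$weights, "tag_weights")) {
    config$weights <- do.call(tag_weights, as.list(config$weights))
  }
  if (config$window %% 2 != 1 || config$window < 1) {
    abort("Config: `window` must be an odd positive integer.",
          class = "tagsite_config_error")
  }
  need <- function(field, stage) {
    val <- config[[field]]
    if (is.null(val)) {
      abort(sprintf(
        "Config: stage \"%s\" has no input; supply `%s` (offline) or enable a fetcher.",
        stage, field
      ), class = "tagsite_config_error")
    }
    if (!file.exists(val)) {
      abort(sprintf("Config: stage \"%s\": file not found: %s", stage, val),
            class = "tagsite_config_error")
    }
  }
  need("query_fasta", "query sequence")
  need("msa", "conservation alignment")
  if (is.null(config$dssp) && is.null(config$structure)) {
    abort("Config: stage \"structure features\" has no input; supply `dssp` or `structure`.",
          class = "tagsite_config_error")
  }
  if (!is.null(config$dssp)) need("dssp", "structure features") else need("structure", "structure features")
  need("anchor", "disorder track")
  config
}

UNIPROT_ACC_RE <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"

#' Fetch a UniProt sequence to a cached FASTA file
#'
#' Opt-in network fetcher. The accession is validated before any network
#' activity; a cache hit returns the file without touching the network.
#'
#' @param accession UniProt accession (e.g. `"Q9W7E7"`).
#' @param cache_dir Cache directory.
#' @param online Must be `TRUE` to allow a network call.
#' @return Path to the cached FASTA file.
#' @export
fetch_uniprot_sequence <- function(accession, cache_dir = tempdir(), online = FALSE) {
  if (!grepl(UNIPROT_ACC_RE, accession)) {
    abort(sprintf("\"%s\" is not a well-formed UniProt accession.", accession),
          class = "tagsite_config_error")
  }
  dest <- file.path(cache_dir, paste0("uniprot_", accession, ".fasta"))
  if (file.exists(dest)) {
    inform(sprintf("cache hit: %s", dest))
    return(dest)
  }
  if (!isTRUE(online)) {
    abort(sprintf(
      "Offline mode: sequence for %s is not cached; supply `query_fasta` as a local file or set online = TRUE.",
      accession
    ), class = "tagsite_config_error")
  }
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", accession)
  fetch_url(url, dest, sprintf("UniProt sequence %s", accession))
}

#' Fetch an AlphaFold model structure to a cached PDB file
#'
#' Opt-in network fetcher for the AlphaFold database model of an accession.
#'
#' @inheritParams fetch_uniprot_sequence
#' @return Path to the cached PDB file.
#' @export
fetch_alphafold_structure <- function(accession, cache_dir = tempdir(), online = FALSE) {
  if (!grepl(UNIPROT_ACC_RE, accession)) {
    abort(sprintf("\"%s\" is not a well-formed UniProt accession.", accession),
          class = "tagsite_config_error")
  }
  dest <- file.path(cache_dir, paste0("alphafold_", accession, ".pdb"))
  if (file.exists(dest)) {
    inform(sprintf("cache hit: %s", dest))
    return(dest)
  }
  if (!isTRUE(online)) {
    abort(sprintf(
      "Offline mode: AlphaFold model for %s is not cached; supply `structure` (or `dssp`) as a local file or set online = TRUE.",
      accession
    ), class = "tagsite_config_error")
  }
  url <- sprintf("https://alphafold.ebi.ac.uk/files/AF-%s-F1-model_v4.pdb", accession)
  fetch_url(url, dest, sprintf("AlphaFold model %s (no model may exist for this accession; a local structure file also works)", accession))
}

fetch_url <- function(url, dest, what, retries = 3) {
  for (k in seq_len(retries)) {
    activity_bump("network_calls")
    ok <- tryCatch({
      utils::download.file(url, dest, quiet = TRUE, mode = "wb")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (ok && file.exists(dest) && file.size(dest) > 0) {
      inform(sprintf("fetched %s -> %s (md5 %s)", what, dest,
                     unname(tools::md5sum(dest))))
      return(dest)
    }
    if (k < retries) Sys.sleep(2^k)
  }
  unlink(dest)
  abort(sprintf("Failed to fetch %s after %d attempts (%s).", what, retries, url),
        class = "tagsite_runtime_error")
}

#' Run an external tool (BLAST, aligner, DSSP) with logging
#'
#' Thin orchestration boundary around `system2()`. The executable and all
#' inputs must exist before the call; declared outputs must exist and be
#' non-empty afterwards. The full command line and exit status are logged.
#' Every stage wrapped here can be bypassed by supplying its output as a
#' file, so offline operation is always possible.
#'
#' @param tool Label for the stage (`"blast"`, `"aligner"`, `"dssp"`, ...).
#' @param exe Executable name or path.
#' @param args Character vector of arguments.
#' @param inputs Character vector of input files that must exist.
#' @param outputs Character vector of output files that must exist
#'   afterwards.
#' @param stdout Optional file to capture standard output into (also treated
#'   as an output).
#' @return Invisibly, the declared output paths.
#' @export
run_external <- function(tool, exe, args = character(), inputs = character(),
                         outputs = character(), stdout = NULL) {
  path <- Sys.which(exe)
  if (!nzchar(path)) {
    abort(sprintf(
      "Stage \"%s\": executable \"%s\" not found; supply this stage's output as a file to bypass it.",
      tool, exe
    ), class = "tagsite_config_error")
  }
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    abort(sprintf("Stage \"%s\": missing input file(s): %s", tool,
                  paste(missing, collapse = ", ")), class = "tagsite_config_error")
  }
  activity_bump("external_calls")
  t0 <- Sys.time()
  err <- tempfile("stderr")
  status <- suppressWarnings(system2(
    path, args,
    stdout = if (is.null(stdout)) FALSE else stdout,
    stderr = err
  ))
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  inform(sprintf("[%s] %s %s (exit %d, %.1fs)", tool, path,
                 paste(args, collapse = " "), status, elapsed))
  if (status != 0L) {
    abort(sprintf("Stage \"%s\" failed with exit status %d: %s", tool, status,
                  paste(readLines(err, warn = FALSE), collapse = "\n")),
          class = "tagsite_runtime_error")
  }
  outs <- c(outputs, stdout)
  bad <- outs[!file.exists(outs) | file.size(outs) == 0]
  if (length(bad)) {
    abort(sprintf("Stage \"%s\": declared output missing or empty: %s", tool,
                  paste(bad, collapse = ", ")), class = "tagsite_runtime_error")
  }
  invisible(outs)
}
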