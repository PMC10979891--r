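# Structure-derived tracks: secondary structure and relative solvent
# accessibility. The reference path parses external DSSP output; an internal
# deterministic Shrake-Rupley SASA (and a coarse geometric secondary-structure
# assignment) is available as a fallback so the pipeline can run with zero
# external binaries.

DSSP_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "P", "C")

#' Theoretical maximum solvent accessibility per residue
#'
#' Returns the Tien et al. (2013) theoretical maximum accessible surface
#' areas (Gly-X-Gly context, in square Angstrom) used to normalize SASA to
#' relative solvent accessibility. Shipped as a tab-separated data file with
#' a provenance note.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
max_sa_table <- function() {
  path <- system.file("extdata", "max_sa_tien2013.tsv", package = "tagsite", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("residue", "max_sa") %in% names(df)), nrow(df) == 20, all(df$max_sa > 0))
  setNames(df$max_sa, df$residue)
}

#' Parse a protein structure file (PDB or mmCIF)
#'
#' Reads atomic coordinates and per-residue metadata. For AlphaFold model
#' files the B-factor column holds the per-residue pLDDT confidence (0-100)
#' and is carried through as `plddt`.
#'
#' @param path Path to a `.pdb`, `.cif` or `.mmcif` file.
#' @param chain Chain identifier to keep. Required when the file contains
#'   more than one polypeptide chain.
#' @return A `structure_model`: list with `atoms` (tibble: `elety`, `resno`,
#'   `residue`, `chain`, `x`, `y`, `z`, `element`, `b`), `residues` (tibble:
#'   `position`, `resno`, `residue`, `plddt`) and `source` (the file path).
#' @export
parse_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("Structure file not found: %s", path), class = "tagsite_input_error")
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) abort(
      sprintf("Could not parse structure file %s: %s", path, conditionMessage(e)),
      class = "tagsite_input_error"
    )
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    abort(sprintf("No protein (ATOM) residues in %s.", path), class = "tagsite_input_error")
  }
  chains <- unique(at$chain)
  if (length(chains) > 1L) {
    if (is.null(chain)) {
      abort(
        sprintf("File has chains %s; supply `chain` to select one.",
                paste(chains, collapse = ", ")),
        class = "tagsite_input_error"
      )
    }
    at <- at[at$chain == chain, , drop = FALSE]
    if (nrow(at) == 0L) {
      abort(sprintf("Chain \"%s\" not found (chains: %s).", chain,
                    paste(chains, collapse = ", ")), class = "tagsite_input_error")
    }
  }
  element <- toupper(trimws(if ("elesy" %in% names(at)) at$elesy else ""))
  guess <- toupper(substr(trimws(at$elety), 1, 1))
  element <- ifelse(is.na(element) | element == "", guess, element)
  atoms <- tibble(
    elety = trimws(at$elety),
    resno = at$resno,
    residue = aa3to1(at$resid),
    chain = at$chain,
    x = at$x, y = at$y, z = at$z,
    element = element,
    b = at$b
  )
  resno <- unique(atoms$resno)
  residues <- tibble(
    position = seq_along(resno),
    resno = resno,
    residue = vapply(resno, function(r) atoms$residue[atoms$resno == r][1], character(1)),
    plddt = vapply(resno, function(r) {
      ca <- atoms$b[atoms$resno == r & atoms$elety == "CA"]
      if (length(ca)) ca[1] else mean(atoms$b[atoms$resno == r])
    }, numeric(1))
  )
  structure(list(atoms = atoms, residues = residues, source = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residues, %d atoms (%s)\n",
              nrow(x$residues), nrow(x$atoms), x$source))
  invisible(x)
}

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU", "GLN", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

aa3to1 <- function(resid) {
  map <- setNames(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"), AA3)
  out <- unname(map[toupper(resid)])
  out[is.na(out)] <- "X"
  out
}

#' Map structure residues onto query positions
#'
#' Residues are matched to query positions by order, using the author residue
#' number when it is a plausible 1-based index, and checked for identity.
#' Query positions absent from the structure receive missing feature values
#' downstream; they are never imputed.
#'
#' @param model A `structure_model`.
#' @param query A `query_protein`.
#' @return The `model` with a `query_position` column added to `residues`.
#' @export
map_structure_to_query <- function(model, query) {
  stopifnot(inherits(model, "structure_model"), inherits(query, "query_protein"))
  res <- model$residues
  # prefer author numbering when it indexes the query consistently
  use_resno <- all(res$resno >= 1) && all(res$resno <= query$length) &&
    !anyDuplicated(res$resno)
  pos <- if (use_resno) res$resno else seq_len(nrow(res))
  if (max(pos) > query$length) {
    abort(sprintf("Structure has %d residues but the query only %d.",
                  nrow(res), query$length), class = "tagsite_input_error")
  }
  mism <- which(res$residue != query$residues[pos] & res$residue != "X" &
                  query$residues[pos] != "X")
  if (length(mism)) {
    i <- mism[1]
    abort(
      sprintf(
        "Structure residue %s at query position %d does not match query residue %s.",
        res$residue[i], pos[i], query$residues[pos[i]]
      ),
      class = "tagsite_input_error"
    )
  }
  model$residues$query_position <- pos
  model
}

# van der Waals radii (A) by element; matches common SASA implementations
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(element) {
  r <- unname(VDW_RADII[toupper(element)])
  unknown <- is.na(r)
  if (any(unknown)) {
    warn(sprintf("Unknown element(s) %s; using default van der Waals radius 1.70 A.",
                 paste(unique(element[unknown]), collapse = ", ")))
    r[unknown] <- 1.70
  }
  r
}

# deterministic quasi-uniform points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Deterministic Shrake-Rupley SASA: each atom is surrounded by a fixed
#' golden-angle lattice of test points on its solvent-expanded sphere
#' (van der Waals radius + probe); points falling inside any neighbouring
#' atom's expanded sphere are occluded. No random number generation is
#' involved, so results are exactly reproducible for a given `n_points`.
#'
#' @param model A `structure_model`.
#' @param n_points Number of sphere test points per atom (default 960).
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @return A tibble with `position` (structure residue index), `resno`,
#'   `residue` and `sasa` (square Angstrom).
#' @export
shrake_rupley_sasa <- function(model, n_points = 960, probe = 1.4) {
  stopifnot(inherits(model, "structure_model"), n_points >= 12, probe >= 0)
  atoms <- model$atoms
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (any(!is.finite(xyz))) {
    abort("Structure has non-finite coordinates.", class = "tagsite_input_error")
  }
  rad <- vdw_radius(atoms$element) + probe
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  maxr <- max(rad)
  area <- numeric(n)
  # neighbour lists from the full distance matrix, chunked to bound memory
  chunk <- max(1L, floor(2e7 / n))
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(xyz[idx, 1], xyz[, 1], "-")^2 +
      outer(xyz[idx, 2], xyz[, 2], "-")^2 +
      outer(xyz[idx, 3], xyz[, 3], "-")^2
    for (k in seq_along(idx)) {
      i <- idx[k]
      cut2 <- (rad[i] + rad)^2
      nb <- which(d2[k, ] < cut2)
      nb <- nb[nb != i]
      sp <- pts * rad[i]
      sp <- cbind(sp[, 1] + xyz[i, 1], sp[, 2] + xyz[i, 2], sp[, 3] + xyz[i, 3])
      acc <- rep(TRUE, n_points)
      if (length(nb)) {
        nb <- nb[order(d2[k, nb])]
        for (j in nb) {
          dj <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 + (sp[, 3] - xyz[j, 3])^2
          acc <- acc & (dj > rad[j]^2)
          if (!any(acc)) break
        }
      }
      area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
    }
  }
  agg <- tapply(area, factor(atoms$resno, levels = unique(atoms$resno)), sum)
  tibble(
    position = seq_along(agg),
    resno = unique(atoms$resno),
    residue = model$residues$residue,
    sasa = as.numeric(agg)
  )
}

#' Parse classic DSSP output
#'
#' Reads the fixed-column residue records of a classic DSSP file: residue
#' number, amino acid, secondary-structure code and the ACC (solvent
#' accessibility, square Angstrom) field. Chain-break records (`!`) are
#' skipped; a blank or `-` structure code is canonicalized to `"C"` (coil);
#' lowercase amino-acid letters (cystine bridges) become `C` (cysteine).
#'
#' @param path Path to a DSSP output file.
#' @return A tibble with `position` (residue number from the file),
#'   `residue`, `ss_code` and `sasa`.
#' @export
parse_dssp <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("DSSP file not found: %s", path), class = "tagsite_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) {
    abort(sprintf("Malformed DSSP file %s: residue-table header not found.", path),
          class = "tagsite_input_error")
  }
  body <- lines[(hdr[1] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  aa <- aa[keep]
  if (length(body) == 0L) {
    abort(sprintf("DSSP file %s has no residue lines.", path),
          class = "tagsite_input_error")
  }
  resnum <- suppressWarnings(as.integer(substr(body, 6, 10)))
  if (anyNA(resnum)) {
    abort(sprintf("DSSP file %s: unparseable residue number on line %d of the table.",
                  path, which(is.na(resnum))[1]), class = "tagsite_input_error")
  }
  ss <- substr(body, 17, 17)
  ss[ss %in% c(" ", "", "-")] <- "C"
  aa[aa %in% letters] <- "C"
  sasa <- suppressWarnings(as.numeric(substr(body, 35, 38)))
  if (anyNA(sasa)) {
    abort(sprintf("DSSP file %s: unparseable ACC field on line %d of the table.",
                  path, which(is.na(sasa))[1]), class = "tagsite_input_error")
  }
  if (any(sasa < 0)) {
    abort(sprintf("DSSP file %s: negative ACC value at residue %d.",
                  path, resnum[which(sasa < 0)[1]]), class = "tagsite_input_error")
  }
  tibble(position = resnum, residue = toupper(aa), ss_code = ss, sasa = sasa)
}

#' Bin DSSP secondary-structure codes into tag-sensitivity scores
#'
#' Defined structural elements (`G`, `H`, `I` helices and `E` strand) are
#' expected to be sensitive to an inserted tag and score 0; unassigned coil
#' (`C`, including blank and `-`) scores 1; everything else (`B`, `T`, `S`
#' and the newer polyproline `P` code) scores 0.5.
#'
#' @param codes Character vector of single DSSP codes.
#' @return Numeric vector with values in `{0, 0.5, 1}`.
#' @export
ss_score <- function(codes) {
  codes <- as.character(codes)
  codes[codes %in% c(" ", "", "-")] <- "C"
  bad <- which(!codes %in% DSSP_ALPHABET & !is.na(codes))
  if (length(bad)) {
    abort(sprintf("Unknown secondary-structure code \"%s\" at position %d.",
                  codes[bad[1]], bad[1]), class = "tagsite_input_error")
  }
  out <- rep(0.5, length(codes))
  out[codes == "C"] <- 1
  out[codes %in% c("G", "H", "I", "E")] <- 0
  out[is.na(codes)] <- NA_real_
  out
}

#' Secondary-structure feature track
#'
#' Aligns DSSP records to the query and bins the codes with [ss_score()].
#' Query positions with no record get a missing value.
#'
#' @param records Tibble from [parse_dssp()] (columns `position`,
#'   `ss_code`, optionally `residue` for cross-checking).
#' @param query A `query_protein`.
#' @return A normalized `tag_track` (`secondary_structure`).
#' @export
ss_track <- function(records, query) {
  stopifnot(inherits(query, "query_protein"))
  check_positions(records$position, query, "DSSP")
  if ("residue" %in% names(records)) check_residues(records, query, "DSSP")
  vals <- rep(NA_real_, query$length)
  vals[records$position] <- ss_score(records$ss_code)
  feature_track("secondary_structure", vals, normalized = TRUE)
}

#' Relative solvent accessibility track
#'
#' Normalizes per-residue SASA by the residue's theoretical maximum
#' accessibility (`RSA = SASA / SA_max`). Values above 1 (possible with
#' empirical SASA estimates) are clamped to 1 so the track satisfies the
#' `[0, 1]` contract of the scoring function. Unknown residues (`X`) have no
#' maximum and get a missing value.
#'
#' @param sasa Tibble with `position` and `sasa` (square Angstrom), e.g.
#'   from [parse_dssp()] or [shrake_rupley_sasa()].
#' @param query A `query_protein`.
#' @param table Named maximum-accessibility vector (default
#'   [max_sa_table()]).
#' @return A normalized `tag_track` (`rsa`).
#' @export
rsa_track <- function(sasa, query, table = max_sa_table()) {
  stopifnot(inherits(query, "query_protein"))
  check_positions(sasa$position, query, "SASA")
  vals <- rep(NA_real_, query$length)
  res <- query$residues[sasa$position]
  mx <- unname(table[res])
  vals[sasa$position] <- pmin(pmax(sasa$sasa / mx, 0), 1)
  # X residues have no defined maximum: explicit missing, excluded from ranking
  vals[sasa$position[is.na(mx)]] <- NA_real_
  feature_track("rsa", vals, normalized = TRUE)
}

check_positions <- function(position, query, what) {
  if (any(position < 1 | position > query$length)) {
    abort(sprintf("%s records address positions outside 1..%d.", what, query$length),
          class = "tagsite_input_error")
  }
  if (anyDuplicated(position)) {
    abort(sprintf("%s records contain duplicate positions.", what),
          class = "tagsite_input_error")
  }
}

check_residues <- function(records, query, what) {
  qres <- query$residues[records$position]
  bad <- which(records$residue != qres & records$residue != "X" & qres != "X")
  if (length(bad)) {
    i <- bad[1]
    abort(
      sprintf("%s residue \"%s\" at position %d does not match query residue \"%s\".",
              what, records$residue[i], records$position[i], qres[i]),
      class = "tagsite_input_error"
    )
  }
  invisible(TRUE)
}

#' Coarse geometric secondary-structure assignment (non-reference fallback)
#'
#' Assigns helix/strand/coil from backbone phi/psi dihedral angles with
#' minimum run lengths (4 for helix, 3 for strand). This is a deliberately
#' simple stand-in used only when no DSSP output is supplied; it does not
#' reproduce Kabsch-Sander hydrogen-bond assignment, and results are
#' labelled non-reference in the run manifest.
#'
#' @param model A `structure_model` (needs backbone N, CA, C atoms).
#' @return A tibble with `position`, `residue`, `ss_code` (`H`, `E` or `C`).
#' @export
assign_ss_geometric <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  res <- model$residues
  n <- nrow(res)
  get_atom <- function(resno, name) {
    a <- model$atoms[model$atoms$resno == resno & model$atoms$elety == name, ]
    if (nrow(a) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(a$x[1], a$y[1], a$z[1])
  }
  N <- t(vapply(res$resno, get_atom, numeric(3), name = "N"))
  CA <- t(vapply(res$resno, get_atom, numeric(3), name = "CA"))
  CO <- t(vapply(res$resno, get_atom, numeric(3), name = "C"))
  dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
    -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && !anyNA(c(CO[i - 1, ], N[i, ], CA[i, ], CO[i, ]))) {
      phi[i] <- dihedral(CO[i - 1, ], N[i, ], CA[i, ], CO[i, ])
    }
    if (i < n && !anyNA(c(N[i, ], CA[i, ], CO[i, ], N[i + 1, ]))) {
      psi[i] <- dihedral(N[i, ], CA[i, ], CO[i, ], N[i + 1, ])
    }
  }
  code <- rep("C", n)
  helix <- !is.na(phi) & !is.na(psi) & phi > -100 & phi < -30 & psi > -80 & psi < -5
  strand <- !is.na(phi) & !is.na(psi) & phi > -180 & phi < -40 &
    (psi > 90 | psi < -170)
  code[strand] <- "E"
  code[helix] <- "H"
  # enforce minimum run lengths
  r <- rle(code)
  r$values[r$values == "H" & r$lengths < 4] <- "C"
  r$values[r$values == "E" & r$lengths < 3] <- "C"
  code <- inverse.rle(r)
  tibble(position = res$position, residue = res$residue, ss_code = code)
}
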