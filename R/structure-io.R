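#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into a tidy atom table, one row per atom. Coordinates
#' are converted from the PDB's angstrom to nanometre. HETATM records (waters,
#' ligands) are excluded; modified residues deposited as ATOM records are kept.
#' Alternate locations are resolved to a single conformer by keeping, per atom,
#' the altloc with the highest occupancy (ties broken by file order). Hydrogens
#' are retained and can be dropped downstream with [heavy_atoms()].
#'
#' @param path Path to a PDB file.
#' @param model_index Zero-based model to extract from a multi-MODEL file
#'   (default 0, the first model).
#' @return A tibble with one row per atom and columns `chain`, `resid`
#'   (author numbering), `ins` (insertion code, `""` if none), `resname`,
#'   `atom` (atom name), `element`, `x`, `y`, `z` (nm). The attribute
#'   `"title"` carries the structure tag used in serialized contact maps.
#' @seealso [write_pdb()], [heavy_atoms()], [ca_positions()]
#' @export
#' @examples
#' helix <- make_ideal_helix(12)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(helix, f)
#' read_pdb(f)
read_pdb <- function(path, model_index = 0) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path))
  }
  check_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model_index < 0 || model_index >= n_models) {
    abort(paste0(
      "Requested model ", model_index, " but file has ", n_models,
      " model(s) (model_index is 0-based)."
    ))
  }
  at <- pdb$atom
  keep <- at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) abort("No ATOM records after excluding HETATM.")
  xyz <- matrix(pdb$xyz[model_index + 1, ], ncol = 3, byrow = TRUE)
  xyz <- xyz[keep, , drop = FALSE]

  ins <- at$insert
  ins[is.na(ins)] <- ""
  alt <- at$alt
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1
  elesy <- at$elesy
  elesy[is.na(elesy)] <- ""
  chain <- at$chain
  chain[is.na(chain)] <- ""

  tbl <- tibble(
    chain = chain,
    resid = as.integer(at$resno),
    ins = ins,
    resname = at$resid,
    atom = at$elety,
    altloc = alt,
    occupancy = as.numeric(occ),
    element = infer_element(elesy, at$elety),
    x = xyz[, 1] / 10,
    y = xyz[, 2] / 10,
    z = xyz[, 3] / 10
  )

  ## altloc resolution: highest occupancy wins, first-seen breaks ties
  tbl$.ord <- seq_len(nrow(tbl))
  tbl <- tbl |>
    dplyr::group_by(.data$chain, .data$resid, .data$ins, .data$atom) |>
    dplyr::slice_max(.data$occupancy, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(.data$.ord, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)

  ## chains in order of first appearance; residues ordered by (resid, ins)
  chain_order <- unique(tbl$chain)
  tbl <- tbl |>
    dplyr::mutate(.chain_rank = match(.data$chain, chain_order)) |>
    dplyr::arrange(.data$.chain_rank, .data$resid, .data$ins, .data$.ord) |>
    dplyr::select(-".ord", -".chain_rank", -"altloc", -"occupancy")

  attr(tbl, "title") <- pdb_title(path)
  tbl
}

## Pre-scan coordinate fields so malformed ATOM lines fail with a line number;
## bio3d would silently coerce them to NA.
check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec) ) {
    abort(paste0("No ATOM/HETATM records in ", path))
  }
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(paste0("Malformed ATOM record (too short) at line ", i, " of ", path))
    }
    flds <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(flds)))) {
      abort(paste0("Malformed coordinate field at line ", i, " of ", path))
    }
  }
  invisible(TRUE)
}

pdb_title <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  tl <- lines[startsWith(lines, "TITLE")]
  if (length(tl) == 0) {
    return(basename(path))
  }
  trimws(paste(substring(tl, 11), collapse = " "))
}

## Element symbol: PDB element column is authoritative; fall back to atom-name
## inference for minimal writers that leave it blank.
infer_element <- function(element, name) {
  name <- trimws(name)
  element <- rep(toupper(trimws(element)), length.out = length(name))
  miss <- is.na(element) | element == ""
  if (any(miss)) {
    guess <- toupper(sub("^[0-9]*", "", name[miss]))
    ## two-letter elements seen in proteins; otherwise first letter
    two <- substr(guess, 1, 2) %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "NA", "CU")
    element[miss] <- ifelse(two, substr(guess, 1, 2), substr(guess, 1, 1))
  }
  element
}

is_hydrogen <- function(element, name = NULL) {
  h <- element == "H" | element == "D"
  if (!is.null(name)) {
    h <- h | (element == "" & grepl("^[0-9]?H", trimws(name)))
  }
  h
}

#' Filter an atom table to heavy (non-hydrogen) atoms
#'
#' @param atoms An atom tibble as returned by [read_pdb()] (a whole structure,
#'   one chain, or a single residue's rows).
#' @return The subset of rows whose element is not hydrogen. May be empty.
#' @export
heavy_atoms <- function(atoms) {
  atoms[!is_hydrogen(atoms$element, atoms$atom), , drop = FALSE]
}

#' Extract ordered C-alpha positions for a chain
#'
#' One entry per residue possessing a CA atom, in chain order. Residues that
#' lack a CA atom are reported in the `"missing_ca"` attribute of the result.
#'
#' @param structure Atom tibble from [read_pdb()].
#' @param chain_id Chain identifier. Defaults to all chains.
#' @return Tibble with columns `chain`, `resid`, `ins`, `resname`, `x`, `y`,
#'   `z` (nm), one row per CA-bearing residue.
#' @export
ca_positions <- function(structure, chain_id = NULL) {
  if (!is.null(chain_id)) {
    if (!all(chain_id %in% structure$chain)) {
      abort(paste0("Unknown chain id: ",
                   paste(setdiff(chain_id, structure$chain), collapse = ", ")))
    }
    structure <- structure[structure$chain %in% chain_id, , drop = FALSE]
  }
  res <- structure |>
    dplyr::distinct(.data$chain, .data$resid, .data$ins, .data$resname)
  ca <- structure |>
    dplyr::filter(.data$atom == "CA", !is_hydrogen(.data$element)) |>
    dplyr::distinct(.data$chain, .data$resid, .data$ins, .keep_all = TRUE) |>
    dplyr::select("chain", "resid", "ins", "resname", "x", "y", "z")
  missing <- dplyr::anti_join(res, ca, by = c("chain", "resid", "ins"))
  out <- dplyr::semi_join(
    dplyr::left_join(res, ca, by = c("chain", "resid", "ins", "resname")),
    ca, by = c("chain", "resid", "ins")
  )
  attr(out, "missing_ca") <- missing
  out
}

#' Write an atom table to a PDB file
#'
#' Coordinates are converted back from nm to angstrom with the PDB's
#' three-decimal precision. A TER record closes each chain.
#'
#' @param structure Atom tibble (columns `chain`, `resid`, `ins`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z`).
#' @param path Output path.
#' @param title Optional TITLE record content.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path, title = attr(structure, "title")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(title) && nzchar(title)) {
    writeLines(paste0("TITLE     ", title), con)
  }
  writeLines(format_pdb_block(structure), con)
  writeLines("END", con)
  invisible(path)
}

format_pdb_block <- function(structure, serial_start = 1L) {
  serial <- serial_start
  out <- character(0)
  for (ch in unique(structure$chain)) {
    sub <- structure[structure$chain == ch, , drop = FALSE]
    lines <- vapply(seq_len(nrow(sub)), function(k) {
      r <- sub[k, ]
      s <- sprintf(
        "ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        (serial + k - 1L) %% 100000L,
        format_atom_name(r$atom), "", substr(r$resname, 1, 3),
        substr(ch, 1, 1), r$resid %% 10000L,
        ifelse(nzchar(r$ins), r$ins, " "),
        r$x * 10, r$y * 10, r$z * 10, 1.0, 0.0, r$element
      )
      s
    }, character(1))
    serial <- serial + nrow(sub)
    last <- sub[nrow(sub), ]
    ter <- sprintf("TER   %5d      %-3s %1s%4d",
                   serial %% 100000L, substr(last$resname, 1, 3),
                   substr(ch, 1, 1), last$resid %% 10000L)
    serial <- serial + 1L
    out <- c(out, lines, ter)
  }
  out
}

## PDB atom-name column convention: names of <4 chars are padded to start in
## column 14; 4-char names start in column 13.
format_atom_name <- function(name) {
  name <- trimws(name)
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         formatC(paste0(" ", name), width = -4))
}
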