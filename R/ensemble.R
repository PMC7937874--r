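#' Construct a coordinate ensemble
#'
#' An ensemble is an ordered sequence of coordinate frames over a fixed atom
#' set: the input to all trajectory statistics (RMSF, PCA, Q_AB, minimum
#' distances). Frames with differing atom counts are rejected, not repaired.
#'
#' @param coords A `n_frames x n_atoms x 3` array (nm), or a list of
#'   `n_atoms x 3` matrices.
#' @param atoms Tibble describing the atom/bead set (columns `chain`,
#'   `resid`, `ins`, and optionally `resname`, `atom`).
#' @param times Optional per-frame times, ns.
#' @return An object of class `"cg_ensemble"` with elements `coords`
#'   (3-d array), `atoms`, `times`.
#' @export
ensemble <- function(coords, atoms, times = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    na <- unique(vapply(coords, nrow, integer(1)))
    if (length(na) != 1) {
      abort("ensemble: frames have differing atom counts.")
    }
    arr <- array(NA_real_, c(length(coords), na, 3))
    for (f in seq_along(coords)) arr[f, , ] <- coords[[f]]
    coords <- arr
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 1) abort("ensemble: need at least one frame.")
  if (dim(coords)[2] != nrow(atoms)) {
    abort("ensemble: coords atom dimension does not match the atom table.")
  }
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!is.null(times) && length(times) != dim(coords)[1]) {
    abort("ensemble: times length does not match frame count.")
  }
  structure(list(coords = coords, atoms = as_tibble(atoms), times = times),
            class = "cg_ensemble")
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat(sprintf("<cg_ensemble>  %d frames x %d atoms\n",
              n_frames(x), n_atoms(x)))
  invisible(x)
}

#' Ensemble dimensions
#' @param ens A `"cg_ensemble"`.
#' @return Integer count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ens) dim(ens$coords)[2]

#' Extract one frame as a coordinate matrix
#' @param ens A `"cg_ensemble"`.
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` matrix, nm.
#' @export
ensemble_frame <- function(ens, i) {
  matrix(ens$coords[i, , ], ncol = 3)
}

#' Read an ensemble from a multi-model PDB file
#'
#' Each MODEL block becomes one frame; the atom set is taken from the first
#' model. Coordinates are converted to nm.
#'
#' @param path Path to a multi-model PDB file.
#' @return A `"cg_ensemble"`.
#' @export
read_ensemble_pdb <- function(path) {
  first <- read_pdb(path, model_index = 0)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  keep <- pdb$atom$type == "ATOM"
  nf <- nrow(pdb$xyz)
  na <- sum(keep)
  arr <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    m <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE] / 10
    arr[f, , ] <- m
  }
  atoms <- first[, c("chain", "resid", "ins", "resname", "atom", "element")]
  if (nrow(atoms) != na) {
    ## altloc resolution in read_pdb may drop atoms; redo the selection here
    arr <- arr[, seq_len(na), , drop = FALSE]
    atoms <- tibble(
      chain = pdb$atom$chain[keep], resid = as.integer(pdb$atom$resno[keep]),
      ins = ifelse(is.na(pdb$atom$insert[keep]), "", pdb$atom$insert[keep]),
      resname = pdb$atom$resid[keep], atom = pdb$atom$elety[keep],
      element = infer_element(pdb$atom$elesy[keep], pdb$atom$elety[keep])
    )
    atoms$chain[is.na(atoms$chain)] <- ""
  }
  ensemble(arr, atoms)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens A `"cg_ensemble"` whose atom table has `resname` and `atom`
#'   columns (bead ensembles use `atom = "CA"`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  atoms <- ens$atoms
  if (!"atom" %in% names(atoms)) atoms$atom <- "CA"
  if (!"resname" %in% names(atoms)) atoms$resname <- "ALA"
  if (!"element" %in% names(atoms)) atoms$element <- "C"
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    frame <- atoms
    xyz <- ensemble_frame(ens, f)
    frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
    writeLines(format_pdb_block(frame), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an ensemble from GRO frame files
#'
#' Accepts one file containing concatenated GRO frames or a character vector
#' of single-frame files. GRO coordinates are already in nm.
#'
#' @param paths One or more GRO file paths.
#' @return A `"cg_ensemble"`.
#' @export
read_ensemble_gro <- function(paths) {
  frames <- list()
  atoms <- NULL
  for (p in paths) {
    lines <- readLines(p, warn = FALSE)
    i <- 1
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
      na <- suppressWarnings(as.integer(trimws(lines[i + 1])))
      if (is.na(na)) abort(paste0("Malformed GRO atom count at line ", i + 1,
                                  " of ", p))
      block <- lines[(i + 2):(i + 1 + na)]
      parsed <- parse_gro_block(block, p, i + 1)
      if (is.null(atoms)) atoms <- parsed$atoms
      frames[[length(frames) + 1]] <- parsed$xyz
      i <- i + na + 3  # title + count + atoms + box line
    }
  }
  ensemble(frames, atoms)
}

## GRO fixed columns: resid 1-5, resname 6-10, atom 11-15, serial 16-20,
## then x, y, z in %8.3f (nm).
parse_gro_block <- function(block, path, offset) {
  resid <- suppressWarnings(as.integer(substr(block, 1, 5)))
  xs <- suppressWarnings(as.numeric(substr(block, 21, 28)))
  ys <- suppressWarnings(as.numeric(substr(block, 29, 36)))
  zs <- suppressWarnings(as.numeric(substr(block, 37, 44)))
  bad <- which(is.na(resid) | is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0) {
    abort(paste0("Malformed GRO atom line ", offset + bad[1], " of ", path))
  }
  list(
    atoms = tibble(
      chain = "", resid = resid, ins = "",
      resname = trimws(substr(block, 6, 10)),
      atom = trimws(substr(block, 11, 15)),
      element = infer_element("", trimws(substr(block, 11, 15)))
    ),
    xyz = cbind(xs, ys, zs)
  )
}

#' Write an ensemble as concatenated GRO frames
#'
#' @inheritParams write_ensemble_pdb
#' @export
write_ensemble_gro <- function(ens, path) {
  atoms <- ens$atoms
  if (!"atom" %in% names(atoms)) atoms$atom <- "CA"
  if (!"resname" %in% names(atoms)) atoms$resname <- "ALA"
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    xyz <- ensemble_frame(ens, f)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%5d", n_atoms(ens)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       atoms$resid %% 100000L, substr(atoms$resname, 1, 5),
                       substr(atoms$atom, 1, 5),
                       seq_len(nrow(atoms)) %% 100000L,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", 0, 0, 0), con)
  }
  invisible(path)
}

## Internal: resolve a frame window. NULL or "last_half" selects the frames
## the validation statistics use by default: 0-based index >= ceiling(n/2).
resolve_window <- function(n, window = NULL) {
  if (is.null(window) || identical(window, "last_half")) {
    if (n == 1) return(1L)
    return(seq.int(ceiling(n / 2) + 1L, n))
  }
  if (identical(window, "all")) return(seq_len(n))
  w <- as.integer(window)
  if (length(w) == 0 || any(w < 1 | w > n)) {
    abort("Invalid frame window.")
  }
  w
}

## Internal: resolve an atom selection to integer indices.
resolve_selection <- function(ens, selection = NULL) {
  if (is.null(selection)) return(seq_len(n_atoms(ens)))
  if (is.data.frame(selection)) {
    if (!"ins" %in% names(selection)) selection$ins <- ""
    idx <- match(res_key(selection$chain, selection$resid, selection$ins),
                 res_key(ens$atoms$chain, ens$atoms$resid, ens$atoms$ins))
    if (anyNA(idx)) abort("Selection references atoms absent from the ensemble.")
    return(idx)
  }
  sel <- as.integer(selection)
  if (length(sel) == 0 || any(sel < 1 | sel > n_atoms(ens))) {
    abort("Selection references atoms absent from the ensemble.")
  }
  sel
}
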