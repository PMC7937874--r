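#' Write a topology as a GROMACS-dialect include (.itp) file
#'
#' Emits `[ moleculetype ]`, `[ atoms ]`, `[ bonds ]` (function type 1:
#' `i j 1 b0 k`), `[ angles ]` (function type 2: `i j k 2 theta0 k`),
#' `[ pairs ]` (function type 1: `i j 1 c6 c12`) and `[ exclusions ]`.
#' Energies are kJ/mol, lengths nm, angles degrees; the pair coefficients
#' c6/c12 are printed in scientific notation with 10 significant digits.
#'
#' @param topology A `"cg_topology"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_itp()]
#' @export
write_itp <- function(topology, path) {
  stopifnot(inherits(topology, "cg_topology"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)

  w("; coarse-grained backbone topology (gomartini)",
    "", "[ moleculetype ]", "; name  nrexcl",
    sprintf("%-10s %d", topology$molecule_name, 1L))

  b <- topology$beads
  w("", "[ atoms ]", ";  nr  type  resnr  residue  atom  cgnr  charge")
  if (nrow(b) > 0) {
    w(sprintf("%6d %5s %6d %6s %5s %6d %8.4f",
              b$index, b$bead, b$resid, b$resname, b$bead, b$index, 0))
  }

  w("", "[ bonds ]", ";   i     j  func     b0(nm)      k(kJ/mol/nm^2)")
  bd <- topology$bonds
  if (nrow(bd) > 0) {
    w(sprintf("%6d %6d %4d %12.5f %14.2f ; %s",
              bd$bead_i, bd$bead_j, 1L, bd$b0, bd$k_bond, bd$origin))
  }

  w("", "[ angles ]", ";   i     j     k  func  theta0(deg)   k(kJ/mol)")
  an <- topology$angles
  if (nrow(an) > 0) {
    w(sprintf("%6d %6d %6d %4d %12.4f %12.2f",
              an$bead_i, an$bead_j, an$bead_k, 2L, an$theta0, an$k_angle))
  }

  w("", "[ pairs ]", ";   i     j  func  c6(kJ/mol nm^6)  c12(kJ/mol nm^12)")
  pr <- topology$pairs
  if (nrow(pr) > 0) {
    w(sprintf("%6d %6d %4d  %.9e  %.9e", pr$bead_i, pr$bead_j, 1L,
              pr$c6, pr$c12))
  }

  w("", "[ exclusions ]")
  ex <- topology$exclusions
  if (nrow(ex) > 0) {
    w(sprintf("%6d %6d", ex$bead_i, ex$bead_j))
  }
  invisible(path)
}

#' Read a GROMACS-dialect topology include file
#'
#' Parses the dialect written by [write_itp()] back into a `"cg_topology"`.
#' Unknown sections (e.g. `[ dihedrals ]`) are skipped with a warning;
#' malformed numeric fields fail with the offending line number. Bead
#' coordinates are not stored in .itp files, so the returned bead table
#' carries `NA` coordinates.
#'
#' @param path Path to an .itp file.
#' @return A `"cg_topology"` object.
#' @export
read_itp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stripped <- sub(";.*$", "", lines)
  stripped <- trimws(stripped)
  section <- NA_character_
  mol <- "molecule"
  atoms <- list(); bonds <- list(); angles <- list()
  pairs <- list(); excl <- list()
  known <- c("moleculetype", "atoms", "bonds", "angles", "pairs", "exclusions")

  num <- function(x, lineno) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      abort(paste0("Malformed numeric field at line ", lineno, " of ", path))
    }
    v
  }

  for (i in seq_along(stripped)) {
    ln <- stripped[i]
    if (!nzchar(ln)) next
    sec <- regmatches(ln, regexec("^\\[\\s*(\\S+)\\s*\\]$", ln))[[1]]
    if (length(sec) == 2) {
      section <- tolower(sec[2])
      if (!section %in% known) {
        warn(paste0("read_itp: skipping unknown section [ ", sec[2], " ]"))
      }
      next
    }
    if (is.na(section) || !section %in% known) next
    f <- strsplit(ln, "\\s+")[[1]]
    ## comment annotations after ';' were already stripped
    if (section == "moleculetype") {
      mol <- f[1]
    } else if (section == "atoms") {
      if (length(f) < 6) abort(paste0("Malformed [ atoms ] line ", i, " of ", path))
      atoms[[length(atoms) + 1]] <- tibble(
        index = as.integer(num(f[1], i)), bead = f[2],
        resid = as.integer(num(f[3], i)), resname = f[4]
      )
    } else if (section == "bonds") {
      if (length(f) < 5) abort(paste0("Malformed [ bonds ] line ", i, " of ", path))
      bonds[[length(bonds) + 1]] <- tibble(
        bead_i = as.integer(num(f[1], i)), bead_j = as.integer(num(f[2], i)),
        b0 = num(f[4], i), k_bond = num(f[5], i), origin = "backbone"
      )
    } else if (section == "angles") {
      if (length(f) < 6) abort(paste0("Malformed [ angles ] line ", i, " of ", path))
      angles[[length(angles) + 1]] <- tibble(
        bead_i = as.integer(num(f[1], i)), bead_j = as.integer(num(f[2], i)),
        bead_k = as.integer(num(f[3], i)),
        theta0 = num(f[5], i), k_angle = num(f[6], i)
      )
    } else if (section == "pairs") {
      if (length(f) < 5) abort(paste0("Malformed [ pairs ] line ", i, " of ", path))
      c6 <- num(f[4], i); c12 <- num(f[5], i)
      ## invert c6/c12 to sigma/epsilon: sigma^6 = c12/c6, eps = c6^2/(4 c12)
      sigma <- if (c6 > 0 && c12 > 0) (c12 / c6)^(1 / 6) else NA_real_
      epsilon <- if (c12 > 0) c6^2 / (4 * c12) else NA_real_
      pairs[[length(pairs) + 1]] <- tibble(
        bead_i = as.integer(num(f[1], i)), bead_j = as.integer(num(f[2], i)),
        sigma = sigma, epsilon = epsilon, r0 = sigma * 2^(1 / 6),
        c6 = c6, c12 = c12
      )
    } else if (section == "exclusions") {
      v <- as.integer(num(f, i))
      if (length(v) >= 2) {
        excl[[length(excl) + 1]] <- tibble(bead_i = v[1], bead_j = v[-1])
      }
    }
  }

  beads <- if (length(atoms)) dplyr::bind_rows(atoms) else
    tibble(index = integer(0), bead = character(0),
           resid = integer(0), resname = character(0))
  beads$ins <- ""
  beads$chain <- ""
  beads$x <- NA_real_; beads$y <- NA_real_; beads$z <- NA_real_
  cg_topology(
    mol, beads,
    bonds = if (length(bonds)) dplyr::bind_rows(bonds) else NULL,
    angles = if (length(angles)) dplyr::bind_rows(angles) else NULL,
    pairs = if (length(pairs)) dplyr::bind_rows(pairs) else NULL,
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else NULL
  )
}
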