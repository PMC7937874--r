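#' Model constants for Go-MARTINI and elastic-network topologies
#'
#' Bundles every tunable constant of the model. Defaults are the optimized
#' parameter set for the Pacsin1 F-BAR dimer: native-contact cutoff 0.5 nm,
#' contact strength scaling `lambda = 1`, base well depth
#' `epsilon0 = 6.276` kJ/mol (the typical hydrogen-bond energy scale in
#' proteins), backbone angle force constants 700 kJ/mol in helices and
#' 20 kJ/mol elsewhere, with the helix-kink prolines (author residues 145 and
#' 221 in Pacsin1) forced to the soft constant. Elastic-network parameters
#' follow the conventional setup: spring 500 kJ/mol/nm^2 between backbone
#' beads separated by 0.5--1.2 nm.
#'
#' @param cutoff Native-contact heavy-atom cutoff, nm.
#' @param lambda Dimensionless scaling of the contact well depth;
#'   `epsilon_ij = lambda * epsilon0`.
#' @param epsilon0 Base contact well depth, kJ/mol.
#' @param k_helix,k_other Backbone angle force constants, kJ/mol, for
#'   helix-class (`H`, `G`, `I`) and all other central residues.
#' @param kink_residues Integer author residue numbers whose central angles
#'   are forced to `k_other` regardless of secondary structure (helix-kink
#'   prolines). Applies in every chain. Use `integer(0)` to disable.
#' @param en_lower,en_upper Elastic-network distance window, nm (inclusive).
#' @param en_spring Elastic-network spring constant, kJ/mol/nm^2.
#' @param k_backbone Harmonic backbone bond constant, kJ/mol/nm^2 (MARTINI
#'   convention).
#' @return A validated list of class `"go_params"`.
#' @export
go_params <- function(cutoff = 0.5,
                      lambda = 1.0,
                      epsilon0 = 6.276,
                      k_helix = 700,
                      k_other = 20,
                      kink_residues = c(145L, 221L),
                      en_lower = 0.5,
                      en_upper = 1.2,
                      en_spring = 500,
                      k_backbone = 1250) {
  stopifnot(
    cutoff > 0, lambda > 0, epsilon0 > 0,
    k_helix >= 0, k_other >= 0,
    en_lower < en_upper, en_spring >= 0, k_backbone >= 0
  )
  structure(
    list(
      cutoff = cutoff, lambda = lambda, epsilon0 = epsilon0,
      k_helix = k_helix, k_other = k_other,
      kink_residues = as.integer(kink_residues),
      en_lower = en_lower, en_upper = en_upper, en_spring = en_spring,
      k_backbone = k_backbone
    ),
    class = "go_params"
  )
}

#' @export
print.go_params <- function(x, ...) {
  cat("Go-MARTINI parameters\n")
  cat(sprintf("  contact cutoff : %.3f nm\n", x$cutoff))
  cat(sprintf("  lambda         : %.3f  (epsilon_ij = %.3f kJ/mol)\n",
              x$lambda, x$lambda * x$epsilon0))
  cat(sprintf("  angle K_BBB    : %g (helix) / %g (other) kJ/mol\n",
              x$k_helix, x$k_other))
  cat(sprintf("  kink residues  : %s\n",
              if (length(x$kink_residues)) paste(x$kink_residues, collapse = ", ")
              else "none"))
  cat(sprintf("  elastic network: k = %g kJ/mol/nm^2, window %.2f-%.2f nm\n",
              x$en_spring, x$en_lower, x$en_upper))
  invisible(x)
}

#' Write or read model parameters as a flat key = value file
#'
#' The same format is used for the run-log sidecar of the command-line front
#' end, so a run is replayable from its log.
#'
#' @param params A [go_params()] object.
#' @param path File path.
#' @return `write_go_params()`: `path` invisibly; `read_go_params()`: a
#'   `go_params` object.
#' @export
write_go_params <- function(params, path) {
  vals <- unclass(params)
  lines <- vapply(names(vals), function(k) {
    v <- vals[[k]]
    paste0(k, " = ", paste(format(v, digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_go_params
#' @export
read_go_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)))
  p <- go_params()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(unclass(p))) next
    parsed <- as.numeric(strsplit(vals[i], ",", fixed = TRUE)[[1]])
    if (k == "kink_residues") {
      p[[k]] <- as.integer(parsed[!is.na(parsed)])
    } else {
      p[[k]] <- parsed[1]
    }
  }
  do.call(go_params, unclass(p))
}

#' The Q_AB contact-presence threshold factor
#'
#' An interface contact is counted as present in a frame when its
#' backbone-bead distance is below `1.5 * sigma_ij`. With
#' `sigma_ij = r0 / 2^(1/6)` this equals `1.5 / 2^(1/6) = 1.33635...` times
#' the native distance `r0` (commonly quoted as approximately `1.34 r0`).
#'
#' @return The scalar `1.5 / 2^(1/6)`.
#' @export
qab_threshold_factor <- function() 1.5 / 2^(1 / 6)
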