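#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares fits `mobile` onto `reference` using the selected atoms,
#' applies the rotation and translation to all atoms, and reports the RMSD
#' over the selection. The rotation is proper (determinant +1): reflections
#' are never introduced. Degenerate selections (collinear or a single point)
#' are fitted on the available rank and flagged via the `"degenerate"`
#' attribute.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices, nm.
#' @param selection Integer atom indices used for the fit (default: all).
#' @return The transformed `mobile` matrix with attributes `"rmsd"` (nm, over
#'   the selection), `"rotation"`, `"translation"` and `"degenerate"`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) == 0) abort("kabsch_superpose: empty selection.")
  a <- mobile[selection, , drop = FALSE]
  b <- reference[selection, , drop = FALSE]
  if (nrow(a) != nrow(b)) {
    abort("kabsch_superpose: selection length differs between structures.")
  }
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(a0, b0)
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sum(sv$d > max(sv$d, .Machine$double.eps) * 1e-8) < 3
  fitted <- sweep(sweep(mobile, 2, ca) %*% t(rot), 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((fitted[selection, , drop = FALSE] - b)^2)))
  attr(fitted, "rmsd") <- rmsd
  attr(fitted, "rotation") <- rot
  attr(fitted, "translation") <- cb - as.numeric(rot %*% ca)
  attr(fitted, "degenerate") <- degenerate
  fitted
}

#' RMSD between two coordinate sets after optimal superposition
#' @inheritParams kabsch_superpose
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(mobile, reference, selection = NULL) {
  attr(kabsch_superpose(mobile, reference, selection), "rmsd")
}

#' Superpose every frame of an ensemble onto a common reference
#'
#' Two-pass procedure: every frame is first fitted to the first frame, the
#' mean structure of those fitted frames is computed, and every original
#' frame is then re-fitted to that mean. This is the standard way to obtain
#' a well-defined internal reference for fluctuation analysis.
#'
#' @param ens A `"cg_ensemble"`.
#' @param selection Atom indices (or a `chain`/`resid` data frame) used for
#'   the fit.
#' @param reference `"mean"` (two-pass, default) or `"first"` (single pass
#'   onto frame 1), or an explicit `n_atoms x 3` matrix.
#' @return The superposed ensemble, with per-frame RMSDs (nm, over the
#'   selection) in the `"rmsd"` attribute and the reference used in
#'   `"reference"`.
#' @export
superpose_ensemble <- function(ens, selection = NULL, reference = "mean") {
  sel <- resolve_selection(ens, selection)
  nf <- n_frames(ens)
  fit_all <- function(ref) {
    out <- ens$coords
    rmsd <- numeric(nf)
    for (f in seq_len(nf)) {
      fitted <- kabsch_superpose(ensemble_frame(ens, f), ref, sel)
      out[f, , ] <- fitted
      rmsd[f] <- attr(fitted, "rmsd")
    }
    list(coords = out, rmsd = rmsd)
  }
  if (is.matrix(reference)) {
    ref <- reference
  } else if (identical(reference, "first")) {
    ref <- ensemble_frame(ens, 1)
  } else {
    pass1 <- fit_all(ensemble_frame(ens, 1))
    ref <- apply(pass1$coords, c(2, 3), mean)
  }
  res <- fit_all(ref)
  out <- ensemble(res$coords, ens$atoms, ens$times)
  attr(out, "rmsd") <- res$rmsd
  attr(out, "reference") <- ref
  out
}

#' Per-atom root-mean-square fluctuation
#'
#' RMSF of each selected atom about its mean position over a frame window.
#' The default window is the last half of the trajectory, where the
#' statistics are collected after equilibration. Frames are assumed already
#' superposed; set `superpose = TRUE` to run [superpose_ensemble()] first.
#'
#' @param ens A `"cg_ensemble"`.
#' @param selection Atom indices or `chain`/`resid` data frame (default all).
#' @param window Frame indices, `"last_half"` (default) or `"all"`.
#' @param superpose Fit frames to their mean structure first.
#' @return Tibble with the selected atoms' key columns and `rmsf` (nm).
#' @export
rmsf <- function(ens, selection = NULL, window = NULL, superpose = FALSE) {
  if (superpose) ens <- superpose_ensemble(ens, selection)
  sel <- resolve_selection(ens, selection)
  win <- resolve_window(n_frames(ens), window)
  x <- ens$coords[win, sel, , drop = FALSE]
  mu <- apply(x, c(2, 3), mean)
  dev2 <- sweep(x, c(2, 3), mu)^2
  msf <- apply(dev2, 2, mean) * 3  # mean over frames & xyz -> sum over xyz
  out <- ens$atoms[sel, , drop = FALSE]
  out$rmsf <- sqrt(msf)
  out
}
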