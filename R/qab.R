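#' Fraction of native interface contacts present per frame (Q_AB)
#'
#' For every frame, the fraction of the reference interface contacts whose
#' backbone-bead distance is below `1.5 * sigma_ij` — equivalently
#' `(1.5 / 2^(1/6)) * r0 = 1.336 * r0` (see [qab_threshold_factor()]). The
#' interface contacts are *virtual*: no model potential acts on them, so
#' Q_AB measures how well the force field's nonbonded interactions alone
#' maintain the dimer interface. Q_AB is 1 on the native frame and invariant
#' under rigid motion of a frame.
#'
#' @param ens A `"cg_ensemble"` of backbone beads.
#' @param interface_map Contact tibble from [build_interface_contacts()].
#' @param window Frames used for the summary mean: indices, `"last_half"`
#'   (default) or `"all"`.
#' @return Tibble with `frame` and `qab` for every frame; the mean over the
#'   summary window is in the `"window_mean"` attribute, and the threshold
#'   distances (nm) in `"thresholds"`.
#' @export
qab <- function(ens, interface_map, window = NULL) {
  if (nrow(interface_map) == 0) abort("qab: empty interface map.")
  key <- res_key(ens$atoms$chain, ens$atoms$resid, ens$atoms$ins)
  bi <- match(res_key(interface_map$chain_i, interface_map$resid_i,
                      interface_map$ins_i), key)
  bj <- match(res_key(interface_map$chain_j, interface_map$resid_j,
                      interface_map$ins_j), key)
  if (anyNA(bi) || anyNA(bj)) {
    abort("qab: interface contact references a residue absent from the ensemble.")
  }
  thr <- qab_threshold_factor() * interface_map$r0
  nf <- n_frames(ens)
  q <- vapply(seq_len(nf), function(f) {
    xyz <- ensemble_frame(ens, f)
    d <- sqrt(rowSums((xyz[bi, , drop = FALSE] - xyz[bj, , drop = FALSE])^2))
    mean(d < thr)
  }, numeric(1))
  out <- tibble(frame = seq_len(nf), qab = q)
  if (!is.null(ens$times)) out$time <- ens$times
  win <- resolve_window(nf, window)
  attr(out, "window_mean") <- mean(q[win])
  attr(out, "thresholds") <- thr
  out
}

#' Minimum distance between two atom selections over a trajectory
#'
#' Per-frame minimum pairwise distance between two selections — e.g. a
#' membrane-inserting loop residue versus the lipid phosphate beads, as a
#' binding metric.
#'
#' @param ens A `"cg_ensemble"`.
#' @param sel_a,sel_b Atom selections: integer indices or `chain`/`resid`
#'   data frames. Both must be non-empty.
#' @return Tibble with `frame` (and `time` if available) and `min_dist` (nm).
#' @export
min_distance_series <- function(ens, sel_a, sel_b) {
  ia <- resolve_selection(ens, sel_a)
  ib <- resolve_selection(ens, sel_b)
  nf <- n_frames(ens)
  d <- vapply(seq_len(nf), function(f) {
    xyz <- ensemble_frame(ens, f)
    min(cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]))
  }, numeric(1))
  out <- tibble(frame = seq_len(nf), min_dist = d)
  if (!is.null(ens$times)) out$time <- ens$times
  out
}
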