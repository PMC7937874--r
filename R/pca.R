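#' Principal component analysis of a coordinate ensemble
#'
#' Builds the `3m x 3m` covariance matrix of the flattened selected
#' coordinates over a frame window and diagonalizes it. Eigenvectors are the
#' collective modes of motion, ordered by decreasing eigenvalue (variance,
#' nm^2); frame projections onto the modes describe the sampled conformations
#' in the essential subspace. Coordinates are mass-unweighted, appropriate
#' for backbone beads of near-uniform mass. Frames are assumed superposed;
#' set `superpose = TRUE` to fit them to their mean structure first.
#'
#' @param ens A `"cg_ensemble"`.
#' @param selection Atom indices or `chain`/`resid` data frame (default all).
#' @param window Frame indices, `"last_half"`, or `"all"` (the default:
#'   conformational sampling normally uses every superposed frame).
#' @param n_modes Number of mode projections to keep (default: all).
#' @param superpose Fit frames before the analysis.
#' @return An object of class `"go_pca"`: list with `mean` (`m x 3`),
#'   `values` (length `3m`, descending), `vectors` (`3m x 3m`, orthonormal
#'   columns, coordinate order `x1 y1 z1 x2 ...`), `projections` (tibble with
#'   `frame` and `PC1..PCk`), `atoms`, `n_frames_used`, `trace`.
#' @seealso [rmsip()], [joint_pca()], [tidy.go_pca()], [autoplot.go_pca()]
#' @export
pca_ensemble <- function(ens, selection = NULL, window = "all",
                         n_modes = NULL, superpose = FALSE) {
  if (superpose) ens <- superpose_ensemble(ens, selection)
  sel <- resolve_selection(ens, selection)
  win <- resolve_window(n_frames(ens), window)
  if (length(win) < 2) abort("pca_ensemble: need at least 2 frames.")
  flat <- flatten_coords(ens, sel, win)
  fit_pca(flat, ens$atoms[sel, , drop = FALSE],
          frame_ids = win, n_modes = n_modes)
}

## frames x 3m matrix, coordinate order x1 y1 z1 x2 y2 z2 ...
flatten_coords <- function(ens, sel, win) {
  x <- ens$coords[win, sel, , drop = FALSE]
  nf <- length(win); m <- length(sel)
  flat <- matrix(NA_real_, nf, 3 * m)
  for (k in 1:3) flat[, seq(k, 3 * m, by = 3)] <- x[, , k]
  flat
}

fit_pca <- function(flat, atoms, frame_ids, n_modes = NULL,
                    source = NULL) {
  mu <- colMeans(flat)
  centred <- sweep(flat, 2, mu)
  cv <- cov(flat)
  eig <- eigen(cv, symmetric = TRUE)
  p <- ncol(flat)
  k <- min(n_modes %||% p, p)
  proj <- centred %*% eig$vectors[, seq_len(k), drop = FALSE]
  proj_tbl <- as_tibble(setNames(as.data.frame(proj), paste0("PC", seq_len(k))))
  proj_tbl <- dplyr::bind_cols(tibble(frame = frame_ids), proj_tbl)
  if (!is.null(source)) proj_tbl <- dplyr::bind_cols(
    tibble(ensemble = source), proj_tbl)
  structure(list(
    mean = matrix(mu, ncol = 3, byrow = TRUE),
    values = eig$values,
    vectors = eig$vectors,
    projections = proj_tbl,
    atoms = atoms,
    n_frames_used = nrow(flat),
    trace = sum(diag(cv))
  ), class = "go_pca")
}

#' @export
print.go_pca <- function(x, ...) {
  frac <- x$values[1:min(3, length(x$values))] / sum(pmax(x$values, 0))
  cat(sprintf(
    "<go_pca>  %d frames, %d coordinates; top eigenvalues explain %s of variance\n",
    x$n_frames_used, length(x$values),
    paste(sprintf("%.1f%%", 100 * frac), collapse = ", ")
  ))
  invisible(x)
}

#' Joint PCA of several ensembles on common principal components
#'
#' Superposes every frame of every ensemble onto a single common reference
#' (the mean structure of the pooled, pre-fitted frames), performs one PCA on
#' the concatenated frames, and projects each ensemble onto the common modes.
#' Projection rows are labeled by the source ensemble, so trajectories from
#' different models can be compared in one essential subspace.
#'
#' @param ensembles Named list of `"cg_ensemble"` objects sharing the same
#'   atom ordering.
#' @param selection Atom indices or `chain`/`resid` data frame.
#' @param windows A single window spec applied to all ensembles, or a list of
#'   one spec per ensemble.
#' @param n_modes Number of mode projections to keep.
#' @return A `"go_pca"` whose `projections` tibble has an `ensemble` column.
#' @export
joint_pca <- function(ensembles, selection = NULL, windows = "all",
                      n_modes = NULL) {
  if (is.null(names(ensembles)) || any(!nzchar(names(ensembles)))) {
    names(ensembles) <- paste0("ensemble_", seq_along(ensembles))
  }
  m0 <- n_atoms(ensembles[[1]])
  if (!all(vapply(ensembles, n_atoms, integer(1)) == m0)) {
    abort("joint_pca: ensembles have incompatible atom sets.")
  }
  if (!is.list(windows)) windows <- rep(list(windows), length(ensembles))
  sel <- resolve_selection(ensembles[[1]], selection)

  ## pass 1: fit everything to the first frame of the first ensemble,
  ## pool, take the grand mean as the common reference
  ref0 <- ensemble_frame(ensembles[[1]], 1)
  pooled <- list()
  for (e in seq_along(ensembles)) {
    ens <- ensembles[[e]]
    win <- resolve_window(n_frames(ens), windows[[e]])
    for (f in win) {
      pooled[[length(pooled) + 1]] <-
        kabsch_superpose(ensemble_frame(ens, f), ref0, sel)
    }
  }
  grand <- Reduce(`+`, pooled) / length(pooled)

  flat <- list(); labels <- character(0); frame_ids <- integer(0)
  for (e in seq_along(ensembles)) {
    ens <- ensembles[[e]]
    win <- resolve_window(n_frames(ens), windows[[e]])
    block <- matrix(NA_real_, length(win), 3 * length(sel))
    for (fi in seq_along(win)) {
      fitted <- kabsch_superpose(ensemble_frame(ens, win[fi]), grand, sel)
      block[fi, ] <- as.numeric(t(fitted[sel, , drop = FALSE]))
    }
    flat[[e]] <- block
    labels <- c(labels, rep(names(ensembles)[e], length(win)))
    frame_ids <- c(frame_ids, win)
  }
  fit_pca(do.call(rbind, flat), ensembles[[1]]$atoms[sel, , drop = FALSE],
          frame_ids = frame_ids, n_modes = n_modes, source = labels)
}

#' Root mean square inner product of two essential subspaces
#'
#' `RMSIP = sqrt( (1/n) * sum_i sum_j (u_i . v_j)^2 )` over the first
#' `n_modes` eigenvectors of each analysis. RMSIP is 1 when the subspaces
#' coincide (in particular for identical analyses) and 0 when they are
#' orthogonal; it is symmetric in its arguments and invariant under
#' rotations within either subspace.
#'
#' @param a,b `"go_pca"` objects, or matrices with eigenvectors in columns.
#' @param n_modes Number of leading modes compared (default 10).
#' @return Scalar in `[0, 1]`.
#' @export
rmsip <- function(a, b, n_modes = 10) {
  ua <- if (inherits(a, "go_pca")) a$vectors else as.matrix(a)
  vb <- if (inherits(b, "go_pca")) b$vectors else as.matrix(b)
  if (nrow(ua) != nrow(vb)) {
    abort("rmsip: eigenvector sets span different coordinate dimensions.")
  }
  if (n_modes > ncol(ua) || n_modes > ncol(vb)) {
    abort("rmsip: fewer modes available than requested.")
  }
  u <- ua[, seq_len(n_modes), drop = FALSE]
  v <- vb[, seq_len(n_modes), drop = FALSE]
  sqrt(sum(crossprod(u, v)^2) / n_modes)
}

#' Tidy the eigenvalue spectrum of a PCA
#'
#' @param x A `"go_pca"` object.
#' @param n_modes Number of leading modes to report (default: all).
#' @param ... Unused.
#' @return Tibble with `mode`, `eigenvalue` (nm^2), `variance_fraction`,
#'   `cumulative_fraction`.
#' @export
tidy.go_pca <- function(x, n_modes = NULL, ...) {
  k <- min(n_modes %||% length(x$values), length(x$values))
  total <- sum(pmax(x$values, 0))
  tibble(
    mode = seq_len(k),
    eigenvalue = x$values[seq_len(k)],
    variance_fraction = pmax(x$values[seq_len(k)], 0) / total,
    cumulative_fraction = cumsum(pmax(x$values[seq_len(k)], 0)) / total
  )
}

#' One-row summary of a PCA
#'
#' @param x A `"go_pca"` object.
#' @param ... Unused.
#' @return Tibble with `n_frames`, `n_coords`, `total_variance` (the
#'   covariance trace, nm^2) and the variance fractions of the first two
#'   modes.
#' @export
glance.go_pca <- function(x, ...) {
  total <- sum(pmax(x$values, 0))
  tibble(
    n_frames = x$n_frames_used,
    n_coords = length(x$values),
    total_variance = x$trace,
    pc1_fraction = pmax(x$values[1], 0) / total,
    pc2_fraction = if (length(x$values) > 1) pmax(x$values[2], 0) / total else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
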