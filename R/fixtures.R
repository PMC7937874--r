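#' Ideal-helix test structure
#'
#' A C-alpha trace on a regular helix (rise 0.15 nm and twist 100 degrees
#' per residue, radius 0.23 nm, giving the canonical ~0.38 nm consecutive
#' C-alpha spacing), plus one dummy side-chain heavy atom per residue. The
#' dummy atom is offset along the helix axis toward the next turn — the
#' direction of the backbone carbonyl oxygen that mediates helical i,i+4
#' packing — so that i,i+4 heavy-atom minimum distances fall inside a 0.5 nm
#' contact cutoff, as in a real alpha-helix.
#'
#' @param n Number of residues (>= 4).
#' @param rise Rise per residue, nm.
#' @param twist Twist per residue, degrees.
#' @param ca_radius Helix radius of the C-alpha trace, nm.
#' @param chain Chain identifier.
#' @param sc_offset Axial offset of the dummy side-chain atom, nm.
#' @return An atom tibble (2 heavy atoms per residue: `CA` and `CB`).
#' @export
make_ideal_helix <- function(n, rise = 0.15, twist = 100, ca_radius = 0.23,
                             chain = "A", sc_offset = 0.27) {
  if (n < 4) abort("make_ideal_helix: need at least 4 residues.")
  theta <- (seq_len(n) - 1) * twist * pi / 180
  z <- (seq_len(n) - 1) * rise
  ca <- cbind(ca_radius * cos(theta), ca_radius * sin(theta), z)
  cb <- cbind(ca[, 1], ca[, 2], z + sc_offset)
  out <- tibble(
    chain = chain,
    resid = rep(seq_len(n), each = 2),
    ins = "",
    resname = "ALA",
    atom = rep(c("CA", "CB"), n),
    element = "C",
    x = as.numeric(t(cbind(ca[, 1], cb[, 1]))),
    y = as.numeric(t(cbind(ca[, 2], cb[, 2]))),
    z = as.numeric(t(cbind(ca[, 3], cb[, 3])))
  )
  attr(out, "title") <- sprintf("ideal_helix_n%d", n)
  out
}

#' Compact random-coil test structure
#'
#' A self-avoiding random C-alpha walk with fixed 0.38 nm steps, biased
#' toward its running centroid so the chain stays compact enough to produce
#' spatial contacts, plus one side-chain atom per residue in a random
#' direction. Deterministic for a given seed.
#'
#' @param n Number of residues.
#' @param seed Random seed.
#' @param spacing Consecutive C-alpha distance, nm.
#' @param min_sep Minimum allowed distance between non-consecutive C-alpha
#'   atoms, nm.
#' @param chain Chain identifier.
#' @return An atom tibble.
#' @export
make_random_coil <- function(n, seed = 7, spacing = 0.38, min_sep = 0.25,
                             chain = "A") {
  withr::with_seed(seed, {
    ca <- matrix(NA_real_, n, 3)
    ca[1, ] <- 0
    for (i in 2:n) {
      for (try in 1:200) {
        dir <- rnorm(3)
        ## pull toward the centroid of what is built so far -> compact coil
        centroid <- colMeans(ca[1:(i - 1), , drop = FALSE])
        pull <- centroid - ca[i - 1, ]
        if (sum(pull^2) > 0) dir <- dir + 1.5 * pull / sqrt(sum(pull^2))
        step <- spacing * dir / sqrt(sum(dir^2))
        cand <- ca[i - 1, ] + step
        prev <- ca[seq_len(max(1, i - 2)), , drop = FALSE]
        if (i == 2 || min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
          ca[i, ] <- cand
          break
        }
      }
      if (anyNA(ca[i, ])) abort("make_random_coil: failed to place residue.")
    }
    sc_dir <- matrix(rnorm(3 * n), n, 3)
    sc_dir <- sc_dir / sqrt(rowSums(sc_dir^2))
    sc <- ca + 0.15 * sc_dir
    out <- tibble(
      chain = chain,
      resid = rep(seq_len(n), each = 2),
      ins = "",
      resname = "GLY",
      atom = rep(c("CA", "CB"), n),
      element = "C",
      x = as.numeric(t(cbind(ca[, 1], sc[, 1]))),
      y = as.numeric(t(cbind(ca[, 2], sc[, 2]))),
      z = as.numeric(t(cbind(ca[, 3], sc[, 3])))
    )
    attr(out, "title") <- sprintf("random_coil_n%d_seed%d", n, seed)
    out
  })
}

#' Toy antiparallel homodimer with designed interface contacts
#'
#' Two copies of an ideal helix placed antiparallel, with `k` designed
#' inter-chain residue pairs brought to a stated distance by protruding dummy
#' atoms, while every other inter-chain heavy-atom distance stays well above
#' the contact cutoff. A surrogate for a homodimer whose interface is probed
#' with virtual contacts. The designed pairs are returned alongside the
#' structure. Small coordinate jitter (normal, sd `jitter`) makes distinct
#' seeds produce distinct coordinates without changing the designed contact
#' count.
#'
#' @param n Residues per chain.
#' @param k Number of designed interface pairs.
#' @param pair_distance Designed inter-chain atom distance, nm.
#' @param jitter Coordinate jitter standard deviation, nm.
#' @param seed Random seed for the jitter.
#' @return List with `structure` (atom tibble, chains `A` and `B`) and
#'   `designed_pairs` (tibble `chain_i`, `resid_i`, `chain_j`, `resid_j`).
#' @export
make_toy_dimer <- function(n = 20, k = 3, pair_distance = 0.45,
                           jitter = 0.005, seed = 7) {
  if (n < 3 * k + 4) abort("make_toy_dimer: n too small for k designed pairs.")
  anchors_b <- as.integer(5 + 3 * (seq_len(k) - 1))  # designed residues in chain B
  anchors_a <- as.integer(n + 1 - anchors_b)         # their partners in chain A
  rise <- 0.15
  w <- 0.45                                    # protrusion x of designed atoms
  dx <- 2 * w + pair_distance                  # chain separation
  z_c <- (n - 1) * rise / 2

  helix <- make_ideal_helix(n)
  sd_atom <- function(resid) tibble(
    chain = "A", resid = resid, ins = "", resname = "ALA", atom = "SD",
    element = "S", x = w, y = 0, z = (resid - 1) * rise
  )
  chain_a <- dplyr::bind_rows(helix, dplyr::bind_rows(lapply(anchors_a, sd_atom)))
  chain_b_t <- dplyr::bind_rows(helix, dplyr::bind_rows(lapply(anchors_b, sd_atom)))
  ## antiparallel placement: 180-degree rotation about the y axis through the
  ## helix mid-height, then translation along x
  chain_b <- chain_b_t |>
    dplyr::mutate(chain = "B",
                  x = -.data$x + dx,
                  z = -.data$z + 2 * z_c)
  structure_tbl <- dplyr::bind_rows(chain_a, chain_b) |>
    dplyr::arrange(.data$chain, .data$resid, .data$atom != "CA")
  if (jitter > 0) {
    structure_tbl <- withr::with_seed(seed, {
      m <- nrow(structure_tbl)
      structure_tbl |>
        dplyr::mutate(x = .data$x + rnorm(m, sd = jitter),
                      y = .data$y + rnorm(m, sd = jitter),
                      z = .data$z + rnorm(m, sd = jitter))
    })
  }
  ## overlap guard: the chains must not clash
  a_xyz <- coords_matrix(structure_tbl[structure_tbl$chain == "A", ])
  b_xyz <- coords_matrix(structure_tbl[structure_tbl$chain == "B", ])
  if (min(cross_dist(a_xyz, b_xyz)) < 0.15) {
    abort("make_toy_dimer: inter-chain atom clash in constructed dimer.")
  }
  attr(structure_tbl, "title") <- sprintf("toy_dimer_n%d_k%d_seed%d", n, k, seed)
  list(
    structure = structure_tbl,
    designed_pairs = tibble(
      chain_i = "A", resid_i = anchors_a,
      chain_j = "B", resid_j = anchors_b,
      distance = pair_distance
    )
  )
}

#' Gaussian ensemble with a planted covariance spectrum
#'
#' Synthetic trajectory around a reference structure:
#' `frame = reference + sum_k sqrt(variance_k) z_k e_k` with independent
#' standard-normal `z_k` and orthonormal planted modes `e_k` (random unless
#' supplied). The known spectrum makes the ensemble an exact oracle for PCA
#' eigenvalue recovery, RMSF and RMSIP self-consistency.
#'
#' @param reference Atom/bead tibble (coordinates used as the mean) or an
#'   `m x 3` coordinate matrix.
#' @param variances Planted mode variances, nm^2 (length <= 3m, all > 0).
#' @param n_frames Number of frames.
#' @param seed Random seed.
#' @param modes Optional `3m x k` orthonormal mode matrix; random orthonormal
#'   columns are drawn when `NULL`.
#' @return A `"cg_ensemble"` with the planted `modes` and `variances` stored
#'   as attributes.
#' @export
make_gaussian_ensemble <- function(reference, variances, n_frames,
                                   seed = 7, modes = NULL) {
  if (any(variances <= 0)) {
    abort("make_gaussian_ensemble: planted variances must be positive.")
  }
  if (is.data.frame(reference)) {
    atoms <- reference[, intersect(c("chain", "resid", "ins", "resname",
                                     "atom", "element"), names(reference))]
    ref <- coords_matrix(reference)
  } else {
    ref <- as.matrix(reference)
    atoms <- tibble(chain = "A", resid = seq_len(nrow(ref)), ins = "",
                    resname = "ALA", atom = "CA", element = "C")
  }
  m <- nrow(ref)
  p <- 3 * m
  kk <- length(variances)
  if (kk > p) abort("make_gaussian_ensemble: more planted modes than coordinates.")
  withr::with_seed(seed, {
    if (is.null(modes)) {
      qr_d <- qr(matrix(rnorm(p * kk), p, kk))
      modes <- qr.Q(qr_d)
    }
    z <- matrix(rnorm(n_frames * kk), n_frames, kk)
  })
  flat_ref <- as.numeric(t(ref))               # x1 y1 z1 x2 ...
  disp <- z %*% (t(modes) * sqrt(variances))
  frames <- sweep(disp, 2, flat_ref, "+")
  arr <- array(NA_real_, c(n_frames, m, 3))
  for (f in seq_len(n_frames)) {
    arr[f, , ] <- matrix(frames[f, ], ncol = 3, byrow = TRUE)
  }
  ens <- ensemble(arr, atoms)
  attr(ens, "modes") <- modes
  attr(ens, "variances") <- variances
  ens
}
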