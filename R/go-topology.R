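#' Assign one backbone bead per residue
#'
#' Backbone beads (BB) sit at the C-alpha positions and are the interaction
#' sites of all Go pair terms, elastic bonds and backbone angles. By default
#' every CA-bearing residue of the structure gets one bead, numbered 1..n with
#' chains in order of appearance (chain A block before chain B). An external
#' index map (e.g. BB bead numbers from a full MARTINI topology) can be
#' supplied instead.
#'
#' @param structure Atom tibble from [read_pdb()].
#' @param index_map Optional tibble with columns `index`, `chain`, `resid`
#'   (and optionally `ins`) giving the bead index of each residue.
#' @return Bead table: tibble with columns `index`, `chain`, `resid`, `ins`,
#'   `resname`, `x`, `y`, `z` (CA coordinates, nm), `bead` (`"BB"`).
#' @export
assign_backbone_beads <- function(structure, index_map = NULL) {
  ca <- ca_positions(structure)
  miss <- attr(ca, "missing_ca")
  if (nrow(miss) > 0) {
    abort(paste0(
      "assign_backbone_beads: residue(s) without a CA atom: ",
      paste(head(res_key(miss$chain, miss$resid, miss$ins), 5), collapse = ", ")
    ))
  }
  beads <- ca |>
    dplyr::mutate(bead = "BB") |>
    dplyr::select("chain", "resid", "ins", "resname", "x", "y", "z", "bead")
  if (is.null(index_map)) {
    beads$index <- seq_len(nrow(beads))
  } else {
    if (!"ins" %in% names(index_map)) index_map$ins <- ""
    m <- dplyr::left_join(beads, index_map[, c("index", "chain", "resid", "ins")],
                          by = c("chain", "resid", "ins"))
    if (anyNA(m$index)) {
      abort("assign_backbone_beads: index_map does not cover every residue.")
    }
    beads$index <- as.integer(m$index)
    if (anyDuplicated(beads$index)) {
      abort("assign_backbone_beads: index_map assigns duplicate bead indices.")
    }
  }
  dplyr::relocate(beads, "index")
}

#' Convert a contact map into Go-MARTINI Lennard-Jones pair terms
#'
#' Each native contact becomes a 12-6 Lennard-Jones pair term between the
#' backbone beads of its residues, with the minimum placed at the native
#' C-alpha--C-alpha distance: `sigma = r0 / 2^(1/6)`, well depth
#' `epsilon_ij = lambda * epsilon0`, and GROMACS pair coefficients
#' `c6 = 4 epsilon sigma^6`, `c12 = 4 epsilon sigma^12`. A matching exclusion
#' is emitted for every pair so the term replaces, rather than adds to, the
#' force field's own nonbonded interaction between those beads.
#'
#' @param contacts Contact tibble from [build_chain_contacts()].
#' @param beads Bead table from [assign_backbone_beads()].
#' @param params A [go_params()] object.
#' @return List with `pairs` (tibble `bead_i`, `bead_j`, `sigma`, `epsilon`,
#'   `r0`, `c6`, `c12`) and `exclusions` (tibble `bead_i`, `bead_j`).
#' @export
make_go_pairs <- function(contacts, beads, params = go_params()) {
  bi <- bead_index_of(contacts$chain_i, contacts$resid_i, contacts$ins_i, beads)
  bj <- bead_index_of(contacts$chain_j, contacts$resid_j, contacts$ins_j, beads)
  sigma <- contacts$r0 / 2^(1 / 6)
  eps <- params$lambda * params$epsilon0
  pairs <- tibble(
    bead_i = pmin(bi, bj),
    bead_j = pmax(bi, bj),
    sigma = sigma,
    epsilon = eps,
    r0 = contacts$r0,
    c6 = 4 * eps * sigma^6,
    c12 = 4 * eps * sigma^12
  ) |>
    dplyr::arrange(.data$bead_i, .data$bead_j)
  list(pairs = pairs, exclusions = pairs[, c("bead_i", "bead_j")])
}

bead_index_of <- function(chain, resid, ins, beads) {
  idx <- match(res_key(chain, resid, ins),
               res_key(beads$chain, beads$resid, beads$ins))
  if (anyNA(idx)) {
    abort(paste0("No bead for residue(s): ",
                 paste(head(res_key(chain, resid, ins)[is.na(idx)], 5),
                       collapse = ", ")))
  }
  beads$index[idx]
}

#' Backbone angle terms with secondary-structure-dependent force constants
#'
#' One angle per consecutive intra-chain bead triple. The equilibrium angle
#' `theta0` is measured in the native structure, biasing the backbone toward
#' the native geometry. The force constant is `k_helix` when the central
#' residue's DSSP class is helical (`H`, `G`, `I`) and `k_other` otherwise;
#' residues listed in `params$kink_residues` (helix-kink prolines) are forced
#' to `k_other` regardless of their assignment.
#'
#' @param beads Bead table.
#' @param ss Secondary-structure tibble from [read_secondary_structure()]
#'   (may cover any subset of chains), or `NULL` for all-coil.
#' @param params A [go_params()] object.
#' @return Tibble with columns `bead_i`, `bead_j`, `bead_k`, `theta0`
#'   (degrees), `k_angle` (kJ/mol).
#' @export
make_angles <- function(beads, ss = NULL, params = go_params()) {
  out <- list()
  for (ch in unique(beads$chain)) {
    b <- beads[beads$chain == ch, , drop = FALSE]
    n <- nrow(b)
    if (n < 3) next
    xyz <- coords_matrix(b)
    i <- seq_len(n - 2)
    theta0 <- vapply(i, function(k) {
      v1 <- xyz[k, ] - xyz[k + 1, ]
      v2 <- xyz[k + 2, ] - xyz[k + 1, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }, numeric(1))
    centre_ss <- rep("C", n)
    if (!is.null(ss)) {
      m <- match(res_key(ch, b$resid, b$ins),
                 res_key(ss$chain, ss$resid, ss$ins))
      centre_ss[!is.na(m)] <- ss$ss[m[!is.na(m)]]
    }
    k_angle <- ifelse(centre_ss[i + 1] %in% helix_codes(),
                      params$k_helix, params$k_other)
    k_angle[b$resid[i + 1] %in% params$kink_residues] <- params$k_other
    out[[ch]] <- tibble(
      bead_i = b$index[i], bead_j = b$index[i + 1], bead_k = b$index[i + 2],
      theta0 = theta0, k_angle = k_angle
    )
  }
  if (length(out) == 0) {
    return(tibble(bead_i = integer(0), bead_j = integer(0),
                  bead_k = integer(0), theta0 = numeric(0),
                  k_angle = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Harmonic backbone bonds between consecutive beads
#'
#' One bond per consecutive intra-chain bead pair, with the equilibrium
#' length taken from the native C-alpha--C-alpha distance. No bond ever
#' crosses a chain boundary.
#'
#' @param beads Bead table.
#' @param k_bond Force constant, kJ/mol/nm^2.
#' @return Tibble with columns `bead_i`, `bead_j`, `b0` (nm), `k_bond`,
#'   `origin` (`"backbone"`).
#' @export
make_backbone_bonds <- function(beads, k_bond = 1250) {
  out <- list()
  for (ch in unique(beads$chain)) {
    b <- beads[beads$chain == ch, , drop = FALSE]
    n <- nrow(b)
    if (n < 2) next
    xyz <- coords_matrix(b)
    i <- seq_len(n - 1)
    b0 <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[i + 1, , drop = FALSE])^2))
    out[[ch]] <- tibble(bead_i = b$index[i], bead_j = b$index[i + 1],
                        b0 = b0, k_bond = k_bond, origin = "backbone")
  }
  if (length(out) == 0) {
    return(tibble(bead_i = integer(0), bead_j = integer(0), b0 = numeric(0),
                  k_bond = numeric(0), origin = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Elastic-network bonds between backbone beads
#'
#' Harmonic springs between intra-chain bead pairs with sequence separation
#' of at least 3 residues whose native distance falls inside the closed
#' window `[en_lower, en_upper]`. This is the conventional elastic-network
#' restraint set that holds the fold rigid; the Go pair terms are its
#' breakable replacement.
#'
#' @param beads Bead table.
#' @param params A [go_params()] object (fields `en_lower`, `en_upper`,
#'   `en_spring`).
#' @return Tibble with columns `bead_i`, `bead_j`, `b0` (nm), `k_bond`,
#'   `origin` (`"elastic"`).
#' @export
make_elastic_bonds <- function(beads, params = go_params()) {
  out <- list()
  for (ch in unique(beads$chain)) {
    b <- beads[beads$chain == ch, , drop = FALSE]
    n <- nrow(b)
    if (n < 4) next
    d <- cross_dist(coords_matrix(b), coords_matrix(b))
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    hit <- which(upper.tri(d) & sep >= 3 &
                   d >= params$en_lower & d <= params$en_upper,
                 arr.ind = TRUE)
    if (nrow(hit) == 0) next
    ord <- order(hit[, 1], hit[, 2])
    hit <- hit[ord, , drop = FALSE]
    out[[ch]] <- tibble(
      bead_i = b$index[hit[, 1]], bead_j = b$index[hit[, 2]],
      b0 = d[hit], k_bond = params$en_spring, origin = "elastic"
    )
  }
  if (length(out) == 0) {
    return(tibble(bead_i = integer(0), bead_j = integer(0), b0 = numeric(0),
                  k_bond = numeric(0), origin = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Assemble a coarse-grained topology object
#'
#' Container for the bead table and all term lists, validated so every bead
#' index referenced by a term exists and every Go pair has a matching
#' exclusion.
#'
#' @param molecule_name Molecule name for the `[ moleculetype ]` section.
#' @param beads Bead table.
#' @param bonds,angles,pairs,exclusions Term tibbles (may be empty/`NULL`).
#' @return An object of class `"cg_topology"`.
#' @export
cg_topology <- function(molecule_name, beads, bonds = NULL, angles = NULL,
                        pairs = NULL, exclusions = NULL) {
  empty <- function(x, proto) if (is.null(x)) proto else x
  top <- structure(list(
    molecule_name = molecule_name,
    beads = beads,
    bonds = empty(bonds, make_backbone_bonds(beads[0, ])),
    angles = empty(angles, make_angles(beads[0, ])),
    pairs = empty(pairs, tibble(bead_i = integer(0), bead_j = integer(0),
                                sigma = numeric(0), epsilon = numeric(0),
                                r0 = numeric(0), c6 = numeric(0),
                                c12 = numeric(0))),
    exclusions = empty(exclusions, tibble(bead_i = integer(0),
                                          bead_j = integer(0)))
  ), class = "cg_topology")
  refd <- c(top$bonds$bead_i, top$bonds$bead_j,
            top$angles$bead_i, top$angles$bead_j, top$angles$bead_k,
            top$pairs$bead_i, top$pairs$bead_j,
            top$exclusions$bead_i, top$exclusions$bead_j)
  if (!all(refd %in% beads$index)) {
    abort("cg_topology: a term references a bead index that does not exist.")
  }
  pk <- paste(top$pairs$bead_i, top$pairs$bead_j)
  ek <- paste(top$exclusions$bead_i, top$exclusions$bead_j)
  if (!all(pk %in% ek)) {
    abort("cg_topology: every pair term needs a matching exclusion.")
  }
  top
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf(
    "<cg_topology '%s'>  %d beads, %d bonds, %d angles, %d pairs, %d exclusions\n",
    x$molecule_name, nrow(x$beads), nrow(x$bonds), nrow(x$angles),
    nrow(x$pairs), nrow(x$exclusions)
  ))
  invisible(x)
}

#' Build a complete Go-MARTINI backbone topology from a structure
#'
#' Convenience pipeline: backbone beads, per-chain native-contact maps at
#' `params$cutoff`, Lennard-Jones pair terms with exclusions, harmonic
#' backbone bonds and secondary-structure-dependent angles. No terms are
#' generated between chains; the dimer interface is held by the force field's
#' own nonbonded interactions.
#'
#' @param structure Atom tibble from [read_pdb()].
#' @param ss Secondary-structure tibble covering any subset of chains, or
#'   `NULL` for all-coil.
#' @param params A [go_params()] object.
#' @param molecule_name Molecule name.
#' @return A `"cg_topology"` object.
#' @export
go_martini_topology <- function(structure, ss = NULL, params = go_params(),
                                molecule_name = "protein") {
  beads <- assign_backbone_beads(structure)
  cmaps <- lapply(unique(beads$chain), function(ch) {
    build_chain_contacts(structure, ch, cutoff = params$cutoff)
  })
  contacts <- dplyr::bind_rows(cmaps)
  gp <- make_go_pairs(contacts, beads, params)
  cg_topology(
    molecule_name, beads,
    bonds = make_backbone_bonds(beads, k_bond = params$k_backbone),
    angles = make_angles(beads, ss, params),
    pairs = gp$pairs, exclusions = gp$exclusions
  )
}

#' Build a conventional elastic-network backbone topology
#'
#' Backbone beads, harmonic backbone bonds, native-geometry angles and the
#' elastic-network springs of [make_elastic_bonds()]; no Lennard-Jones pair
#' terms.
#'
#' @inheritParams go_martini_topology
#' @return A `"cg_topology"` object.
#' @export
en_martini_topology <- function(structure, ss = NULL, params = go_params(),
                                molecule_name = "protein") {
  beads <- assign_backbone_beads(structure)
  cg_topology(
    molecule_name, beads,
    bonds = dplyr::bind_rows(
      make_backbone_bonds(beads, k_bond = params$k_backbone),
      make_elastic_bonds(beads, params)
    ),
    angles = make_angles(beads, ss, params)
  )
}

#' Lennard-Jones 12-6 pair energy
#'
#' `U(r) = 4 epsilon ((sigma/r)^12 - (sigma/r)^6)`. The minimum sits at
#' `r = 2^(1/6) sigma` with depth `-epsilon`, and `U(sigma) = 0`.
#'
#' @param r Distance(s), nm.
#' @param sigma LJ length parameter, nm.
#' @param epsilon Well depth, kJ/mol.
#' @return Energy in kJ/mol.
#' @export
lj_energy <- function(r, sigma, epsilon) {
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}
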