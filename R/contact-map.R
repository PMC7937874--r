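#' Minimum heavy-atom distance between two residues
#'
#' The residue-residue distance used by the cutoff native-contact scheme:
#' the minimum Euclidean distance over all pairs of non-hydrogen atoms.
#'
#' @param a,b Atom tibbles holding the atoms of one residue each.
#' @return Distance in nm.
#' @export
min_residue_distance <- function(a, b) {
  ha <- heavy_atoms(a)
  hb <- heavy_atoms(b)
  if (nrow(ha) == 0 || nrow(hb) == 0) {
    abort("min_residue_distance: a residue has no heavy atoms.")
  }
  min(cross_dist(coords_matrix(ha), coords_matrix(hb)))
}

## Internal: split one chain into per-residue heavy-atom coordinate blocks,
## with CA coordinates and a bounding sphere for the spatial prefilter.
chain_residue_index <- function(structure, chain_id) {
  sub <- structure[structure$chain == chain_id, , drop = FALSE]
  if (nrow(sub) == 0) abort(paste0("Unknown chain id: ", chain_id))
  sub <- heavy_atoms(sub)
  key <- res_key(sub$chain, sub$resid, sub$ins)
  keys <- unique(key)
  blocks <- lapply(keys, function(k) coords_matrix(sub[key == k, , drop = FALSE]))
  first <- match(keys, key)
  ca <- matrix(NA_real_, length(keys), 3)
  is_ca <- sub$atom == "CA"
  for (i in seq_along(keys)) {
    rows <- which(key == keys[i] & is_ca)
    if (length(rows) > 0) ca[i, ] <- coords_matrix(sub[rows[1], , drop = FALSE])
  }
  centroid <- t(vapply(blocks, colMeans, numeric(3)))
  radius <- vapply(seq_along(blocks), function(i) {
    max(sqrt(rowSums(sweep(blocks[[i]], 2, centroid[i, ])^2)))
  }, numeric(1))
  list(
    keys = keys,
    chain = chain_id,
    resid = sub$resid[first],
    ins = sub$ins[first],
    blocks = blocks,
    ca = ca,
    centroid = centroid,
    radius = radius
  )
}

#' Build the intra-chain native-contact map of one chain
#'
#' Implements the simple cutoff scheme for structure-based (Go-type) models:
#' every `(i, i+3)` pair along a continuous stretch of the resolved sequence
#' is a native contact unconditionally (`kind = "sequence"`, standing in for
#' the dihedral term of classic Go models), and every pair with `j > i+3`
#' whose minimum heavy-atom distance is strictly below `cutoff` is a spatial
#' contact (`kind = "spatial"`). Pairs `(i, i+1)` and `(i, i+2)` are never
#' contacts: they are covered by bond and angle terms. The stored `r0` is the
#' native C-alpha--C-alpha distance, which places the Lennard-Jones minimum of
#' the derived pair term at the native separation.
#'
#' @param structure Atom tibble from [read_pdb()].
#' @param chain_id Chain to map.
#' @param cutoff Heavy-atom minimum-distance cutoff in nm (default 0.5,
#'   i.e. 5.0 angstrom).
#' @return A contact tibble with columns `chain_i`, `resid_i`, `ins_i`,
#'   `chain_j`, `resid_j`, `ins_j`, `r0` (nm), `kind`, carrying the cutoff and
#'   the structure tag as attributes.
#' @seealso [build_interface_contacts()], [compare_maps()], [make_go_pairs()]
#' @export
build_chain_contacts <- function(structure, chain_id, cutoff = 0.5) {
  idx <- chain_residue_index(structure, chain_id)
  n <- length(idx$keys)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  kind <- character(0)

  ## sequence contacts: (i, i+3) over continuous author numbering
  if (n >= 4) {
    for (i in seq_len(n - 3)) {
      run <- idx$resid[i:(i + 3)]
      if (all(diff(run) == 1L)) {
        pairs_i <- c(pairs_i, i)
        pairs_j <- c(pairs_j, i + 3L)
        kind <- c(kind, "sequence")
      }
    }
  }

  ## spatial contacts: j > i+3, min heavy-atom distance < cutoff;
  ## centroid + bounding-radius prefilter, exact distance to decide
  cand <- spatial_candidates(idx, idx, cutoff)
  cand <- cand[cand$j > cand$i + 3L, , drop = FALSE]
  if (nrow(cand) > 0) {
    hit <- vapply(seq_len(nrow(cand)), function(k) {
      min(cross_dist(idx$blocks[[cand$i[k]]], idx$blocks[[cand$j[k]]])) < cutoff
    }, logical(1))
    pairs_i <- c(pairs_i, cand$i[hit])
    pairs_j <- c(pairs_j, cand$j[hit])
    kind <- c(kind, rep("spatial", sum(hit)))
  }

  finish_contact_map(idx, idx, pairs_i, pairs_j, kind, cutoff,
                     attr(structure, "title") %||% "structure")
}

spatial_candidates <- function(ia, ib, cutoff) {
  d <- cross_dist(ia$centroid, ib$centroid)
  reach <- outer(ia$radius, ib$radius, "+") + cutoff
  hits <- which(d < reach, arr.ind = TRUE)
  tibble(i = hits[, 1], j = hits[, 2])
}

finish_contact_map <- function(ia, ib, pi, pj, kind, cutoff, tag) {
  r0 <- sqrt(rowSums((ia$ca[pi, , drop = FALSE] - ib$ca[pj, , drop = FALSE])^2))
  if (anyNA(r0)) {
    bad <- unique(c(ia$keys[pi[is.na(r0)]], ib$keys[pj[is.na(r0)]]))
    abort(paste0("Contact residue(s) missing a CA atom: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  out <- tibble(
    chain_i = rep(ia$chain, length(pi)),
    resid_i = ia$resid[pi],
    ins_i = ia$ins[pi],
    chain_j = rep(ib$chain, length(pj)),
    resid_j = ib$resid[pj],
    ins_j = ib$ins[pj],
    r0 = r0,
    kind = kind
  )
  out <- dplyr::arrange(out, .data$resid_i, .data$ins_i, .data$resid_j, .data$ins_j)
  attr(out, "cutoff") <- cutoff
  attr(out, "structure") <- tag
  out
}

#' Build virtual interface contacts between two chains
#'
#' Inter-chain residue pairs whose minimum heavy-atom distance is below the
#' cutoff, defined exactly like the intra-chain spatial contacts but across
#' the dimer interface (`kind = "interface"`). No sequence rule applies
#' across chains. These contacts are *virtual*: they are not turned into
#' model potentials, but serve as the reference set for the Q_AB interface
#' statistic ([qab()]).
#'
#' @inheritParams build_chain_contacts
#' @param chain_a,chain_b The two (distinct) chains.
#' @return A contact tibble (see [build_chain_contacts()]).
#' @export
build_interface_contacts <- function(structure, chain_a, chain_b, cutoff = 0.5) {
  if (identical(chain_a, chain_b)) {
    abort("build_interface_contacts: the two chain ids must differ.")
  }
  ia <- chain_residue_index(structure, chain_a)
  ib <- chain_residue_index(structure, chain_b)
  cand <- spatial_candidates(ia, ib, cutoff)
  hit <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    hit[k] <- min(cross_dist(ia$blocks[[cand$i[k]]], ib$blocks[[cand$j[k]]])) < cutoff
  }
  finish_contact_map(ia, ib, cand$i[hit], cand$j[hit],
                     rep("interface", sum(hit)), cutoff,
                     attr(structure, "title") %||% "structure")
}

#' Compare two contact maps under a residue-key correspondence
#'
#' Partitions the union of two maps into contacts common to both and contacts
#' unique to each, after translating residue keys through a mapping. The
#' default mapping matches residues by author `resid` + insertion code, the
#' natural correspondence between the chains of a homodimer.
#'
#' @param a,b Contact tibbles.
#' @param mapping Optional two-column data frame mapping `a`'s residue keys to
#'   `b`'s (columns `from`, `to`, keys as `"resid|ins"` strings). Must be a
#'   bijection.
#' @return A list with tibbles `common`, `only_a`, `only_b` (rows taken from
#'   `a` for `common`) and the counts `n_a`, `n_b`, `n_common`, plus
#'   `frac_a = n_common / n_a` and `frac_b = n_common / n_b`.
#' @export
compare_maps <- function(a, b, mapping = NULL) {
  key_of <- function(m, map = NULL) {
    ki <- paste(m$resid_i, m$ins_i, sep = "|")
    kj <- paste(m$resid_j, m$ins_j, sep = "|")
    if (!is.null(map)) {
      if (anyDuplicated(map$from) || anyDuplicated(map$to)) {
        abort("compare_maps: mapping is not a bijection.")
      }
      ki <- map$to[match(ki, map$from)]
      kj <- map$to[match(kj, map$from)]
      if (anyNA(ki) || anyNA(kj)) {
        abort("compare_maps: mapping does not cover all residue keys of map a.")
      }
    }
    ## canonical unordered pair
    paste(pmin(ki, kj), pmax(ki, kj), sep = " & ")
  }
  ka <- key_of(a, mapping)
  kb <- key_of(b)
  common_keys <- intersect(ka, kb)
  list(
    common = a[ka %in% common_keys, , drop = FALSE],
    only_a = a[!(ka %in% common_keys), , drop = FALSE],
    only_b = b[!(kb %in% common_keys), , drop = FALSE],
    n_a = length(ka),
    n_b = length(kb),
    n_common = length(common_keys),
    frac_a = length(common_keys) / length(ka),
    frac_b = length(common_keys) / length(kb)
  )
}

#' Write or read a contact map as tab-separated text
#'
#' One contact per line with columns `chain_i`, `resid_i`, `chain_j`,
#' `resid_j`, `r0_nm` (5 decimals), `kind`; insertion codes are appended to
#' the residue number (e.g. `100A`). Header comment lines (`#`) carry the
#' cutoff and the structure tag.
#'
#' @param contacts Contact tibble.
#' @param path File path.
#' @return `write_contacts()`: `path` invisibly. `read_contacts()`: a contact
#'   tibble.
#' @export
write_contacts <- function(contacts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# cutoff_nm=", format(attr(contacts, "cutoff") %||% NA)),
    paste0("# structure=", attr(contacts, "structure") %||% ""),
    "# chain_i\tresid_i\tchain_j\tresid_j\tr0_nm\tkind"
  ), con)
  lines <- sprintf("%s\t%s%s\t%s\t%s%s\t%.5f\t%s",
                   contacts$chain_i, contacts$resid_i, contacts$ins_i,
                   contacts$chain_j, contacts$resid_j, contacts$ins_j,
                   contacts$r0, contacts$kind)
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_contacts
#' @export
read_contacts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  cutoff <- NA_real_
  tag <- ""
  cut_ln <- grep("^# cutoff_nm=", hdr, value = TRUE)
  if (length(cut_ln) > 0) cutoff <- as.numeric(sub("^# cutoff_nm=", "", cut_ln[1]))
  tag_ln <- grep("^# structure=", hdr, value = TRUE)
  if (length(tag_ln) > 0) tag <- sub("^# structure=", "", tag_ln[1])
  f <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 6)
  if (length(bad) > 0) {
    abort(paste0("Malformed contact line ", bad[1], " in ", path))
  }
  m <- do.call(rbind, f)
  split_res <- function(s) {
    resid <- as.integer(sub("^(-?[0-9]+).*$", "\\1", s))
    ins <- sub("^-?[0-9]+", "", s)
    list(resid = resid, ins = ins)
  }
  ri <- split_res(m[, 2])
  rj <- split_res(m[, 4])
  out <- tibble(
    chain_i = m[, 1], resid_i = ri$resid, ins_i = ri$ins,
    chain_j = m[, 3], resid_j = rj$resid, ins_j = rj$ins,
    r0 = as.numeric(m[, 5]), kind = m[, 6]
  )
  attr(out, "cutoff") <- cutoff
  attr(out, "structure") <- tag
  out
}
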