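# Independent reference implementations used as oracles. Deliberately naive:
# correctness by construction, no shared code with the package internals.

# Exhaustive O(n^2 m^2) native-contact reference: every residue pair scanned
# with a double loop over all heavy-atom pairs.
oracle_chain_contacts <- function(structure, chain_id, cutoff) {
  sub <- structure[structure$chain == chain_id, , drop = FALSE]
  sub <- sub[!(sub$element %in% c("H", "D")), , drop = FALSE]
  keys <- unique(paste(sub$resid, sub$ins))
  n <- length(keys)
  resid <- sub$resid[match(keys, paste(sub$resid, sub$ins))]
  res_atoms <- lapply(keys, function(k) {
    as.matrix(sub[paste(sub$resid, sub$ins) == k, c("x", "y", "z")])
  })
  min_dist <- function(A, B) {
    best <- Inf
    for (p in seq_len(nrow(A))) {
      for (q in seq_len(nrow(B))) {
        best <- min(best, sqrt(sum((A[p, ] - B[q, ])^2)))
      }
    }
    best
  }
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sep <- j - i
      if (sep < 3) next
      if (sep == 3) {
        if (all(diff(resid[i:j]) == 1)) {
          out[[length(out) + 1]] <- c(resid[i], resid[j], "sequence")
        }
      } else if (min_dist(res_atoms[[i]], res_atoms[[j]]) < cutoff) {
        out[[length(out) + 1]] <- c(resid[i], resid[j], "spatial")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(resid_i = integer(0), resid_j = integer(0),
                      kind = character(0)))
  }
  m <- do.call(rbind, out)
  data.frame(resid_i = as.integer(m[, 1]), resid_j = as.integer(m[, 2]),
             kind = m[, 3], stringsAsFactors = FALSE)
}

oracle_interface_contacts <- function(structure, chain_a, chain_b, cutoff) {
  pick <- function(ch) {
    sub <- structure[structure$chain == ch, , drop = FALSE]
    sub[!(sub$element %in% c("H", "D")), , drop = FALSE]
  }
  sa <- pick(chain_a); sb <- pick(chain_b)
  ra <- unique(sa$resid); rb <- unique(sb$resid)
  out <- list()
  for (i in ra) {
    A <- as.matrix(sa[sa$resid == i, c("x", "y", "z")])
    for (j in rb) {
      B <- as.matrix(sb[sb$resid == j, c("x", "y", "z")])
      d <- Inf
      for (p in seq_len(nrow(A))) for (q in seq_len(nrow(B))) {
        d <- min(d, sqrt(sum((A[p, ] - B[q, ])^2)))
      }
      if (d < cutoff) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) {
    return(data.frame(resid_i = integer(0), resid_j = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(resid_i = m[, 1], resid_j = m[, 2])
}

# Horn's quaternion method for optimal rigid superposition RMSD: an
# SVD-free route, independent of the Kabsch implementation.
oracle_quaternion_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(a, b)  # sum over points of a_i b_i^T
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(msd, 0))
}

# Explicit double-sum RMSIP, term by term.
oracle_rmsip <- function(U, V, n_modes) {
  s <- 0
  for (i in seq_len(n_modes)) {
    for (j in seq_len(n_modes)) {
      s <- s + sum(U[, i] * V[, j])^2
    }
  }
  sqrt(s / n_modes)
}

# Random orthonormal basis of k columns in d dimensions.
random_orthonormal <- function(d, k, seed) {
  withr::with_seed(seed, qr.Q(qr(matrix(rnorm(d * k), d, k))))
}

contact_key <- function(cm) {
  paste(cm$resid_i, cm$ins_i, cm$resid_j, cm$ins_j, sep = "_")
}
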