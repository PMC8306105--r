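# Shared fixtures and independent brute-force oracles used across tests.
# Everything here is deliberately naive (double loops, exhaustive merges)
# and independent of the package's vectorized implementations.

toy3 <- function() make_toy_complex(seed = 3)

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Exact rigid motion of a system's Cartesian traces (no re-projection).
rigid_system <- function(sys, R, t) {
  list(receptor = ca_xyz(sys$receptor) %*% t(R) +
         matrix(t, length(sys$receptor$seq), 3, byrow = TRUE),
       ligand = if (is.null(sys$ligand)) NULL else
         ca_xyz(sys$ligand) %*% t(R) +
         matrix(t, length(sys$ligand$seq), 3, byrow = TRUE))
}

# O(n^2) side-chain contact + hard-core energy, straight from the rules.
bf_contact_energy <- function(sc, seq, ff, chain = rep(1, nrow(sc)),
                              ca = NULL) {
  n <- nrow(sc)
  cm <- ff$contact_matrix
  core <- ff$repulsion$sc_core
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (chain[i] == chain[j] && j - i < 3) next
    d <- sqrt(sum((sc[i, ] - sc[j, ])^2))
    if (d < core) e <- e + ff$repulsion$slope * (core - d)
    else if (d <= ff$contact_cutoff) e <- e + cm[seq[i], seq[j]]
    if (!is.null(ca)) {
      dca <- sqrt(sum((ca[i, ] - ca[j, ])^2))
      if (dca < ff$repulsion$ca_core)
        e <- e + ff$repulsion$slope * (ff$repulsion$ca_core - dca)
    }
  }
  e
}

# O(n.m) reference contact map between two side-chain coordinate sets.
bf_contacts <- function(sc_r, sc_l, cutoff = 6) {
  out <- NULL
  for (i in seq_len(nrow(sc_r))) for (j in seq_len(nrow(sc_l))) {
    if (sqrt(sum((sc_r[i, ] - sc_l[j, ])^2)) <= cutoff)
      out <- rbind(out, c(i, j))
  }
  out
}

# Naive O(n^3) complete-link agglomeration down to k clusters.
bf_complete_link <- function(D, k) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(Inf, NA, NA)
    for (a in seq_len(length(groups) - 1)) for (b in (a + 1):length(groups)) {
      dmax <- max(D[groups[[a]], groups[[b]]])
      if (dmax < best[1]) best <- c(dmax, a, b)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  # canonical labels: cluster id by smallest member
  lab <- integer(n)
  ord <- order(vapply(groups, min, 1))
  for (g in seq_along(ord)) lab[groups[[ord[g]]]] <- g
  lab
}

# Canonical form of a partition (for comparing two clusterings).
partition_sets <- function(labels) {
  s <- split(seq_along(labels), labels)
  unname(s[order(vapply(s, min, 1))])
}

# Two parallel poly-glycine chains: for glycine the side-chain centre is the
# C-alpha itself, so inter-chain contact distances are controlled exactly by
# the lattice offset (units of 0.61 A).
gly_pair <- function(dy_units) {
  lat <- lattice_spec()
  n <- 6
  ca_a <- cbind(6L * (seq_len(n) - 1L), seq_len(n) - 1L, 0L)
  ca_b <- ca_a + matrix(c(0L, dy_units, 0L), n, 3, byrow = TRUE)
  cg_system(cg_chain(rep("G", n), ca_a, lat, "receptor"),
            cg_chain(rep("G", n), ca_b, lat, "ligand"))
}

# Minimal hand-written PDB text for parser tests.
pdb_line <- function(serial, name, res3, chain, resno, icode, x, y, z) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
          serial, name, res3, chain, resno, icode, x, y, z)
}
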