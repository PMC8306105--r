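# Internal mutable sampler state: flat arrays over all residues of the
# system, cached pseudo-atoms and an incrementally maintained energy
# decomposition. Kept in an environment so moves mutate in place. The
# footprint machinery below recomputes exactly the energy terms a move can
# touch, once before and once after the coordinate write, so the cached
# decomposition stays exact up to floating-point addition.

#' Build a sampler state from a docking system
#'
#' Compiles a [cg_system()], force field and restraint sets into the flat
#' mutable representation used by the Monte Carlo engine, with cached
#' pseudo-atoms and energy decomposition. Mostly internal, but exported so
#' move proposals and incremental energies can be exercised directly.
#'
#' @param system a [cg_system()].
#' @param ff force field.
#' @param rsets list of `restraint_set`s (evaluated on the molecule each
#'   names).
#' @return A `sampler_state` environment.
#' @export
sampler_state <- function(system, ff = default_forcefield(), rsets = list()) {
  stopifnot(inherits(system, "cg_system"))
  chains <- Filter(Negate(is.null), list(receptor = system$receptor,
                                         ligand = system$ligand))
  nres <- vapply(chains, function(c) length(c$seq), 1L)
  n <- sum(nres)
  st <- new.env(parent = emptyenv())
  st$lattice <- chains[[1]]$lattice
  st$sp <- st$lattice$spacing
  st$n <- n
  st$nch <- length(chains)
  st$chain <- rep(seq_along(chains), nres)
  st$chain_start <- cumsum(c(1L, nres[-length(nres)]))
  st$chain_end <- cumsum(nres)
  st$roles <- names(chains)
  st$seqs <- lapply(chains, `[[`, "seq")
  st$aa <- unlist(lapply(st$seqs, aa_index), use.names = FALSE)
  st$ca <- do.call(rbind, lapply(chains, `[[`, "ca"))
  st$caA <- st$ca * st$sp
  st$occ <- vec_key(st$ca)
  if (anyDuplicated(st$occ)) stop("system violates bead excluded volume")

  # force-field scalars unpacked for the hot path
  st$ff <- ff
  st$cm <- ff$contact_matrix
  st$cutoff <- ff$contact_cutoff
  st$sc_core <- ff$repulsion$sc_core
  st$ca_core <- ff$repulsion$ca_core
  st$rep_slope <- ff$repulsion$slope
  hp <- ff$hbond_params
  st$hb_depth <- hp$depth; st$hb_win <- hp$window
  st$hb_align <- hp$align; st$hb_sep <- hp$min_sep
  lb <- ff$local_bias_params
  st$lb_dw <- lb$dihedral_windows; st$lb_aw <- lb$angle_window
  st$lb_pen <- lb$penalty
  # per-residue C-beta tilt data
  st$dsc <- SC_DISTANCE[st$aa]
  st$is_gly <- st$aa == match("G", AA_CODES)

  # restraints flattened to global indices, weights pre-scaled
  ri <- integer(0); rj <- integer(0); rd0 <- rtol <- rw <- numeric(0)
  for (rset in rsets) {
    m <- match(rset$molecule, st$roles)
    if (is.na(m)) stop("restraint set names absent molecule: ", rset$molecule)
    off <- st$chain_start[m] - 1L
    r <- rset$restraints
    ri <- c(ri, r$i + off); rj <- c(rj, r$j + off)
    rd0 <- c(rd0, r$d0); rtol <- c(rtol, r$tol)
    rw <- c(rw, r$weight * rset$weight_scale)
  }
  st$r_i <- ri; st$r_j <- rj; st$r_d0 <- rd0; st$r_tol <- rtol; st$r_w <- rw
  st$res2restr <- lapply(seq_len(n), function(i) which(ri == i | rj == i))

  st$sc <- matrix(0, n, 3); st$cb <- matrix(0, n, 3)
  st$pb <- matrix(0, n, 3); st$ubv <- matrix(0, n, 3)
  st$pb_ok <- rep(FALSE, n)
  for (c in seq_len(st$nch)) refresh_chain_pseudo(st, c)
  st$cand_cache <- new.env(parent = emptyenv())
  st$energy <- state_full_energy(st)
  class(st) <- c("sampler_state", "environment")
  st
}

#' @export
print.sampler_state <- function(x, ...) {
  cat(sprintf("<sampler_state> %d residues in %d chain(s), E = %.3f kT\n",
              x$n, x$nch, x$energy$total))
  invisible(x)
}

# Recompute cached pseudo-atoms (sc, cb, pb, unit bond vectors) for one
# whole chain, without re-validating the sequence. Must place side chains
# exactly as rebuild_pseudo_atoms() does.
refresh_chain_pseudo <- function(st, c) {
  idx <- st$chain_start[c]:st$chain_end[c]
  xyz <- st$caA[idx, , drop = FALSE]
  dir <- cb_directions(xyz)
  cb <- xyz + CB_DISTANCE * dir
  g <- st$is_gly[idx]
  if (any(g)) cb[g, ] <- xyz[g, , drop = FALSE]
  sc <- xyz + st$dsc[idx] * dir
  st$cb[idx, ] <- cb
  st$sc[idx, ] <- sc
  nl <- length(idx)
  bidx <- idx[-nl]
  bv <- xyz[-1L, , drop = FALSE] - xyz[-nl, , drop = FALSE]
  st$pb[bidx, ] <- (xyz[-1L, , drop = FALSE] + xyz[-nl, , drop = FALSE]) / 2
  st$ubv[bidx, ] <- bv / sqrt(rowSums(bv^2))
  st$pb_ok[idx] <- c(rep(TRUE, nl - 1L), FALSE)
  invisible(st)
}

#' Extract the current conformation of a sampler state
#'
#' @param st a `sampler_state`.
#' @return A [cg_system()].
#' @export
state_system <- function(st) {
  mk <- function(c, role) {
    idx <- st$chain_start[c]:st$chain_end[c]
    cg_chain(st$seqs[[c]], st$ca[idx, , drop = FALSE], st$lattice, role)
  }
  rec <- mk(1L, "receptor")
  lig <- if (st$nch > 1L) mk(2L, "ligand") else NULL
  cg_system(rec, lig)
}

# ---- full (from scratch) energy of a state, via the public energy surface

state_full_energy <- function(st) {
  bv_rows <- which(st$pb_ok)
  e_local <- local_bias_energy(st$caA, NULL, st$ff, st$chain)
  bv_raw <- st$caA[bv_rows + 1L, , drop = FALSE] -
    st$caA[bv_rows, , drop = FALSE]
  e_hb <- hbond_energy(st$pb[bv_rows, , drop = FALSE], st$ff,
                       bond_vectors = bv_raw,
                       chain = st$chain[bv_rows])
  seq_all <- unlist(st$seqs, use.names = FALSE)
  e_ct <- contact_energy(st$sc, seq_all, st$ff, st$chain, ca = st$caA)
  e_rs <- if (length(st$r_i))
    sum(st$r_w * pmax(0, abs(sqrt(rowSums(
      (st$caA[st$r_i, , drop = FALSE] - st$caA[st$r_j, , drop = FALSE])^2
    )) - st$r_d0) - st$r_tol))
  else 0
  energy_breakdown(e_local, e_hb, e_ct, e_rs)
}

# ---- footprint (incremental) energy --------------------------------------

# Index sets and eligibility masks for the terms a move touching C-alphas A
# can change. Coordinate-independent, so computed once per move and reused
# for the before/after evaluations.
footprint_ctx <- function(st, A) {
  chain <- st$chain
  n <- st$n
  # side chains whose frame may involve a moved C-alpha (frame of i uses
  # i-1..i+1; termini borrow the neighbour frame, hence +/- 2)
  S <- integer(0); Q <- integer(0)
  for (a in A) {
    c <- chain[a]
    S <- c(S, max(st$chain_start[c], a - 2L):min(st$chain_end[c], a + 2L))
    lo <- max(st$chain_start[c], a - 3L)
    hi <- min(a, st$chain_end[c] - 3L)
    if (lo <= hi) Q <- c(Q, lo:hi)
  }
  S <- sort(unique(S)); Q <- sort(unique(Q))
  m <- length(S)
  # eligibility (different chain, or sequence separation >= 3)
  elig_ct <- matrix(chain[S], m, n) != matrix(chain, m, n, byrow = TRUE) |
    abs(matrix(S, m, n) - matrix(seq_len(n), m, n, byrow = TRUE)) >= 3L
  # contact-matrix values for all (S, .) pairs
  cm_S <- matrix(st$cm[cbind(rep(st$aa[S], n), rep(st$aa, each = m))], m, n)
  # peptide bonds whose centre or direction may change
  P <- sort(unique(c(A - 1L, A)))
  P <- P[P >= 1L]
  P <- P[st$pb_ok[P]]
  all_b <- which(st$pb_ok)
  mp <- length(P)
  elig_hb <- if (mp) {
    matrix(chain[P], mp, length(all_b)) !=
      matrix(chain[all_b], mp, length(all_b), byrow = TRUE) |
      abs(matrix(P, mp, length(all_b)) -
            matrix(all_b, mp, length(all_b), byrow = TRUE)) >= st$hb_sep
  } else NULL
  rr <- unique(unlist(st$res2restr[A], use.names = FALSE))
  list(A = A, S = S, Q = Q, P = P, all_b = all_b, rr = rr,
       elig_ct = elig_ct, cm_S = cm_S, elig_hb = elig_hb,
       S_col = S, P_col = match(P, all_b))
}

footprint_energy <- function(st, ctx) {
  e_local <- if (length(ctx$Q)) quad_energy(st, ctx$Q) else 0
  e_hb <- if (length(ctx$P)) hb_pairs_energy(st, ctx) else 0
  e_ct <- contact_pairs_energy(st, ctx)
  e_rs <- if (length(ctx$rr)) {
    rr <- ctx$rr
    d <- sqrt(rowSums((st$caA[st$r_i[rr], , drop = FALSE] -
                         st$caA[st$r_j[rr], , drop = FALSE])^2))
    sum(st$r_w[rr] * pmax(0, abs(d - st$r_d0[rr]) - st$r_tol[rr]))
  } else 0
  c(local = e_local, hbond = e_hb, contact = e_ct, restraint = e_rs)
}

# Local-bias terms of the 4-mers starting at Q: same kernel as the public
# term (see quad_bias_energy) so the incremental and full paths agree bit
# for bit.
quad_energy <- function(st, Q) {
  quad_bias_energy(st$caA, Q,
                   list(dihedral_windows = st$lb_dw, angle_window = st$lb_aw,
                        penalty = st$lb_pen))
}

# Pairwise distance matrix between a row subset and all rows, computed from
# coordinate differences so that each pair's arithmetic is bit-identical to
# the full-recomputation path (sqrt(dx^2 + dy^2 + dz^2) in fixed order);
# norm-expansion forms can classify pairs sitting exactly on a geometric
# threshold differently and silently desynchronize the energy cache.
pair_dist <- function(xs, x) {
  dx <- outer(xs[, 1], x[, 1], `-`)
  dy <- outer(xs[, 2], x[, 2], `-`)
  dz <- outer(xs[, 3], x[, 3], `-`)
  sqrt(dx * dx + dy * dy + dz * dz)
}

hb_pairs_energy <- function(st, ctx) {
  P <- ctx$P; all_b <- ctx$all_b
  d <- pair_dist(st$pb[P, , drop = FALSE], st$pb[all_b, , drop = FALSE])
  ok <- ctx$elig_hb & d >= st$hb_win[1] & d <= st$hb_win[2]
  if (st$hb_align > 0 && any(ok)) {
    uP <- st$ubv[P, , drop = FALSE]
    uA <- st$ubv[all_b, , drop = FALSE]
    cosang <- outer(uP[, 1], uA[, 1]) + outer(uP[, 2], uA[, 2]) +
      outer(uP[, 3], uA[, 3])
    ok <- ok & abs(cosang) >= st$hb_align
  }
  tot <- sum(ok)
  within <- sum(ok[, ctx$P_col, drop = FALSE])
  -st$hb_depth * (tot - within / 2)
}

contact_pairs_energy <- function(st, ctx) {
  S <- ctx$S
  d <- pair_dist(st$sc[S, , drop = FALSE], st$sc)
  Tm <- ctx$cm_S * (ctx$elig_ct & d >= st$sc_core & d <= st$cutoff)
  repm <- ctx$elig_ct & d < st$sc_core
  if (any(repm)) Tm[repm] <- Tm[repm] + st$rep_slope * (st$sc_core - d[repm])
  dca <- pair_dist(st$caA[S, , drop = FALSE], st$caA)
  repc <- ctx$elig_ct & dca < st$ca_core
  if (any(repc))
    Tm[repc] <- Tm[repc] + st$rep_slope * (st$ca_core - dca[repc])
  sum(Tm) - sum(Tm[, ctx$S_col, drop = FALSE]) / 2
}

# ---- applying and reverting moves ----------------------------------------

# Attempt to write new C-alpha rows; returns NULL on an excluded-volume
# violation, otherwise the undo record plus the energy delta (by component).
state_try_move <- function(st, A, new_ca) {
  new_keys <- vec_key(new_ca)
  if (anyDuplicated(new_keys)) return(NULL)
  others <- st$occ[-A]
  if (any(new_keys %in% others)) return(NULL)
  ctx <- footprint_ctx(st, A)
  e_old <- footprint_energy(st, ctx)
  chains_touched <- unique(st$chain[A])
  idx_all <- unlist(lapply(chains_touched, function(c)
    st$chain_start[c]:st$chain_end[c]), use.names = FALSE)
  undo <- list(
    A = A, ca = st$ca[A, , drop = FALSE], caA = st$caA[A, , drop = FALSE],
    occ = st$occ[A], idx = idx_all,
    sc = st$sc[idx_all, , drop = FALSE], cb = st$cb[idx_all, , drop = FALSE],
    pb = st$pb[idx_all, , drop = FALSE], ubv = st$ubv[idx_all, , drop = FALSE]
  )
  st$ca[A, ] <- new_ca
  st$caA[A, ] <- new_ca * st$sp
  st$occ[A] <- new_keys
  for (c in chains_touched) refresh_chain_pseudo(st, c)
  e_new <- footprint_energy(st, ctx)
  list(undo = undo, delta = e_new - e_old)
}

state_revert <- function(st, undo) {
  st$ca[undo$A, ] <- undo$ca
  st$caA[undo$A, ] <- undo$caA
  st$occ[undo$A] <- undo$occ
  st$sc[undo$idx, ] <- undo$sc
  st$cb[undo$idx, ] <- undo$cb
  st$pb[undo$idx, ] <- undo$pb
  st$ubv[undo$idx, ] <- undo$ubv
  invisible(st)
}

state_commit <- function(st, delta) {
  e <- st$energy
  st$energy <- energy_breakdown(e$local + delta[["local"]],
                                e$hbond + delta[["hbond"]],
                                e$contact + delta[["contact"]],
                                e$restraint + delta[["restraint"]])
  invisible(st)
}
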