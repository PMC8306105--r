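# Monte Carlo move set: local lattice movers plus rigid-body ligand moves.

#' Default Monte Carlo move set
#'
#' Proposal kinds and weights for the sampler: `single` (re-place one
#' interior bead between its neighbours), `shift2` (displace two adjacent
#' beads by one small lattice vector), `end` (re-grow a terminal bead),
#' and the rigid whole-ligand movers `lig_translate` (small lattice
#' translation) and `lig_rotate` (90-degree lattice rotation about the
#' ligand's middle bead). All proposal distributions are symmetric, so the
#' plain Metropolis criterion applies. For single-chain systems the ligand
#' movers are dropped and weights renormalized.
#'
#' @param weights named numeric vector of proposal weights (positive; they
#'   are normalized internally).
#' @return A `moveset` object.
#' @export
default_moveset <- function(weights = c(single = 0.55, shift2 = 0.2,
                                        end = 0.1, lig_translate = 0.1,
                                        lig_rotate = 0.05)) {
  known <- c("single", "shift2", "end", "lig_translate", "lig_rotate")
  stopifnot(all(names(weights) %in% known), all(weights > 0))
  structure(list(weights = weights / sum(weights)), class = "moveset")
}

#' @export
print.moveset <- function(x, ...) {
  cat("<moveset>", paste(sprintf("%s %.2f", names(x$weights), x$weights),
                         collapse = ", "), "\n")
  invisible(x)
}

# Small displacement vectors for shift/translation moves: all nonzero
# integer vectors of squared norm <= 4 (closed under negation -> symmetric).
shift_vectors <- function() {
  g <- -2:2
  v <- as.matrix(expand.grid(g, g, g))
  v <- v[rowSums(v^2) > 0 & rowSums(v^2) <= 4, , drop = FALSE]
  dimnames(v) <- NULL
  storage.mode(v) <- "integer"
  v
}

# The 23 proper cubic rotations (24-element rotation group minus identity);
# closed under inversion, and the lattice's allowed-vector set is invariant
# under each of them.
cubic_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    P <- diag(3)[p, ]
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      R <- P * c(s1, s2, s3)
      if (abs(det(R) - 1) < 1e-9 && !all(R == diag(3))) {
        Ri <- R; storage.mode(Ri) <- "integer"
        out[[length(out) + 1L]] <- Ri
      }
    }
  }
  out
}

# Precompile move machinery for a state: candidate pools per mover kind.
resolve_moveset <- function(st, moveset) {
  w <- moveset$weights
  if (st$nch < 2L)
    w <- w[!names(w) %in% c("lig_translate", "lig_rotate")]
  w <- w / sum(w)
  interior <- which(!(seq_len(st$n) %in% c(st$chain_start, st$chain_end)))
  shift_i <- unlist(lapply(seq_len(st$nch), function(c)
    if (st$chain_end[c] > st$chain_start[c])
      st$chain_start[c]:(st$chain_end[c] - 1L) else integer(0)))
  ends <- c(st$chain_start, st$chain_end)
  lig <- if (st$nch > 1L) st$chain_start[2]:st$chain_end[2] else integer(0)
  list(
    kinds = names(w), cum = cumsum(w),
    interior = interior, shift_i = shift_i, ends = ends,
    lig = lig,
    lig_pivot = if (length(lig)) lig[ceiling(length(lig) / 2)] else NA_integer_,
    shifts = shift_vectors(), rots = cubic_rotations(),
    V = st$lattice$vectors
  )
}

# Draw one proposal. Returns NULL for an auto-rejected (invalid/empty)
# proposal, else list(kind, A, new_ca).
draw_proposal <- function(st, mv) {
  kind <- mv$kinds[findInterval(stats::runif(1), c(0, mv$cum),
                                rightmost.closed = TRUE)]
  switch(kind,
    single = {
      if (!length(mv$interior)) return(NULL)
      i <- mv$interior[sample.int(length(mv$interior), 1L)]
      prev <- st$ca[i - 1L, ]; nxt <- st$ca[i + 1L, ]
      d <- nxt - prev
      # memoize the valid bridging offsets per end-to-end displacement
      key <- as.character((d[1] + LAT_B) + LAT_M * ((d[2] + LAT_B) +
                                                      LAT_M * (d[3] + LAT_B)))
      offs <- st$cand_cache[[key]]
      if (is.null(offs)) {
        ok <- key_is_allowed(vec_key(matrix(d, nrow(mv$V), 3L, byrow = TRUE) -
                                       mv$V), st$lattice)
        offs <- mv$V[ok, , drop = FALSE]
        st$cand_cache[[key]] <- offs
      }
      if (!nrow(offs)) return(NULL)
      list(kind = kind, A = i,
           new_ca = matrix(prev + offs[sample.int(nrow(offs), 1L), ], 1L, 3L))
    },
    shift2 = {
      if (!length(mv$shift_i)) return(NULL)
      i <- mv$shift_i[sample.int(length(mv$shift_i), 1L)]
      dl <- mv$shifts[sample.int(nrow(mv$shifts), 1L), ]
      c0 <- st$chain[i]
      new2 <- rbind(st$ca[i, ] + dl, st$ca[i + 1L, ] + dl)
      if (i > st$chain_start[c0] &&
          !key_is_allowed(vec_key(matrix(new2[1, ] - st$ca[i - 1L, ], 1, 3)),
                          st$lattice)) return(NULL)
      if (i + 1L < st$chain_end[c0] &&
          !key_is_allowed(vec_key(matrix(st$ca[i + 2L, ] - new2[2, ], 1, 3)),
                          st$lattice)) return(NULL)
      list(kind = kind, A = c(i, i + 1L), new_ca = new2)
    },
    end = {
      i <- mv$ends[sample.int(length(mv$ends), 1L)]
      nb <- if (i %in% st$chain_start) i + 1L else i - 1L
      v <- mv$V[sample.int(nrow(mv$V), 1L), ]
      list(kind = kind, A = i,
           new_ca = matrix(st$ca[nb, ] + v, 1, 3))
    },
    lig_translate = {
      dl <- mv$shifts[sample.int(nrow(mv$shifts), 1L), ]
      list(kind = kind, A = mv$lig,
           new_ca = st$ca[mv$lig, , drop = FALSE] +
             matrix(dl, length(mv$lig), 3L, byrow = TRUE))
    },
    lig_rotate = {
      R <- mv$rots[[sample.int(length(mv$rots), 1L)]]
      piv <- st$ca[mv$lig_pivot, ]
      rel <- st$ca[mv$lig, , drop = FALSE] -
        matrix(piv, length(mv$lig), 3L, byrow = TRUE)
      list(kind = kind, A = mv$lig,
           new_ca = rel %*% t(R) + matrix(piv, length(mv$lig), 3L, byrow = TRUE))
    }
  )
}

#' Propose one Monte Carlo move on a sampler state
#'
#' Draws a mover kind and a candidate conformation, evaluates the exact
#' energy change of the proposal and reverts the state, leaving it
#' untouched. Proposals violating lattice bonds or bead excluded volume are
#' returned as invalid (they count as rejections in the sampler).
#'
#' @param st a [sampler_state()].
#' @param moveset a [default_moveset()].
#' @return List with `valid`, and when valid: `kind`, `residues` (moved
#'   C-alpha indices), `new_ca` (their proposed lattice coordinates) and
#'   `delta_e` (energy change by component, kT).
#' @export
propose_move <- function(st, moveset = default_moveset()) {
  mv <- resolve_moveset(st, moveset)
  pr <- draw_proposal(st, mv)
  if (is.null(pr)) return(list(valid = FALSE))
  res <- state_try_move(st, pr$A, pr$new_ca)
  if (is.null(res)) return(list(valid = FALSE, kind = pr$kind))
  state_revert(st, res$undo)
  list(valid = TRUE, kind = pr$kind, residues = pr$A, new_ca = pr$new_ca,
       delta_e = res$delta)
}

# One Monte Carlo sweep: n move attempts with Metropolis acceptance at the
# given temperature. Mutates the state; returns the number accepted.
sweep_state <- function(st, temp, mv) {
  acc <- 0L
  for (k in seq_len(st$n)) {
    pr <- draw_proposal(st, mv)
    if (is.null(pr)) next
    res <- state_try_move(st, pr$A, pr$new_ca)
    if (is.null(res)) next
    de <- sum(res$delta)
    if (de <= 0 || stats::runif(1) < exp(-de / temp)) {
      state_commit(st, res$delta)
      acc <- acc + 1L
    } else {
      state_revert(st, res$undo)
    }
  }
  acc
}
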