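#' Define the fine cubic lattice underlying C-alpha traces
#'
#' The model confines C-alpha positions to a fine cubic grid. Consecutive
#' C-alpha beads may be joined only by vectors from a finite set of integer
#' displacements whose physical length falls inside a narrow band around the
#' canonical 3.8 A virtual bond, so the trace keeps near-protein geometry
#' while moves remain local and discrete.
#'
#' @param spacing grid unit in Angstrom. The default 0.61 A gives a dense set
#'   of allowed bond orientations.
#' @param min_bond,max_bond bond-length band in Angstrom; allowed vectors are
#'   all integer triples whose scaled Euclidean length lies in
#'   `[min_bond, max_bond]`.
#' @return A `lattice_spec` object: list with `spacing`, `min_bond`,
#'   `max_bond`, the `vectors` matrix (one allowed displacement per row) and
#'   an internal key table for O(1) membership tests.
#' @examples
#' lat <- lattice_spec()
#' nrow(lat$vectors)  # size of the allowed-vector set
#' @export
lattice_spec <- function(spacing = 0.61, min_bond = 3.5, max_bond = 4.1) {
  stopifnot(spacing > 0, min_bond > 0, min_bond < max_bond)
  rmax <- ceiling(max_bond / spacing)
  g <- seq.int(-rmax, rmax)
  v <- as.matrix(expand.grid(x = g, y = g, z = g))
  len <- sqrt(rowSums(v^2)) * spacing
  v <- v[len >= min_bond & len <= max_bond, , drop = FALSE]
  dimnames(v) <- NULL
  storage.mode(v) <- "integer"
  # canonical deterministic order
  v <- v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
  spec <- list(
    spacing = spacing, min_bond = min_bond, max_bond = max_bond,
    vectors = v, keys = sort(vec_key(v))
  )
  class(spec) <- "lattice_spec"
  spec
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf(
    "<lattice_spec> spacing %.3f A, bond band [%.2f, %.2f] A, %d allowed vectors\n",
    x$spacing, x$min_bond, x$max_bond, nrow(x$vectors)
  ))
  invisible(x)
}

# Encode integer lattice triples as scalar keys (exact in doubles for
# coordinates within +/- 2047 grid units, i.e. +/- 1.2 kA at default spacing).
LAT_B <- 2048
LAT_M <- 4096

vec_key <- function(v) {
  (v[, 1] + LAT_B) + LAT_M * ((v[, 2] + LAT_B) + LAT_M * (v[, 3] + LAT_B))
}

key_is_allowed <- function(keys, lattice) {
  # lattice$keys is sorted; binary search via findInterval
  pos <- findInterval(keys, lattice$keys)
  pos > 0 & lattice$keys[pmax(pos, 1L)] == keys
}

#' Project a Cartesian C-alpha trace onto the lattice
#'
#' Greedy bead-by-bead fit: the first bead is rounded to the nearest grid
#' point; each subsequent bead is placed at the allowed-vector successor of
#' the previous bead that is closest to the input coordinate, skipping
#' positions already occupied (bead-level excluded volume). An input already
#' on the lattice with allowed bonds reproduces itself exactly; realistic
#' protein traces project with sub-Angstrom distortion.
#'
#' @param ca_xyz numeric n x 3 matrix of C-alpha coordinates in Angstrom.
#' @param seq one-letter amino-acid sequence (string or character vector) of
#'   length n; defaults to poly-alanine.
#' @param lattice a [lattice_spec()].
#' @param role `"receptor"` or `"ligand"`.
#' @return A `cg_chain` (see [cg_chain()]).
#' @export
project_to_lattice <- function(ca_xyz, seq = NULL, lattice = lattice_spec(),
                               role = c("receptor", "ligand")) {
  role <- match.arg(role)
  ca_xyz <- as_coord_matrix(ca_xyz)
  n <- nrow(ca_xyz)
  if (n < 4L)
    stop("chain too short: need at least 4 residues, got ", n)
  d <- sqrt(rowSums((ca_xyz[-1, , drop = FALSE] - ca_xyz[-n, , drop = FALSE])^2))
  bad <- which(d < 2.8 | d > 4.6)
  if (length(bad))
    stop(sprintf(
      "broken chain: C-alpha distance %.2f A between residues %d and %d is outside [2.8, 4.6] A",
      d[bad[1]], bad[1], bad[1] + 1L
    ))
  if (is.null(seq)) seq <- rep("A", n)
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  if (length(seq) != n) stop("sequence length does not match coordinates")
  aa_index(seq)  # validate

  sp <- lattice$spacing
  V <- lattice$vectors
  lat <- matrix(0L, n, 3L)
  lat[1L, ] <- as.integer(round(ca_xyz[1L, ] / sp))
  occ <- numeric(n)
  occ[1L] <- vec_key(lat[1L, , drop = FALSE])
  for (i in 2:n) {
    cand <- V + matrix(lat[i - 1L, ], nrow(V), 3L, byrow = TRUE)
    keys <- vec_key(cand)
    free <- !(keys %in% occ[seq_len(i - 1L)])
    if (!any(free))
      stop("lattice projection failed at residue ", i, ": all candidate sites occupied")
    cand <- cand[free, , drop = FALSE]
    err <- rowSums((cand * sp - matrix(ca_xyz[i, ], nrow(cand), 3L, byrow = TRUE))^2)
    lat[i, ] <- cand[which.min(err), ]  # which.min is deterministic on ties
    occ[i] <- vec_key(lat[i, , drop = FALSE])
  }
  cg_chain(seq = seq, ca = lat, lattice = lattice, role = role)
}

as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be an n x 3 matrix")
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}
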