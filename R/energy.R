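#' Generate flat-bottom C-alpha distance restraints from an input structure
#'
#' Restrains exactly the residue pairs that are (a) at least `min_seq_sep`
#' apart along the sequence and (b) whose C-alpha distance in the input lies
#' inside `[dmin, dmax]`; the observed distance becomes the flat-bottom
#' reference `d0`. During docking the receptor gets full-weight restraints
#' and the ligand the same scheme at tenfold weaker weights, which keeps the
#' receptor backbone near-rigid while the ligand may refold.
#'
#' @param ca_xyz numeric n x 3 C-alpha matrix (Angstrom).
#' @param min_seq_sep minimum sequence separation (residues); default 5.
#' @param dmin,dmax distance window for restrained pairs (Angstrom);
#'   defaults 5 and 15.
#' @param weight penalty weight, kT per Angstrom of violation. The default
#'   (12) is calibrated so that a fully restrained receptor fluctuates by
#'   about 1 A backbone RMSF at the coldest default ladder temperature;
#'   much of that residual fluctuation lives inside the +/- 1 A flat
#'   bottom, which no weight can suppress.
#' @param tol flat-bottom half-width (Angstrom); default 1.
#' @param molecule `"receptor"` or `"ligand"`.
#' @param weight_scale multiplier on all member weights; defaults to 1 for
#'   the receptor and 0.1 for the ligand.
#' @return A `restraint_set`: list with a tibble `restraints`
#'   (columns i, j, d0, tol, weight), `molecule` and `weight_scale`.
#' @examples
#' h <- helix_ca(20)
#' rs <- generate_restraints(h)
#' nrow(rs$restraints)
#' @export
generate_restraints <- function(ca_xyz, min_seq_sep = 5L, dmin = 5, dmax = 15,
                                weight = 12, tol = 1,
                                molecule = c("receptor", "ligand"),
                                weight_scale = NULL) {
  molecule <- match.arg(molecule)
  ca_xyz <- as_coord_matrix(ca_xyz)
  n <- nrow(ca_xyz)
  stopifnot(dmin < dmax, tol > 0, weight >= 0)
  if (n < min_seq_sep + 1L)
    stop("chain shorter than min_seq_sep + 1")
  if (is.null(weight_scale))
    weight_scale <- if (molecule == "receptor") 1.0 else 0.1
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep_ok <- pr[, 2] - pr[, 1] >= min_seq_sep
  pr <- pr[sep_ok, , drop = FALSE]
  d <- sqrt(rowSums((ca_xyz[pr[, 1], , drop = FALSE] -
                       ca_xyz[pr[, 2], , drop = FALSE])^2))
  keep <- d >= dmin & d <= dmax
  rs <- tibble::tibble(
    i = as.integer(pr[keep, 1]), j = as.integer(pr[keep, 2]),
    d0 = d[keep], tol = tol, weight = weight
  )
  rs <- rs[order(rs$i, rs$j), ]
  if (!nrow(rs))
    warning("no residue pair satisfies the restraint-generation window; empty restraint set")
  structure(list(restraints = rs, molecule = molecule,
                 weight_scale = weight_scale),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %s, %d restraints, weight scale %.2g\n",
              x$molecule, nrow(x$restraints), x$weight_scale))
  invisible(x)
}

#' Flat-bottom restraint energy
#'
#' Zero while every restrained distance stays within `d0 +/- tol`; outside
#' the flat bottom each restraint contributes
#' `weight * weight_scale * (|d - d0| - tol)` (linear, continuous in d).
#'
#' @param ca_xyz C-alpha coordinates (Angstrom) of the restrained molecule.
#' @param rset a `restraint_set` from [generate_restraints()].
#' @return Energy in kT (non-negative).
#' @export
restraint_energy <- function(ca_xyz, rset) {
  ca_xyz <- as_coord_matrix(ca_xyz)
  r <- rset$restraints
  if (!nrow(r)) return(0)
  if (max(r$j) > nrow(ca_xyz)) stop("restraint index exceeds chain length")
  d <- sqrt(rowSums((ca_xyz[r$i, , drop = FALSE] -
                       ca_xyz[r$j, , drop = FALSE])^2))
  sum(r$weight * rset$weight_scale * pmax(0, abs(d - r$d0) - r$tol))
}

#' Side-chain contact energy
#'
#' Pairwise-additive sum over eligible side-chain pairs: pairs from different
#' chains, or pairs of the same chain at sequence separation of at least 3.
#' A pair inside the contact cutoff but outside the hard core contributes its
#' contact-matrix energy; a pair inside the hard core contributes a linear
#' repulsive penalty instead. If C-alpha coordinates are supplied, the same
#' linear hard-core penalty is added for C-alpha pairs (bead-level soft
#' excluded volume).
#'
#' @param sc n x 3 matrix of united side-chain centres (Angstrom).
#' @param seq one-letter sequence (length n).
#' @param ff a [default_forcefield()] object.
#' @param chain integer chain id per residue (contiguous blocks); default one
#'   chain.
#' @param ca optional n x 3 C-alpha matrix for the C-alpha repulsion term.
#' @return Energy in kT.
#' @export
contact_energy <- function(sc, seq, ff = default_forcefield(), chain = NULL,
                           ca = NULL) {
  sc <- as_coord_matrix(sc)
  n <- nrow(sc)
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  ai <- aa_index(seq)
  if (is.null(chain)) chain <- rep(1L, n)
  if (n < 2L) return(0)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  elig <- chain[pr[, 1]] != chain[pr[, 2]] | (pr[, 2] - pr[, 1]) >= 3L
  pr <- pr[elig, , drop = FALSE]
  if (!nrow(pr)) return(0)
  d <- sqrt(rowSums((sc[pr[, 1], , drop = FALSE] - sc[pr[, 2], , drop = FALSE])^2))
  core <- ff$repulsion$sc_core
  e <- sum(ff$contact_matrix[cbind(ai[pr[, 1]], ai[pr[, 2]])][
    d >= core & d <= ff$contact_cutoff]) +
    sum(ff$repulsion$slope * (core - d[d < core]))
  if (!is.null(ca)) {
    ca <- as_coord_matrix(ca)
    dca <- sqrt(rowSums((ca[pr[, 1], , drop = FALSE] -
                           ca[pr[, 2], , drop = FALSE])^2))
    e <- e + sum(ff$repulsion$slope * (ff$repulsion$ca_core -
                                         dca[dca < ff$repulsion$ca_core]))
  }
  e
}

#' Main-chain hydrogen-bond energy
#'
#' Each eligible pair of peptide-bond centres whose distance falls inside the
#' geometric window — and, when bond vectors are supplied, whose C-alpha bond
#' vectors are sufficiently parallel or antiparallel — contributes one well
#' depth. Eligible pairs are separated by at least `min_sep` bonds within a
#' chain; all inter-chain pairs are eligible.
#'
#' @param pb m x 3 matrix of peptide-bond centres (Angstrom).
#' @param ff force field.
#' @param bond_vectors optional m x 3 matrix of the corresponding C-alpha
#'   bond vectors (used for the alignment criterion).
#' @param chain integer chain id per bond; default one chain.
#' @return Energy in kT (non-positive).
#' @export
hbond_energy <- function(pb, ff = default_forcefield(), bond_vectors = NULL,
                         chain = NULL) {
  pb <- as_coord_matrix(pb)
  m <- nrow(pb)
  if (m < 2L) return(0)
  if (is.null(chain)) chain <- rep(1L, m)
  hp <- ff$hbond_params
  pr <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  elig <- chain[pr[, 1]] != chain[pr[, 2]] | (pr[, 2] - pr[, 1]) >= hp$min_sep
  pr <- pr[elig, , drop = FALSE]
  if (!nrow(pr)) return(0)
  d <- sqrt(rowSums((pb[pr[, 1], , drop = FALSE] - pb[pr[, 2], , drop = FALSE])^2))
  ok <- d >= hp$window[1] & d <= hp$window[2]
  if (!is.null(bond_vectors)) {
    bv <- as_coord_matrix(bond_vectors)
    bv <- bv / sqrt(rowSums(bv^2))
    cosang <- rowSums(bv[pr[, 1], , drop = FALSE] * bv[pr[, 2], , drop = FALSE])
    ok <- ok & abs(cosang) >= hp$align
  }
  -hp$depth * sum(ok)
}

#' Short-range main-chain conformational bias
#'
#' Additive over complete backbone 4-mers of each chain: a 4-mer pays a
#' penalty when its C-alpha pseudo-dihedral lies outside all preferred
#' windows (right-handed helical or extended), and another when the
#' pseudo-angle at its second vertex leaves the admissible band. Chains
#' shorter than 4 residues contribute nothing.
#'
#' @param ca n x 3 C-alpha matrix (Angstrom).
#' @param seq sequence (currently unused by the default parameters; kept in
#'   the interface for residue-specific bias tables).
#' @param ff force field.
#' @param chain integer chain id per residue.
#' @return Energy in kT (non-negative with default parameters).
#' @export
local_bias_energy <- function(ca, seq = NULL, ff = default_forcefield(),
                              chain = NULL) {
  ca <- as_coord_matrix(ca)
  n <- nrow(ca)
  if (is.null(chain)) chain <- rep(1L, n)
  lb <- ff$local_bias_params
  e <- 0
  for (cid in unique(chain)) {
    xyz <- ca[chain == cid, , drop = FALSE]
    nc <- nrow(xyz)
    if (nc < 4L) next
    e <- e + quad_bias_energy(xyz, seq_len(nc - 3L), lb)
  }
  e
}

# Shared local-bias kernel: penalty of the 4-mers starting at rows Q of x
# (dihedral outside all windows; pseudo-angle at the second vertex outside
# the angle band). Both the public term and the sampler's incremental path
# call this one function, so threshold classifications can never diverge
# between them.
quad_bias_energy <- function(x, Q, lb) {
  i1 <- Q; i2 <- Q + 1L; i3 <- Q + 2L; i4 <- Q + 3L
  b1x <- x[i2, 1] - x[i1, 1]; b1y <- x[i2, 2] - x[i1, 2]; b1z <- x[i2, 3] - x[i1, 3]
  b2x <- x[i3, 1] - x[i2, 1]; b2y <- x[i3, 2] - x[i2, 2]; b2z <- x[i3, 3] - x[i2, 3]
  b3x <- x[i4, 1] - x[i3, 1]; b3y <- x[i4, 2] - x[i3, 2]; b3z <- x[i4, 3] - x[i3, 3]
  n1x <- b1y * b2z - b1z * b2y; n1y <- b1z * b2x - b1x * b2z; n1z <- b1x * b2y - b1y * b2x
  n2x <- b2y * b3z - b2z * b3y; n2y <- b2z * b3x - b2x * b3z; n2z <- b2x * b3y - b2y * b3x
  b2n <- sqrt(b2x^2 + b2y^2 + b2z^2)
  ux <- b2x / b2n; uy <- b2y / b2n; uz <- b2z / b2n
  m1x <- uy * n1z - uz * n1y; m1y <- uz * n1x - ux * n1z; m1z <- ux * n1y - uy * n1x
  phi <- atan2(m1x * n2x + m1y * n2y + m1z * n2z,
               n1x * n2x + n1y * n2y + n1z * n2z) * 180 / pi
  in_dw <- rep(FALSE, length(phi))
  for (w in seq_len(nrow(lb$dihedral_windows)))
    in_dw <- in_dw | (phi >= lb$dihedral_windows[w, 1] &
                        phi <= lb$dihedral_windows[w, 2])
  b1n <- sqrt(b1x^2 + b1y^2 + b1z^2)
  cosang <- -(b1x * b2x + b1y * b2y + b1z * b2z) / (b1n * b2n)
  th <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  in_aw <- th >= lb$angle_window[1] & th <= lb$angle_window[2]
  lb$penalty * (sum(!in_dw) + sum(!in_aw))
}

# C-alpha pseudo-dihedral angles (degrees, in (-180, 180]) for quadruples
# (i, i+1, i+2, i+3).
pseudo_dihedrals <- function(xyz) {
  n <- nrow(xyz)
  b1 <- xyz[2:(n - 2), , drop = FALSE] - xyz[1:(n - 3), , drop = FALSE]
  b2 <- xyz[3:(n - 1), , drop = FALSE] - xyz[2:(n - 2), , drop = FALSE]
  b3 <- xyz[4:n, , drop = FALSE] - xyz[3:(n - 1), , drop = FALSE]
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  m1 <- row_cross(b2 / sqrt(rowSums(b2^2)), n1)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

# C-alpha pseudo-bond angles (degrees) at vertices (i+1) of triples.
pseudo_angles <- function(xyz) {
  n <- nrow(xyz)
  u <- xyz[1:(n - 2), , drop = FALSE] - xyz[2:(n - 1), , drop = FALSE]
  v <- xyz[3:n, , drop = FALSE] - xyz[2:(n - 1), , drop = FALSE]
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total energy of a docking system with diagnostic decomposition
#'
#' Evaluates the four energy classes on the full system and returns their
#' decomposition; `total` is their exact sum.
#'
#' @param system a [cg_system()] (receptor with optional ligand).
#' @param ff force field.
#' @param rsets list of `restraint_set` objects; each is evaluated on the
#'   molecule named by its `molecule` field.
#' @return An `energy_breakdown`: list with `local`, `hbond`, `contact`,
#'   `restraint`, `total` (kT).
#' @export
total_energy <- function(system, ff = default_forcefield(), rsets = list()) {
  stopifnot(inherits(system, "cg_system"))
  chains <- Filter(Negate(is.null), list(receptor = system$receptor,
                                         ligand = system$ligand))
  xyz <- lapply(chains, ca_xyz)
  ps <- lapply(chains, rebuild_pseudo_atoms)
  nres <- vapply(xyz, nrow, 1L)
  chain_id <- rep(seq_along(chains), nres)
  ca_all <- do.call(rbind, xyz)
  sc_all <- do.call(rbind, lapply(ps, `[[`, "sc"))
  seq_all <- unlist(lapply(chains, `[[`, "seq"), use.names = FALSE)
  pb_all <- do.call(rbind, lapply(ps, `[[`, "pb"))
  bv <- do.call(rbind, lapply(xyz, function(x)
    x[-1L, , drop = FALSE] - x[-nrow(x), , drop = FALSE]))
  pb_chain <- rep(seq_along(chains), nres - 1L)

  e_local <- local_bias_energy(ca_all, seq_all, ff, chain_id)
  e_hb <- hbond_energy(pb_all, ff, bond_vectors = bv, chain = pb_chain)
  e_ct <- contact_energy(sc_all, seq_all, ff, chain_id, ca = ca_all)
  e_rs <- 0
  for (rset in rsets) {
    mol <- chains[[rset$molecule]]
    if (is.null(mol)) stop("restraint set refers to an absent molecule: ",
                           rset$molecule)
    e_rs <- e_rs + restraint_energy(ca_xyz(mol), rset)
  }
  energy_breakdown(e_local, e_hb, e_ct, e_rs)
}

energy_breakdown <- function(local, hbond, contact, restraint) {
  structure(list(local = local, hbond = hbond, contact = contact,
                 restraint = restraint,
                 total = local + hbond + contact + restraint),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "<energy_breakdown> total %.3f kT (local %.3f, hbond %.3f, contact %.3f, restraint %.3f)\n",
    x$total, x$local, x$hbond, x$contact, x$restraint))
  invisible(x)
}

#' Write / read a restraint set as TSV
#'
#' Plain-text exchange format: columns i, j, d0, tol, weight, with the
#' molecule and weight scale in `#` header lines.
#'
#' @param rset a `restraint_set`.
#' @param path file path.
#' @return `write_restraints` returns `path` invisibly; `read_restraints`
#'   returns a `restraint_set`.
#' @export
write_restraints <- function(rset, path) {
  hdr <- c(sprintf("# molecule\t%s", rset$molecule),
           sprintf("# weight_scale\t%g", rset$weight_scale))
  writeLines(c(hdr, paste(c("i", "j", "d0", "tol", "weight"), collapse = "\t")),
             path)
  utils::write.table(rset$restraints, path, append = TRUE, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  hdr <- readLines(path, n = 2L)
  molecule <- sub("^# molecule\t", "", hdr[1])
  scale <- as.numeric(sub("^# weight_scale\t", "", hdr[2]))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L)
  structure(list(restraints = tibble::as_tibble(tab), molecule = molecule,
                 weight_scale = scale),
            class = "restraint_set")
}
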