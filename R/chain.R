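#' Construct a coarse-grained chain
#'
#' A `cg_chain` is one protein reduced to its C-alpha trace on the lattice:
#' an ordered residue sequence plus integer grid coordinates. Consecutive
#' displacements must belong to the lattice's allowed-vector set and no two
#' beads may occupy the same grid point.
#'
#' @param seq one-letter amino-acid codes, character vector of length n.
#' @param ca integer n x 3 matrix of lattice coordinates.
#' @param lattice a [lattice_spec()].
#' @param role `"receptor"` or `"ligand"`.
#' @param meta optional list of I/O metadata (e.g. original PDB numbering).
#' @return A validated `cg_chain` object.
#' @export
cg_chain <- function(seq, ca, lattice = lattice_spec(),
                     role = c("receptor", "ligand"), meta = list()) {
  role <- match.arg(role)
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  ca <- as.matrix(ca)
  storage.mode(ca) <- "integer"
  dimnames(ca) <- NULL
  chain <- structure(
    list(seq = seq, ca = ca, lattice = lattice, role = role, meta = meta),
    class = "cg_chain"
  )
  validate_cg_chain(chain)
  chain
}

validate_cg_chain <- function(chain) {
  n <- length(chain$seq)
  if (nrow(chain$ca) != n) stop("sequence and coordinate lengths differ")
  aa_index(chain$seq)
  if (n >= 2L) {
    dv <- chain$ca[-1L, , drop = FALSE] - chain$ca[-n, , drop = FALSE]
    ok <- key_is_allowed(vec_key(dv), chain$lattice)
    if (!all(ok))
      stop("bond between residues ", which(!ok)[1], " and ", which(!ok)[1] + 1L,
           " is not an allowed lattice vector")
  }
  k <- vec_key(chain$ca)
  if (anyDuplicated(k))
    stop("excluded-volume violation: residues ",
         paste(which(k %in% k[duplicated(k)])[1:2], collapse = " and "),
         " occupy the same lattice site")
  invisible(chain)
}

#' @export
print.cg_chain <- function(x, ...) {
  cat(sprintf("<cg_chain> %s, %d residues, lattice spacing %.2f A\n",
              x$role, length(x$seq), x$lattice$spacing))
  invisible(x)
}

#' @export
length.cg_chain <- function(x) length(x$seq)

#' C-alpha coordinates of a chain in Angstrom
#'
#' @param chain a `cg_chain`.
#' @return Numeric n x 3 matrix (lattice coordinates scaled by the spacing).
#' @export
ca_xyz <- function(chain) {
  chain$ca * chain$lattice$spacing
}

#' Rebuild pseudo-atoms from a C-alpha trace
#'
#' Derives the three classes of united pseudo-atoms from the trace geometry
#' and the sequence: C-beta, the united side-chain centre, and the
#' peptide-bond centre. The local frame of residue i is built from the three
#' consecutive C-alphas (i-1, i, i+1): with unit bond vectors v1, v2, the
#' C-beta direction is a fixed combination of the bisector (v1 - v2) and the
#' normal v1 x v2, so placement is deterministic and equivariant under rigid
#' motions. Side-chain centres lie along the same direction at a per-residue
#' distance; glycine's side-chain centre is its C-alpha and alanine's is its
#' C-beta. Terminal residues copy the direction frame of their neighbour.
#' Peptide-bond centres are the midpoints of consecutive C-alphas.
#'
#' For a locally straight trace the frame is degenerate; a fixed axis-based
#' fallback keeps the result deterministic (though not equivariant) there.
#'
#' @param chain a `cg_chain`, or a plain numeric n x 3 C-alpha matrix in
#'   Angstrom (then `seq` must be given).
#' @param seq sequence override when `chain` is a bare coordinate matrix.
#' @return A `cg_pseudo` object: list with matrices `cb` (n x 3), `sc`
#'   (n x 3), `pb` ((n-1) x 3), all in Angstrom.
#' @export
rebuild_pseudo_atoms <- function(chain, seq = NULL) {
  if (inherits(chain, "cg_chain")) {
    xyz <- ca_xyz(chain)
    seq <- chain$seq
  } else {
    xyz <- as_coord_matrix(chain)
    if (is.null(seq)) stop("seq required when passing bare coordinates")
    if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  }
  n <- nrow(xyz)
  if (n < 3L) stop("need at least 3 residues to build pseudo-atoms")
  ai <- aa_index(seq)
  dir <- cb_directions(xyz)
  cb <- xyz + CB_DISTANCE * dir
  cb[ai == match("G", AA_CODES), ] <- xyz[ai == match("G", AA_CODES), ]
  dsc <- SC_DISTANCE[ai]
  sc <- xyz + dsc * dir
  pb <- (xyz[-1L, , drop = FALSE] + xyz[-n, , drop = FALSE]) / 2
  structure(list(cb = cb, sc = sc, pb = pb), class = "cg_pseudo")
}

# Unit C-beta directions for every residue from consecutive C-alpha triples.
# Vectorized over the chain.
cb_directions <- function(xyz) {
  n <- nrow(xyz)
  b <- xyz[-1L, , drop = FALSE] - xyz[-n, , drop = FALSE]
  b <- b / sqrt(rowSums(b^2))
  v1 <- b[-(n - 1L), , drop = FALSE]  # bond entering residue i = 2..n-1
  v2 <- b[-1L, , drop = FALSE]        # bond leaving residue i
  bis <- v1 - v2
  nrm <- cbind(
    v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
    v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
    v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  )
  bl <- sqrt(rowSums(bis^2))
  nl <- sqrt(rowSums(nrm^2))
  deg <- bl < 1e-8 | nl < 1e-8
  if (any(deg)) {
    # locally straight backbone: fall back to a fixed perpendicular of v1
    for (k in which(deg)) {
      a <- v1[k, ]
      e <- diag(3)[which.min(abs(a)), ]
      p <- e - sum(e * a) * a
      bis[k, ] <- p / sqrt(sum(p^2))
      nrm[k, ] <- 0
      bl[k] <- 1; nl[k] <- 1
    }
  }
  bis <- bis / ifelse(bl < 1e-8, 1, bl)
  nrm <- nrm / ifelse(nl < 1e-8, 1, nl)
  # fixed tilt of the C-beta direction out of the bisector plane
  ang <- 0.66  # rad
  dir_mid <- cos(ang) * bis + sin(ang) * nrm
  dir_mid <- dir_mid / sqrt(rowSums(dir_mid^2))
  dir <- rbind(dir_mid[1L, ], dir_mid, dir_mid[n - 2L, ])
  dir
}

#' Read a single chain's C-alpha trace from a PDB file
#'
#' Extracts ordered C-alpha coordinates and the one-letter sequence for one
#' chain. Residues are ordered by (residue number, insertion code); altloc
#' 'A'/blank records are kept, HETATM and waters ignored. A residue lacking a
#' C-alpha record makes the chain unusable for trace-based modelling and is
#' reported as a chain gap.
#'
#' @param path PDB file path.
#' @param chain_id chain identifier; defaults to the first chain in the file.
#' @return List with `xyz` (n x 3 C-alpha matrix, Angstrom), `seq`
#'   (one-letter codes), `resno` and `insert` (original numbering metadata).
#' @export
chain_from_pdb <- function(path, chain_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain_id)) chain_id <- at$chain[1L]
  at <- at[at$chain %in% chain_id, , drop = FALSE]
  if (!nrow(at)) stop("unknown chain id: ", chain_id)
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  ins <- ifelse(is.na(at$insert), "", at$insert)
  ord <- order(at$resno, ins)
  at <- at[ord, , drop = FALSE]
  ins <- ins[ord]
  rid <- paste(at$resno, ins, sep = "_")
  urid <- unique(rid)
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca_rid <- paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert), sep = "_")
  missing <- setdiff(urid, ca_rid)
  if (length(missing))
    stop("chain gap: residue(s) without a C-alpha record: ",
         paste(utils::head(sub("_$", "", missing), 5), collapse = ", "))
  if (anyDuplicated(ca_rid))
    ca <- ca[!duplicated(ca_rid), , drop = FALSE]
  seq1 <- bio3d::aa321(ca$resid)
  if (any(seq1 == "X"))
    stop("non-standard residue(s) in chain: ",
         paste(unique(ca$resid[seq1 == "X"]), collapse = ", "))
  list(
    xyz = cbind(ca$x, ca$y, ca$z),
    seq = seq1,
    resno = ca$resno,
    insert = ifelse(is.na(ca$insert), "", ca$insert)
  )
}

#' Bundle a receptor and an (optional) ligand into a docking system
#'
#' @param receptor,ligand `cg_chain` objects on the same lattice; `ligand`
#'   may be `NULL` for single-molecule simulations.
#' @return A `cg_system` object.
#' @export
cg_system <- function(receptor, ligand = NULL) {
  stopifnot(inherits(receptor, "cg_chain"))
  if (!is.null(ligand)) {
    stopifnot(inherits(ligand, "cg_chain"))
    if (!identical(receptor$lattice$spacing, ligand$lattice$spacing))
      stop("receptor and ligand must share one lattice")
    kk <- c(vec_key(receptor$ca), vec_key(ligand$ca))
    if (anyDuplicated(kk))
      stop("excluded-volume violation: receptor and ligand share a lattice site")
  }
  structure(list(receptor = receptor, ligand = ligand), class = "cg_system")
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("<cg_system> receptor %d aa%s\n", length(x$receptor$seq),
              if (is.null(x$ligand)) "" else
                sprintf(" + ligand %d aa", length(x$ligand$seq))))
  invisible(x)
}
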