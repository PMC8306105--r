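#' Default coarse-grained force field
#'
#' A simplified knowledge-based-style potential with the three classical
#' functional classes of C-alpha-trace models — short-range conformational
#' bias of the main chain, main-chain hydrogen bonds located through the
#' peptide-bond centres, and pairwise united-side-chain contacts — plus soft
#' hard-core repulsion. Parameters are the package's own, chosen from
#' idealized geometry and a hydropathy scale rather than re-derived from a
#' structure-database survey; energies are in kT units.
#'
#' The side-chain contact matrix is built from Kyte-Doolittle hydropathies
#' rescaled to `[0, 1]` as `e(a,b) = -(base + strength * h_a * h_b)`, so every
#' contact is mildly cohesive and hydrophobic-hydrophobic contacts are the
#' strongest (about -1.2 kT for Ile-Ile vs. -0.2 kT for Arg-Arg).
#'
#' @param contact_base,contact_strength parameters of the contact matrix (kT).
#' @param contact_cutoff side-chain contact cutoff (Angstrom).
#' @param sc_core,ca_core hard-core radii for side-chain and C-alpha pairs
#'   (Angstrom); pairs closer than the core are penalized linearly.
#' @param repulsion penalty slope inside the hard core (kT per Angstrom).
#' @param hbond_depth well depth of a main-chain hydrogen bond (kT).
#' @param hbond_window admissible peptide-bond-centre distance window
#'   (Angstrom, length-2 vector).
#' @param hbond_align minimum |cos| of the angle between the two C-alpha bond
#'   vectors for a hydrogen bond (alignment tolerance).
#' @param hbond_min_sep minimum separation (in bonds, within a chain).
#' @param local_penalty penalty (kT) for a backbone 4-mer outside the
#'   preferred pseudo-dihedral / pseudo-angle windows.
#' @return A `forcefield` object (list of parameter blocks).
#' @export
default_forcefield <- function(contact_base = 0.2, contact_strength = 1.0,
                               contact_cutoff = 6.0,
                               sc_core = 2.8, ca_core = 3.8, repulsion = 5.0,
                               hbond_depth = 1.0, hbond_window = c(4.2, 5.4),
                               hbond_align = 0.48, hbond_min_sep = 3L,
                               local_penalty = 0.6) {
  stopifnot(contact_cutoff > 0, sc_core > 0, sc_core < contact_cutoff,
            ca_core > 0, hbond_window[1] < hbond_window[2])
  h <- (KD_HYDROPATHY[AA_CODES] + 4.5) / 9  # rescale to [0, 1]
  cm <- -(contact_base + contact_strength * outer(h, h))
  dimnames(cm) <- list(AA_CODES, AA_CODES)
  ff <- list(
    contact_matrix = cm,
    contact_cutoff = contact_cutoff,
    repulsion = list(sc_core = sc_core, ca_core = ca_core, slope = repulsion),
    hbond_params = list(depth = hbond_depth, window = hbond_window,
                        align = hbond_align, min_sep = as.integer(hbond_min_sep)),
    local_bias_params = list(
      # preferred C-alpha pseudo-dihedral windows (degrees): right-handed
      # helical turn and extended; pseudo-angle window for the bond angle
      dihedral_windows = rbind(c(30, 75), c(140, 180), c(-180, -140)),
      angle_window = c(75, 155),
      penalty = local_penalty
    )
  )
  class(ff) <- "forcefield"
  ff
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf(
    "<forcefield> contact cutoff %.1f A, hbond window [%.1f, %.1f] A, %d aa types\n",
    x$contact_cutoff, x$hbond_params$window[1], x$hbond_params$window[2],
    nrow(x$contact_matrix)
  ))
  invisible(x)
}
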