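#' Ideal C-alpha secondary-structure templates
#'
#' Deterministic Cartesian C-alpha traces built from idealized geometry:
#' an alpha-helix with 1.5 A rise and 100 degrees twist per residue
#' (radius 2.3 A, giving ~3.8 A virtual bonds), a two-stranded hairpin of
#' lightly zig-zagged extended strands, and a single extended strand.
#'
#' @param n number of residues.
#' @param rise,twist,radius helix parameters (Angstrom, degrees, Angstrom).
#' @return Numeric n x 3 coordinate matrix (Angstrom).
#' @export
helix_ca <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1L
  th <- i * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), rise * i)
}

#' @rdname helix_ca
#' @param step,wobble extended-strand parameters: along-axis step and
#'   alternating lateral offset (Angstrom).
#' @export
extended_ca <- function(n, step = 3.3, wobble = 0.9) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1L
  cbind(i * step, wobble * (i %% 2L), 0)
}

#' @rdname helix_ca
#' @param strand_sep distance between the two hairpin strands (Angstrom).
#' @export
hairpin_ca <- function(n, step = 3.3, wobble = 0.9, strand_sep = 4.8) {
  stopifnot(n >= 6)
  n1 <- ceiling((n - 2L) / 2)
  n2 <- n - 2L - n1
  s1 <- extended_ca(n1, step, wobble)
  # two turn residues arcing over to the antiparallel strand
  e <- s1[n1, ]
  turn <- rbind(
    c(e[1] + 2.6, e[2] + 1.2, e[3] + 1.5),
    c(e[1] + 2.6, strand_sep - 1.2, -1.5)
  )
  i2 <- seq_len(n2) - 1L
  s2 <- cbind(e[1] - i2 * step,
              strand_sep + wobble * (i2 %% 2L), 0)
  rbind(s1, turn, s2)
}

#' Generate a synthetic toy protein-protein complex
#'
#' Builds a deterministic reference complex from ideal secondary-structure
#' templates — by default a helical receptor and a hairpin ligand docked
#' against the receptor's mid-face with a hydrophobic interface patch — plus
#' optionally perturbed "unbound-like" input chains whose deviation from the
#' reference emulates the conformational difference between unbound and
#' bound experimental structures.
#'
#' @param receptor_size,ligand_size chain lengths (residues, >= 8).
#' @param receptor_template,ligand_template `"helix"`, `"hairpin"` or
#'   `"extended"`.
#' @param perturb requested input-vs-reference C-alpha RMSD (Angstrom) for
#'   the perturbed input chains; 0 returns inputs identical to the
#'   reference.
#' @param gap receptor-surface-to-ligand gap used when posing the native
#'   complex (Angstrom).
#' @param seed integer seed making the complex fully reproducible.
#' @param lattice lattice for the projected chains.
#' @return A `toy_complex`: list with `reference` (a [cg_system()]),
#'   `receptor_input`, `ligand_input` (perturbed `cg_chain`s), the residue
#'   `contacts` of the reference interface (tibble), and the achieved input
#'   RMSDs.
#' @export
make_toy_complex <- function(receptor_size = 30L, ligand_size = 12L,
                             receptor_template = "helix",
                             ligand_template = "hairpin",
                             perturb = 0, gap = 1.2, seed = 1L,
                             lattice = lattice_spec()) {
  stopifnot(receptor_size >= 8L, ligand_size >= 8L)
  template_fun <- function(tpl, n) switch(
    tpl,
    helix = helix_ca(n),
    hairpin = hairpin_ca(n),
    extended = extended_ca(n),
    stop("unknown template: ", tpl)
  )
  rec_xyz <- template_fun(receptor_template, receptor_size)
  lig_xyz <- template_fun(ligand_template, ligand_size)

  # hydrophobic patch facing the interface, polar elsewhere, deterministic
  rec_seq <- rep(c("S", "E", "L", "K", "I", "Q", "V"), length.out = receptor_size)
  lig_seq <- rep(c("L", "I", "S", "V", "F", "T"), length.out = ligand_size)

  # pose the ligand against the receptor mid-face along +x
  rec_cen <- colMeans(rec_xyz)
  lig_cen <- colMeans(lig_xyz)
  lig0 <- lig_xyz - matrix(lig_cen, nrow(lig_xyz), 3, byrow = TRUE)
  # rotate ligand long axis to z (already along x for hairpin: swap x/z)
  lig0 <- lig0[, c(3, 2, 1)] * matrix(c(1, 1, -1), nrow(lig0), 3, byrow = TRUE)
  rmax <- max(sqrt(rec_xyz[, 1]^2 + rec_xyz[, 2]^2))
  lig_half <- max(abs(lig0[, 1]))
  shift <- c(rmax + gap + lig_half + 3.0, 0, rec_cen[3])
  lig_pose <- lig0 + matrix(shift, nrow(lig0), 3, byrow = TRUE)

  receptor <- project_to_lattice(rec_xyz, rec_seq, lattice, role = "receptor")
  ligand <- project_to_lattice(lig_pose, lig_seq, lattice, role = "ligand")
  reference <- cg_system(receptor, ligand)
  cmap <- compute_contact_map(reference)

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    expr
  }
  out <- withr_seed({
    ri <- perturb_chain(receptor, perturb)
    li <- perturb_chain(ligand, perturb)
    list(ri = ri, li = li)
  })
  structure(list(
    reference = reference,
    receptor_input = out$ri$chain, ligand_input = out$li$chain,
    receptor_input_rmsd = out$ri$rmsd, ligand_input_rmsd = out$li$rmsd,
    contacts = as_tibble(cmap), seed = seed
  ), class = "toy_complex")
}

#' @export
print.toy_complex <- function(x, ...) {
  cat(sprintf(
    "<toy_complex> receptor %d aa + ligand %d aa, %d native contacts, input RMSD %.2f / %.2f A\n",
    length(x$reference$receptor$seq), length(x$reference$ligand$seq),
    nrow(x$contacts), x$receptor_input_rmsd, x$ligand_input_rmsd))
  invisible(x)
}

# Jitter a chain's Cartesian trace towards a target RMSD (after optimal
# superposition) and re-project to the lattice. The raw noise is smoothed
# along the chain (so bonds stay near-protein) and rescaled to the target
# amplitude; an outer loop corrects for the shrinkage introduced by
# superposition and lattice projection.
perturb_chain <- function(chain, target_rmsd) {
  if (target_rmsd <= 0)
    return(list(chain = chain, rmsd = 0))
  xyz <- ca_xyz(chain)
  n <- nrow(xyz)
  amp <- target_rmsd
  best <- NULL
  for (it in 1:40) {
    # a few smooth low-frequency bending modes: large-scale deformation
    # with per-bond stretches far smaller than the overall amplitude
    i <- seq_len(n) - 0.5
    noise <- matrix(0, n, 3)
    for (k in 1:3) {
      dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      noise <- noise + (stats::rnorm(1) *
                          sin(pi * k * i / n + stats::runif(1, 0, 2 * pi))) %o%
        dirv
    }
    noise <- sweep(noise, 2, colMeans(noise))
    noise <- noise * amp / sqrt(mean(rowSums(noise^2)))
    cand <- xyz + noise
    d <- sqrt(rowSums(diff(cand)^2))
    if (any(d < 2.9 | d > 4.5)) { amp <- amp * 0.93; next }
    pr <- try(project_to_lattice(cand, chain$seq, chain$lattice, chain$role),
              silent = TRUE)
    if (inherits(pr, "try-error")) { amp <- amp * 0.93; next }
    got <- superpose(ca_xyz(pr), xyz)$rmsd
    if (is.null(best) || abs(got - target_rmsd) < abs(best$rmsd - target_rmsd))
      best <- list(chain = pr, rmsd = got)
    if (abs(got - target_rmsd) <= 0.15) break
    amp <- min(max(amp * target_rmsd / max(got, 1e-3), target_rmsd / 3),
               target_rmsd * 4)
  }
  if (is.null(best)) stop("could not generate a perturbed chain at RMSD ",
                          target_rmsd)
  best
}

#' Generate a labelled decoy ensemble around a reference complex
#'
#' Produces `n` models by rigidly displacing (and optionally jittering) the
#' reference ligand around the receptor: low noise levels give near-native
#' poses, and a fraction of decoys is re-posed on the opposite receptor face
#' so the ensemble always contains far-from-native models with fNAT 0. Each
#' model is labelled with its fNAT and iRMSD against the reference.
#'
#' @param reference a `cg_system` reference complex (e.g. from
#'   [make_toy_complex()]).
#' @param n ensemble size.
#' @param noise_levels vector of rigid-displacement scales (Angstrom)
#'   recycled over models; level 0 reproduces the native pose.
#' @param far_fraction fraction of models re-posed on the reversed face.
#' @param seed integer seed.
#' @return A `decoy_ensemble`: list with `models` (list of `cg_system`) and
#'   `labels` (tibble: model, noise, far, fnat, irmsd).
#' @export
make_decoy_ensemble <- function(reference, n = 20L,
                                noise_levels = c(0, 0.5, 1, 2, 4),
                                far_fraction = 0.25, seed = 1L) {
  stopifnot(inherits(reference, "cg_system"), !is.null(reference$ligand))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rec <- reference$receptor
  lig <- reference$ligand
  lig_xyz <- ca_xyz(lig)
  rec_cen <- colMeans(ca_xyz(rec))
  noise <- rep_len(noise_levels, n)
  far <- rep(FALSE, n)
  if (far_fraction > 0)
    far[seq_len(max(1L, floor(n * far_fraction)))] <- TRUE
  far <- sample(far)  # scatter far decoys over the ensemble
  # keep at least one exact-native and one far decoy
  noise[which(!far)[1]] <- 0
  models <- vector("list", n)
  for (k in seq_len(n)) {
    xyz <- lig_xyz
    if (far[k]) {
      # reflect the ligand centre through the receptor centre (reversed face)
      cen <- colMeans(xyz)
      xyz <- xyz + matrix(2 * (rec_cen - cen) * c(1, 1, 0), nrow(xyz), 3,
                          byrow = TRUE)
    }
    if (noise[k] > 0) {
      ang <- stats::rnorm(1, 0, noise[k] * 4) * pi / 180
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- rotation_about_axis(ax, ang)
      cen <- colMeans(xyz)
      xyz <- (xyz - matrix(cen, nrow(xyz), 3, byrow = TRUE)) %*% t(R) +
        matrix(cen + stats::rnorm(3, 0, noise[k] / sqrt(3)), nrow(xyz), 3,
               byrow = TRUE)
    }
    pl <- try(project_to_lattice(xyz, lig$seq, lig$lattice, "ligand"),
              silent = TRUE)
    if (inherits(pl, "try-error")) { models[[k]] <- reference; next }
    sys <- try(cg_system(rec, pl), silent = TRUE)
    models[[k]] <- if (inherits(sys, "try-error")) reference else sys
  }
  labels <- tibble::tibble(
    model = seq_len(n), noise = noise, far = far,
    fnat = vapply(models, function(m) fnat(m, reference), 0),
    irmsd = vapply(models, function(m) irmsd(m, reference), 0)
  )
  structure(list(models = models, labels = labels, seed = seed),
            class = "decoy_ensemble")
}

rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) * c0 + s0 * K + (1 - c0) * (a %o% a)
}
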