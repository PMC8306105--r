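#' Configuration of a docking run
#'
#' Bundles the inputs and all protocol parameters. Defaults follow the
#' standard protocol: 20 replicas, 20 annealing stages, ligand starting
#' centres about 20 A off the receptor surface, 500 snapshots per replica
#' (2% of generated models, 10,000 pooled models in total), restraints
#' auto-generated from the input coordinates (sequence separation >= 5,
#' C-alpha distance 5-15 A, flat bottom +/- 1 A) with tenfold weaker
#' weights on the ligand.
#'
#' @param receptor,ligand `cg_chain`s, or paths to PDB files (first chain
#'   read and projected to the default lattice).
#' @param n_replicas,annealing_steps,snapshot_per_replica,snapshot_fraction,t_min,t_max,ratio,cooling,exchange_every
#'   see [remc_config()].
#' @param start_offset requested ligand-centre-to-receptor-surface distance
#'   (Angstrom) for starting poses.
#' @param min_seq_sep,dmin,dmax,tol,receptor_weight,ligand_weight_scale
#'   restraint-scheme parameters (see [generate_restraints()]);
#'   `ligand_weight_scale` is the ligand's weight multiplier relative to
#'   the receptor's.
#' @param ff force field.
#' @param master_seed master seed for pose generation and sampling.
#' @param max_ligand warn when the ligand exceeds this many residues
#'   (sampling whole-ligand refolding becomes impractical).
#' @return A `docking_config` list.
#' @export
docking_config <- function(receptor, ligand,
                           n_replicas = 20L, annealing_steps = 20L,
                           start_offset = 20, snapshot_per_replica = 500L,
                           snapshot_fraction = 0.02,
                           t_min = 1.0, t_max = 3.5, ratio = 1.1,
                           cooling = 0.95, exchange_every = 5L,
                           min_seq_sep = 5L, dmin = 5, dmax = 15, tol = 1,
                           receptor_weight = 12.0, ligand_weight_scale = 0.1,
                           ff = default_forcefield(), master_seed = 1L,
                           max_ligand = 150L) {
  as_chain <- function(x, role) {
    if (inherits(x, "cg_chain")) return(x)
    raw <- chain_from_pdb(x)
    project_to_lattice(raw$xyz, raw$seq, role = role)
  }
  receptor <- as_chain(receptor, "receptor")
  ligand <- as_chain(ligand, "ligand")
  if (length(ligand$seq) > max_ligand)
    warning("ligand has ", length(ligand$seq), " residues; flexible docking ",
            "of ligands beyond ", max_ligand, " residues may be impractical")
  if (length(ligand$seq) > length(receptor$seq))
    warning("ligand is larger than receptor; the smaller protein is ",
            "usually the better choice of flexible ligand")
  structure(list(
    receptor = receptor, ligand = ligand,
    n_replicas = as.integer(n_replicas),
    annealing_steps = as.integer(annealing_steps),
    start_offset = start_offset,
    snapshot_per_replica = as.integer(snapshot_per_replica),
    snapshot_fraction = snapshot_fraction,
    t_min = t_min, t_max = t_max, ratio = ratio, cooling = cooling,
    exchange_every = as.integer(exchange_every),
    min_seq_sep = as.integer(min_seq_sep), dmin = dmin, dmax = dmax,
    tol = tol, receptor_weight = receptor_weight,
    ligand_weight_scale = ligand_weight_scale,
    ff = ff, master_seed = as.integer(master_seed)
  ), class = "docking_config")
}

#' Random ligand starting arrangements around a receptor
#'
#' Places copies of the ligand (internal conformation preserved, orientation
#' uniformly random) at random positions around the receptor so that each
#' ligand geometric centre sits at the requested distance — within a +/- 2 A
#' band — from the receptor surface, where the surface distance of a point
#' is its minimum distance to any receptor heavy pseudo-atom (C-alpha,
#' C-beta, side chain, peptide-bond centre). Poses clashing with the
#' receptor are rejected and re-drawn.
#'
#' @param receptor,ligand `cg_chain`s.
#' @param n number of arrangements; default 20.
#' @param offset requested centre-to-surface distance (Angstrom);
#'   default 20.
#' @param seed integer seed.
#' @param max_tries placement attempts per arrangement before failing.
#' @return List of `n` [cg_system()]s.
#' @export
generate_starting_structures <- function(receptor, ligand, n = 20L,
                                         offset = 20, seed = 1L,
                                         max_tries = 200L) {
  stopifnot(inherits(receptor, "cg_chain"), inherits(ligand, "cg_chain"),
            n >= 1L)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ps <- rebuild_pseudo_atoms(receptor)
  surf_atoms <- rbind(ca_xyz(receptor), ps$cb, ps$sc, ps$pb)
  rec_cen <- colMeans(ca_xyz(receptor))
  rmax <- max(sqrt(rowSums((surf_atoms -
                              matrix(rec_cen, nrow(surf_atoms), 3,
                                     byrow = TRUE))^2)))
  surf_dist <- function(p)
    min(sqrt(rowSums((surf_atoms - matrix(p, nrow(surf_atoms), 3,
                                          byrow = TRUE))^2)))
  lig_xyz <- ca_xyz(ligand)
  lig_cen <- colMeans(lig_xyz)
  lig0 <- lig_xyz - matrix(lig_cen, nrow(lig_xyz), 3, byrow = TRUE)

  out <- vector("list", n)
  last_err <- "none"
  for (k in seq_len(n)) {
    placed <- NULL
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      R <- quaternion_rotation(q)
      # radial bisection for surface distance = offset along direction u
      lo <- 0; hi <- rmax + offset + 10
      for (it in 1:40) {
        mid <- (lo + hi) / 2
        if (surf_dist(rec_cen + mid * u) < offset) lo <- mid else hi <- mid
      }
      cen <- rec_cen + hi * u
      xyz <- lig0 %*% t(R) + matrix(cen, nrow(lig0), 3, byrow = TRUE)
      pl <- try(project_to_lattice(xyz, ligand$seq, ligand$lattice, "ligand"),
                silent = TRUE)
      if (inherits(pl, "try-error")) { last_err <- "projection failure"; next }
      got <- surf_dist(colMeans(ca_xyz(pl)))
      if (abs(got - offset) > 2) { last_err <- sprintf(
        "surface distance %.1f A outside band", got); next }
      sys <- try(cg_system(receptor, pl), silent = TRUE)
      if (inherits(sys, "try-error")) { last_err <- "bead clash with receptor"; next }
      placed <- sys
      break
    }
    if (is.null(placed))
      stop("ligand placement ", k, " failed after ", max_tries,
           " attempts (last problem: ", last_err, ")")
    out[[k]] <- placed
  }
  out
}

quaternion_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Run the full docking protocol
#'
#' End-to-end orchestration: generates the flat-bottom restraints from the
#' input coordinates (full weight on the receptor, tenfold weaker on the
#' ligand), scatters `n_replicas` random ligand starting arrangements
#' around the receptor, runs Replica Exchange Monte Carlo with simulated
#' annealing, and pools the saved snapshots from all replicas.
#'
#' @param config a [docking_config()].
#' @return A `dock_pool` tibble of `n_replicas * snapshot_per_replica`
#'   models (see [run_remc()]); restraint sets and the configuration are
#'   attached as attributes.
#' @export
run_docking <- function(config) {
  stopifnot(inherits(config, "docking_config"))
  rs_rec <- generate_restraints(
    ca_xyz(config$receptor), config$min_seq_sep, config$dmin, config$dmax,
    weight = config$receptor_weight, tol = config$tol,
    molecule = "receptor", weight_scale = 1.0)
  rs_lig <- generate_restraints(
    ca_xyz(config$ligand), config$min_seq_sep, config$dmin, config$dmax,
    weight = config$receptor_weight, tol = config$tol,
    molecule = "ligand", weight_scale = config$ligand_weight_scale)
  starts <- generate_starting_structures(
    config$receptor, config$ligand, n = config$n_replicas,
    offset = config$start_offset, seed = config$master_seed)
  rc <- remc_config(
    n_replicas = config$n_replicas, t_min = config$t_min,
    t_max = config$t_max, ratio = config$ratio,
    annealing_steps = config$annealing_steps, cooling = config$cooling,
    snapshot_per_replica = config$snapshot_per_replica,
    snapshot_fraction = config$snapshot_fraction,
    exchange_every = config$exchange_every, seed = config$master_seed)
  pool <- run_remc(starts, ff = config$ff, rsets = list(rs_rec, rs_lig),
                   config = rc)
  attr(pool, "restraints") <- list(receptor = rs_rec, ligand = rs_lig)
  attr(pool, "config") <- config
  pool
}

#' Per-residue fluctuation of one molecule over a pool
#'
#' Convenience wrapper: extracts the C-alpha frames of one molecule from a
#' pool (optionally restricted, e.g. to the coldest rung) and computes the
#' RMSF profile.
#'
#' @param pool a `dock_pool` tibble.
#' @param molecule `"receptor"` or `"ligand"`.
#' @return Tibble with `residue` and `rmsf` (Angstrom), see [rmsf()].
#' @export
pool_rmsf <- function(pool, molecule = c("receptor", "ligand")) {
  molecule <- match.arg(molecule)
  tpl <- attr(pool, "template")
  sp <- tpl$receptor$lattice$spacing
  frames <- lapply(pool$coords, function(co) co[[molecule]] * sp)
  rmsf(frames)
}
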