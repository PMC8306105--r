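#' Least-squares superposition of two coordinate sets
#'
#' Kabsch algorithm: finds the proper rotation and translation minimizing
#' the RMSD between paired coordinate sets (improper rotations/reflections
#' are excluded). The fitted transform maps `x` onto `y` as
#' `x %*% rotation + translation` (row-vector convention).
#'
#' @param x,y numeric n x 3 matrices, n >= 3, paired rows.
#' @return A `superposition`: list with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
superpose <- function(x, y) {
  x <- as_coord_matrix(x); y <- as_coord_matrix(y)
  if (nrow(x) != nrow(y)) stop("coordinate sets differ in length")
  if (nrow(x) < 3L) stop("need at least 3 points for a superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  u <- s$u
  u[, 3] <- u[, 3] * d
  R <- u %*% t(s$v)
  fit <- xc %*% R
  res <- structure(list(
    rotation = R,
    translation = as.numeric(cy - cx %*% R),
    rmsd = sqrt(mean(rowSums((fit - yc)^2)))
  ), class = "superposition")
  res
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

apply_superposition <- function(coords, sp) {
  sweep(coords %*% sp$rotation, 2, sp$translation, `+`)
}

#' Interface residues of a reference complex
#'
#' Residues of either molecule having at least one inter-molecular
#' side-chain-centre distance within the cutoff in the reference complex.
#'
#' @param reference a [cg_system()] with a ligand.
#' @param cutoff contact cutoff (Angstrom), default 6.
#' @return List with integer vectors `receptor` and `ligand`.
#' @export
interface_residues <- function(reference, cutoff = 6) {
  cm <- compute_contact_map(reference, cutoff = cutoff)
  el <- as_tibble(cm)
  list(receptor = sort(unique(el$rec_res)), ligand = sort(unique(el$lig_res)))
}

sys_ca <- function(system) {
  list(receptor = ca_xyz(system$receptor),
       ligand = if (is.null(system$ligand)) NULL else ca_xyz(system$ligand))
}

check_congruent <- function(model, reference) {
  stopifnot(inherits(model, "cg_system"), inherits(reference, "cg_system"))
  if (length(model$receptor$seq) != length(reference$receptor$seq))
    stop("model and reference receptors differ in length")
  if (!is.null(reference$ligand) &&
      length(model$ligand$seq) != length(reference$ligand$seq))
    stop("model and reference ligands differ in length")
  invisible(TRUE)
}

#' Interface RMSD (iRMSD)
#'
#' RMSD over the reference complex's interface C-alphas (both molecules
#' jointly) after superposing the model's interface onto the reference's.
#' Models with iRMSD below ~4 A are conventionally of acceptable docking
#' quality.
#'
#' @param model,reference [cg_system()] complexes with matching chain
#'   lengths.
#' @param cutoff interface definition cutoff (Angstrom), default 6.
#' @return iRMSD in Angstrom.
#' @export
irmsd <- function(model, reference, cutoff = 6) {
  check_congruent(model, reference)
  ir <- interface_residues(reference, cutoff)
  if (!length(ir$receptor))
    stop("reference complex has no interface at the given cutoff")
  mca <- sys_ca(model); rca <- sys_ca(reference)
  m <- rbind(mca$receptor[ir$receptor, , drop = FALSE],
             mca$ligand[ir$ligand, , drop = FALSE])
  r <- rbind(rca$receptor[ir$receptor, , drop = FALSE],
             rca$ligand[ir$ligand, , drop = FALSE])
  superpose(m, r)$rmsd
}

#' Ligand RMSD (LRMSD)
#'
#' RMSD over ligand C-alphas after superposing the receptors only; measures
#' the pose error of the ligand relative to the receptor frame.
#'
#' @inheritParams irmsd
#' @return LRMSD in Angstrom.
#' @export
lrmsd <- function(model, reference) {
  check_congruent(model, reference)
  mca <- sys_ca(model); rca <- sys_ca(reference)
  sp <- superpose(mca$receptor, rca$receptor)
  lig <- apply_superposition(mca$ligand, sp)
  sqrt(mean(rowSums((lig - rca$ligand)^2)))
}

#' Ligand-only RMSD (LoRMSD)
#'
#' RMSD of the ligand's internal conformation: the model ligand is
#' superposed directly onto the reference ligand, so rigid-body pose
#' differences do not contribute.
#'
#' @param model_ligand,reference_ligand `cg_chain`s, n x 3 C-alpha matrices,
#'   or `cg_system`s (then their ligands are compared).
#' @return LoRMSD in Angstrom.
#' @export
lormsd <- function(model_ligand, reference_ligand) {
  as_ca <- function(x) {
    if (inherits(x, "cg_system")) x <- x$ligand
    if (inherits(x, "cg_chain")) ca_xyz(x) else as_coord_matrix(x)
  }
  superpose(as_ca(model_ligand), as_ca(reference_ligand))$rmsd
}

#' Per-residue root-mean-square fluctuation (RMSF)
#'
#' Each frame is superposed onto the ensemble mean structure (obtained by
#' superposing all frames onto the first and averaging, then refitting);
#' the RMSF of a residue is the square root of its positional variance
#' around its mean position.
#'
#' @param frames list of n x 3 C-alpha matrices (one per frame), or a
#'   3-dimensional array `n x 3 x n_frames`.
#' @param fit superpose each frame onto the reference (default). With
#'   `fit = FALSE` the frames are taken as already expressed in a common
#'   frame and only the variance around the mean is measured.
#' @return Tibble with columns `residue` and `rmsf` (Angstrom).
#' @export
rmsf <- function(frames, fit = TRUE) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  stopifnot(length(frames) >= 1L)
  n <- nrow(frames[[1]])
  for (f in frames) if (nrow(f) != n) stop("frames differ in length")
  if (!fit) {
    mean_xyz <- Reduce(`+`, frames) / length(frames)
    dev2 <- Reduce(`+`, lapply(frames, function(f)
      rowSums((f - mean_xyz)^2))) / length(frames)
    return(tibble::tibble(residue = seq_len(n), rmsf = sqrt(dev2)))
  }
  aligned <- lapply(frames, function(f)
    apply_superposition(f, superpose(f, frames[[1]])))
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(frames, function(f)
    apply_superposition(f, superpose(f, mean_xyz)))
  mean_xyz <- Reduce(`+`, aligned) / length(aligned)
  dev2 <- Reduce(`+`, lapply(aligned, function(f) rowSums((f - mean_xyz)^2))) /
    length(aligned)
  tibble::tibble(residue = seq_len(n), rmsf = sqrt(dev2))
}

#' Fraction of native contacts (fNAT)
#'
#' Number of reference-complex residue contacts reproduced by the model,
#' divided by the total number of reference contacts. Contacts use the
#' side-chain-centre criterion at 6 A (C-beta for alanine, C-alpha for
#' glycine).
#'
#' @inheritParams irmsd
#' @return Fraction in `[0, 1]`.
#' @export
fnat <- function(model, reference, cutoff = 6) {
  check_congruent(model, reference)
  ref <- compute_contact_map(reference, cutoff = cutoff)
  if (!length(ref$keys)) stop("reference complex has no contacts")
  mod <- compute_contact_map(model, cutoff = cutoff)
  length(intersect(mod$keys, ref$keys)) / length(ref$keys)
}

#' Score a set of models against a reference complex
#'
#' @param models list of [cg_system()] models.
#' @param reference reference `cg_system`.
#' @param cutoff contact/interface cutoff (Angstrom).
#' @return Tibble with one row per model: `model`, `irmsd`, `lrmsd`,
#'   `lormsd`, `fnat`, and the CAPRI-style flag `acceptable`
#'   (iRMSD < 4 A).
#' @export
score_models <- function(models, reference, cutoff = 6) {
  stopifnot(length(models) >= 1L)
  res <- purrr::map_dfr(seq_along(models), function(k) {
    m <- models[[k]]
    tibble::tibble(
      model = k,
      irmsd = irmsd(m, reference, cutoff),
      lrmsd = lrmsd(m, reference),
      lormsd = lormsd(m, reference),
      fnat = fnat(m, reference, cutoff)
    )
  })
  res$acceptable <- res$irmsd < 4
  res
}
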