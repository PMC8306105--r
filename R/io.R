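# Ensemble I/O: multi-MODEL PDB writing of coarse-grained models, reading
# them back, run reports and manifests. Input PDBs are read with bio3d
# (see chain_from_pdb); the ensemble writer is a small fixed-width
# formatter for the package's own four-pseudo-atom models.

#' Write coarse-grained models as a multi-MODEL PDB file
#'
#' Each model is one MODEL/ENDMDL block; the receptor is chain A and the
#' ligand chain B. Every residue carries its C-alpha (CA), C-beta (CB) and
#' united side-chain centre (SC); peptide-bond centres (PB) are attached to
#' the first residue of their bond. Coordinates are written at the PDB's
#' 3-decimal precision, which round-trips the lattice exactly.
#'
#' @param x a [cg_system()], a list of them, or a `dock_pool` tibble.
#' @param path output file.
#' @param pseudo write CB/SC/PB pseudo-atoms as well as the C-alpha trace.
#' @return `path`, invisibly.
#' @export
write_models <- function(x, path, pseudo = TRUE) {
  systems <- if (inherits(x, "cg_system")) list(x)
  else if (inherits(x, "dock_pool"))
    lapply(seq_len(nrow(x)), function(r) pool_system(x, r))
  else x
  con <- file(path, "w")
  on.exit(close(con))
  for (mi in seq_along(systems)) {
    writeLines(sprintf("MODEL     %4d", mi), con)
    serial <- 0L
    sys <- systems[[mi]]
    chains <- Filter(Negate(is.null), list(A = sys$receptor, B = sys$ligand))
    for (ci in seq_along(chains)) {
      ch <- chains[[ci]]
      cid <- names(chains)[ci]
      xyz <- ca_xyz(ch)
      ps <- if (pseudo) rebuild_pseudo_atoms(ch) else NULL
      res3 <- bio3d::aa123(ch$seq)
      n <- nrow(xyz)
      for (i in seq_len(n)) {
        emit <- function(name, p) {
          serial <<- serial + 1L
          writeLines(sprintf(
            "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, res3[i], cid, i, p[1], p[2], p[3]), con)
        }
        emit("CA", xyz[i, ])
        if (pseudo) {
          emit("CB", ps$cb[i, ])
          emit("SC", ps$sc[i, ])
          if (i < n) emit("PB", ps$pb[i, ])
        }
      }
      writeLines("TER", con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read back a multi-MODEL coarse-grained ensemble
#'
#' Reads a file written by [write_models()]: extracts the C-alpha traces of
#' chains A (receptor) and B (ligand, if present) for every MODEL and
#' snaps them back onto the lattice (exact for files produced by the
#' writer).
#'
#' @param path PDB file.
#' @param lattice the lattice the models live on.
#' @return List of [cg_system()]s.
#' @export
read_models <- function(path, lattice = lattice_spec()) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  ca_sel <- which(at$elety == "CA")
  nmod <- dim(pdb$xyz)[1]
  mk_chain <- function(model_xyz, rows, role) {
    if (!length(rows)) return(NULL)
    seq1 <- bio3d::aa321(at$resid[rows])
    idx <- as.vector(t(cbind(3 * (rows - 1) + 1, 3 * (rows - 1) + 2,
                             3 * (rows - 1) + 3)))
    xyz <- matrix(model_xyz[idx], ncol = 3, byrow = TRUE)
    lat <- round(xyz / lattice$spacing)
    cg_chain(seq1, lat, lattice, role)
  }
  rows_a <- ca_sel[at$chain[ca_sel] == "A"]
  rows_b <- ca_sel[at$chain[ca_sel] == "B"]
  lapply(seq_len(nmod), function(m) {
    mx <- pdb$xyz[m, ]
    cg_system(mk_chain(mx, rows_a, "receptor"),
              mk_chain(mx, rows_b, "ligand"))
  })
}

#' Summarize docking accuracy as a one-row benchmark report
#'
#' Mirrors the usual benchmark-table layout: the ensemble-average
#' ligand-only RMSD, the best iRMSD/LRMSD/fNAT over all scored models, and
#' the same bests over a top-scored subset.
#'
#' @param scores tibble from [score_models()] for all models.
#' @param top_ids indices (into `scores$model`) of the top-scored subset;
#'   `NULL` for none.
#' @return One-row tibble (zero-row if `scores` is empty).
#' @export
docking_report <- function(scores, top_ids = NULL) {
  cols <- c("avg_lormsd", "best_irmsd_all", "best_lrmsd_all",
            "best_fnat_all", "best_irmsd_top", "best_lrmsd_top",
            "best_fnat_top")
  if (!nrow(scores)) {
    out <- tibble::as_tibble(stats::setNames(
      as.list(rep(list(numeric(0)), length(cols))), cols))
    return(out)
  }
  top <- if (is.null(top_ids)) scores[0, ] else
    scores[scores$model %in% top_ids, ]
  tibble::tibble(
    avg_lormsd = mean(scores$lormsd),
    best_irmsd_all = min(scores$irmsd),
    best_lrmsd_all = min(scores$lrmsd),
    best_fnat_all = max(scores$fnat),
    best_irmsd_top = if (nrow(top)) min(top$irmsd) else NA_real_,
    best_lrmsd_top = if (nrow(top)) min(top$lrmsd) else NA_real_,
    best_fnat_top = if (nrow(top)) max(top$fnat) else NA_real_
  )
}

#' Write / read a tabular report as TSV
#'
#' @param report a tibble (e.g. from [docking_report()] or
#'   [tidy.dock_clusters()]).
#' @param path file path.
#' @return `write_report` returns `path` invisibly; `read_report` the
#'   parsed tibble.
#' @export
write_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Run manifest for reproducibility
#'
#' Captures everything needed to reproduce a run bit-identically: the
#' configuration scalars, master seed, package version, per-stage timing
#' and the output file inventory.
#'
#' @param config a [docking_config()] (or any list of scalar settings).
#' @param seed the master seed actually used.
#' @param timings named numeric vector of per-stage wall-clock seconds.
#' @param outputs character vector of produced files.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(config, seed, timings = numeric(0),
                         outputs = character(0)) {
  scalars <- Filter(function(x) is.atomic(x) && length(x) == 1, unclass(config))
  structure(list(
    package = "cgdock",
    version = as.character(utils::packageVersion("cgdock")),
    seed = seed,
    config = scalars,
    timings = as.list(timings),
    outputs = outputs
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
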