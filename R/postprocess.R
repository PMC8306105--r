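#' Receptor-ligand contact map of a model
#'
#' Two residues (one per molecule) form a contact when their united
#' side-chain pseudo-atoms are at most `cutoff` apart; alanine is
#' represented by its C-beta and glycine by its C-alpha, which the
#' pseudo-atom builder already guarantees.
#'
#' @param model a [cg_system()] with a ligand.
#' @param cutoff contact distance cutoff (Angstrom), default 6.
#' @param model_id optional identifier stored with the map.
#' @return A `contact_map`: sorted key set over (receptor residue, ligand
#'   residue) pairs plus chain sizes; convert with [as_tibble()] to an edge
#'   list.
#' @export
compute_contact_map <- function(model, cutoff = 6, model_id = NA_integer_) {
  stopifnot(inherits(model, "cg_system"), !is.null(model$ligand))
  sc_r <- rebuild_pseudo_atoms(model$receptor)$sc
  sc_l <- rebuild_pseudo_atoms(model$ligand)$sc
  contact_map_from_sc(sc_r, sc_l, cutoff, model_id)
}

contact_map_from_sc <- function(sc_r, sc_l, cutoff = 6,
                                model_id = NA_integer_) {
  d2 <- outer(rowSums(sc_r^2), rowSums(sc_l^2), `+`) -
    2 * sc_r %*% t(sc_l)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  new_contact_map(cm_key(hit[, 1], hit[, 2]), nrow(sc_r), nrow(sc_l),
                  model_id)
}

CM_K <- 100000

cm_key <- function(rec, lig) sort((rec - 1) * CM_K + lig)

#' Construct a contact map from an explicit contact list
#'
#' @param rec_res,lig_res paired residue indices (1-based) of the
#'   contacting receptor/ligand residues.
#' @param nrec,nlig chain lengths.
#' @param model_id optional identifier.
#' @return A `contact_map`.
#' @export
contact_map <- function(rec_res, lig_res, nrec = max(rec_res, 1L),
                        nlig = max(lig_res, 1L), model_id = NA_integer_) {
  stopifnot(length(rec_res) == length(lig_res))
  if (length(rec_res) &&
      (any(rec_res < 1L) || any(rec_res > nrec) ||
         any(lig_res < 1L) || any(lig_res > nlig)))
    stop("contact indices out of range")
  new_contact_map(unique(cm_key(rec_res, lig_res)), nrec, nlig, model_id)
}

new_contact_map <- function(keys, nrec, nlig, model_id = NA_integer_) {
  structure(list(keys = as.numeric(keys), nrec = nrec, nlig = nlig,
                 model_id = model_id),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d contacts (%d x %d residues)\n",
              length(x$keys), x$nrec, x$nlig))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @exportS3Method tibble::as_tibble
as_tibble.contact_map <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id,
    rec_res = as.integer(x$keys %/% CM_K) + 1L,
    lig_res = as.integer(x$keys %% CM_K)
  )
}

#' Keep the models with the most receptor-ligand contacts
#'
#' Sorts the maps by contact count (descending) and keeps the top `keep`,
#' discarding transient and weakly bound poses. Ties are broken
#' deterministically by lower energy (when supplied) and then by model id.
#'
#' @param maps list of `contact_map`s.
#' @param keep number of maps to retain, default 1000. If fewer maps are
#'   supplied, all are kept with a warning.
#' @param energy optional numeric vector (one per map) used as tie-break.
#' @return The retained maps, in ranked order.
#' @export
contact_count_filter <- function(maps, keep = 1000L, energy = NULL) {
  n <- length(maps)
  counts <- vapply(maps, function(m) length(m$keys), 0L)
  ids <- vapply(maps, function(m) as.numeric(m$model_id), 0)
  ids[is.na(ids)] <- seq_len(n)[is.na(ids)]
  if (is.null(energy)) energy <- rep(0, n)
  ord <- order(-counts, energy, ids)
  if (n < keep) {
    warning("only ", n, " maps supplied; keeping all")
    keep <- n
  }
  maps[ord[seq_len(keep)]]
}

#' Jaccard distance between two contact maps
#'
#' `1 - |A and B| / |A or B|`; two empty maps are at distance 0 by
#' convention.
#'
#' @param a,b `contact_map`s.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  u <- length(union(a$keys, b$keys))
  if (u == 0L) return(0)
  1 - length(intersect(a$keys, b$keys)) / u
}

# Full pairwise Jaccard distance matrix via a sparse incidence matrix.
jaccard_matrix <- function(maps) {
  n <- length(maps)
  sizes <- vapply(maps, function(m) length(m$keys), 0L)
  allk <- sort(unique(unlist(lapply(maps, `[[`, "keys"))))
  if (!length(allk))
    return(matrix(0, n, n))
  M <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), sizes),
    j = match(unlist(lapply(maps, `[[`, "keys")), allk),
    x = 1, dims = c(n, length(allk))
  )
  inter <- as.matrix(Matrix::tcrossprod(M))
  uni <- outer(sizes, sizes, `+`) - inter
  D <- 1 - inter / pmax(uni, 1)
  D[uni == 0] <- 0  # both maps empty
  diag(D) <- 0
  D
}

#' Complete-link hierarchical clustering of contact maps
#'
#' Agglomerative clustering under the Jaccard distance with the
#' complete-linkage criterion (merge cost = maximum pairwise distance).
#' Maps are canonically ordered by model id before clustering, so the
#' resulting partition does not depend on input order.
#'
#' @param maps list of `contact_map`s.
#' @param n_clusters number of clusters to cut the dendrogram into
#'   (default 30, capped at the number of maps). Exactly one of
#'   `n_clusters` / `h` is used.
#' @param h optional distance threshold to cut at instead.
#' @return A `cluster_result`: list with `assign` (tibble: model_id,
#'   cluster), the ordered `maps`, and the distance matrix `D`.
#' @export
complete_link_cluster <- function(maps, n_clusters = 30L, h = NULL) {
  stopifnot(length(maps) >= 1L)
  ids <- vapply(maps, function(m) as.numeric(m$model_id), 0)
  if (anyNA(ids)) ids[is.na(ids)] <- seq_along(maps)[is.na(ids)]
  ord <- order(ids)
  maps <- maps[ord]
  ids <- ids[ord]
  n <- length(maps)
  if (n == 1L) {
    cl <- 1L
    D <- matrix(0, 1, 1)
  } else {
    D <- jaccard_matrix(maps)
    hc <- stats::hclust(stats::as.dist(D), method = "complete")
    cl <- if (!is.null(h)) stats::cutree(hc, h = h)
    else stats::cutree(hc, k = min(n_clusters, n))
  }
  structure(list(
    assign = tibble::tibble(model_id = ids, cluster = as.integer(cl)),
    maps = maps, D = D
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d maps in %d clusters\n",
              nrow(x$assign), length(unique(x$assign$cluster))))
  invisible(x)
}

#' Rank clusters by density and select representative models
#'
#' Cluster density is the member count divided by the average pairwise
#' Jaccard distance between members; a perfectly tight multi-member cluster
#' (average distance 0) has infinite density and ranks first, a singleton
#' has density 0 by convention and ranks last. The representative of a
#' cluster is the member minimizing the summed Jaccard distance to its
#' co-members (ties: lower energy, then lower model id). A cluster whose
#' members are all empty maps (no receptor-ligand contact, i.e. unbound
#' models that survived the filter) carries no binding-mode information and
#' gets density 0 regardless of size.
#'
#' @param clusters a `cluster_result` from [complete_link_cluster()].
#' @param k number of top clusters to select, default 10. With fewer
#'   clusters, all are returned with a warning.
#' @param energy optional named or plain numeric vector of model energies
#'   (aligned with the clustered maps' model ids) used in tie-breaks.
#' @return A `dock_clusters` tibble: one row per selected cluster with
#'   `rank`, `cluster`, `size`, `density`, `representative` (model id) and
#'   `members` (list-column of model ids).
#' @export
rank_and_select <- function(clusters, k = 10L, energy = NULL) {
  stopifnot(inherits(clusters, "cluster_result"))
  asg <- clusters$assign
  D <- clusters$D
  ids <- asg$model_id
  if (is.null(energy)) energy <- rep(0, length(ids))
  if (!is.null(names(energy))) energy <- energy[as.character(ids)]
  nct <- vapply(clusters$maps, function(mp) length(mp$keys), 0L)
  stats <- lapply(split(seq_along(ids), asg$cluster), function(ii) {
    m <- length(ii)
    if (m == 1L || max(nct[ii]) == 0L) {
      dens <- 0
      rep_i <- ii[order(energy[ii], ids[ii])][1]
    } else {
      sub <- D[ii, ii, drop = FALSE]
      avg <- mean(sub[upper.tri(sub)])
      dens <- if (avg == 0) Inf else m / avg
      ssum <- rowSums(sub)
      best <- which(ssum == min(ssum))
      best <- best[order(energy[ii][best], ids[ii][best])][1]
      rep_i <- ii[best]
    }
    tibble::tibble(cluster = asg$cluster[ii[1]], size = m, density = dens,
                   representative = ids[rep_i],
                   members = list(ids[ii]))
  })
  tab <- dplyr::bind_rows(stats)
  tab <- tab[order(-tab$density, -tab$size, tab$representative), ]
  if (nrow(tab) < k)
    warning("only ", nrow(tab), " clusters available; returning all")
  tab <- utils::head(tab, k)
  tab$rank <- seq_len(nrow(tab))
  tab <- tab[, c("rank", "cluster", "size", "density", "representative",
                 "members")]
  class(tab) <- c("dock_clusters", class(tab))
  tab
}

#' Tidy / summarize cluster selections
#'
#' `tidy()` returns the per-cluster table without the list-column;
#' `glance()` a one-row summary.
#'
#' @param x a `dock_clusters` object.
#' @param ... unused.
#' @export
tidy.dock_clusters <- function(x, ...) {
  out <- x
  out$members <- NULL
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.dock_clusters
#' @export
glance.dock_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x),
    n_models = sum(x$size),
    top_density = max(x$density),
    top_size = x$size[1]
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Cluster a docking pool end-to-end
#'
#' Pipeline over a pooled model set: compute receptor-ligand contact maps,
#' keep the `keep` models with the most contacts, cluster the retained maps
#' by complete-link Jaccard clustering, rank clusters by density and select
#' representatives.
#'
#' @param pool a `dock_pool` tibble from [run_docking()] / [run_remc()].
#' @param keep contact-count filter size (default 1000).
#' @param n_clusters dendrogram cut (default 30).
#' @param k number of selected clusters (default 10).
#' @param cutoff contact cutoff (Angstrom).
#' @return List with `selection` (a `dock_clusters` tibble), the
#'   `cluster_result`, and `maps` (all computed maps).
#' @export
cluster_models <- function(pool, keep = 1000L, n_clusters = 30L, k = 10L,
                           cutoff = 6) {
  maps <- pool_contact_maps(pool, cutoff = cutoff)
  energy <- stats::setNames(pool$e_total, pool$model_id)
  kept <- contact_count_filter(maps, keep = keep, energy = pool$e_total)
  cl <- complete_link_cluster(kept, n_clusters = n_clusters)
  sel <- rank_and_select(cl, k = k, energy = energy)
  list(selection = sel, clusters = cl, maps = maps)
}

# Contact maps for every model in a pool tibble.
pool_contact_maps <- function(pool, cutoff = 6) {
  tpl <- attr(pool, "template")
  stopifnot(!is.null(tpl), !is.null(tpl$ligand))
  lapply(seq_len(nrow(pool)), function(r) {
    sys <- pool_system(pool, r)
    compute_contact_map(sys, cutoff = cutoff, model_id = pool$model_id[r])
  })
}

#' Rebuild the cg_system of one pooled model
#'
#' @param pool a `dock_pool` tibble.
#' @param row row number in the pool.
#' @return A [cg_system()].
#' @export
pool_system <- function(pool, row) {
  tpl <- attr(pool, "template")
  co <- pool$coords[[row]]
  rec <- cg_chain(tpl$receptor$seq, co$receptor, tpl$receptor$lattice,
                  "receptor")
  lig <- if (is.null(tpl$ligand)) NULL else
    cg_chain(tpl$ligand$seq, co$ligand, tpl$ligand$lattice, "ligand")
  cg_system(rec, lig)
}
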