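# Contact maps, the contact-count filter, Jaccard distances, complete-link
# clustering and density ranking.

test_that("the 6 A side-chain criterion decides contacts at the boundary", {
  # 9 lattice units = 5.49 A apart -> every aligned pair is a contact
  near <- compute_contact_map(gly_pair(9L))
  el <- as_tibble(near)
  expect_true(all(paste(1:6, 1:6) %in% paste(el$rec_res, el$lig_res)))
  # 10 units = 6.10 A -> no contact survives the cutoff
  far <- compute_contact_map(gly_pair(10L))
  expect_length(far$keys, 0)
  # widely separated molecules -> empty map
  none <- compute_contact_map(gly_pair(50L))
  expect_length(none$keys, 0)
})

test_that("contact maps equal the brute-force double loop on a toy complex", {
  tc <- toy3()
  cm <- compute_contact_map(tc$reference)
  expect_gt(length(cm$keys), 0)
  sc_r <- rebuild_pseudo_atoms(tc$reference$receptor)$sc
  sc_l <- rebuild_pseudo_atoms(tc$reference$ligand)$sc
  bf <- bf_contacts(sc_r, sc_l, 6)
  el <- as_tibble(cm)
  expect_equal(nrow(el), nrow(bf))
  expect_setequal(paste(el$rec_res, el$lig_res), paste(bf[, 1], bf[, 2]))
})

test_that("the contact-count filter keeps the largest maps deterministically", {
  mk <- function(id, k) contact_map(rep(1L, k), seq_len(k), nrec = 5,
                                    nlig = 60, model_id = id)
  maps <- lapply(1:5, function(i) mk(i, c(5, 4, 3, 2, 1)[i]))
  kept <- contact_count_filter(maps, keep = 2)
  expect_equal(vapply(kept, function(m) m$model_id, 1), c(1, 2))
  # ties broken by energy then id
  tied <- lapply(1:4, function(i) mk(i, 3))
  kept2 <- contact_count_filter(tied, keep = 2, energy = c(5, 1, 1, 0))
  expect_equal(vapply(kept2, function(m) m$model_id, 1), c(4, 2))
  # all-empty maps: retained by tie-break, counts zero
  empties <- lapply(1:6, function(i) contact_map(integer(0), integer(0),
                                                 5, 5, model_id = i))
  kept3 <- contact_count_filter(empties, keep = 3)
  expect_equal(vapply(kept3, function(m) m$model_id, 1), 1:3)
  expect_warning(contact_count_filter(empties, keep = 10), "keeping all")
})

test_that("Jaccard distance follows set arithmetic and is a metric", {
  a <- contact_map(c(1, 3), c(2, 4), 10, 10)
  b <- contact_map(1, 2, 10, 10)
  expect_equal(jaccard_distance(a, a), 0)
  expect_equal(jaccard_distance(a, b), 0.5)
  disj <- contact_map(5, 5, 10, 10)
  expect_equal(jaccard_distance(a, disj), 1)
  e1 <- contact_map(integer(0), integer(0), 10, 10)
  expect_equal(jaccard_distance(e1, e1), 0)
  expect_equal(jaccard_distance(e1, b), 1)
  # triangle inequality on random maps
  set.seed(8)
  maps <- lapply(1:12, function(i) {
    k <- sample(0:6, 1)
    contact_map(sample(1:4, k, replace = TRUE),
                sample(1:6, k, replace = TRUE), 4, 6, model_id = i)
  })
  for (t in 1:200) {
    ijk <- sample(12, 3)
    dij <- jaccard_distance(maps[[ijk[1]]], maps[[ijk[2]]])
    djk <- jaccard_distance(maps[[ijk[2]]], maps[[ijk[3]]])
    dik <- jaccard_distance(maps[[ijk[1]]], maps[[ijk[3]]])
    expect_lte(dik, dij + djk + 1e-12)
  }
})

test_that("complete-link clustering matches brute force and is order-stable", {
  set.seed(14)
  mkmap <- function(id, base, extra) {
    contact_map(c(base[, 1], extra[, 1]), c(base[, 2], extra[, 2]),
                20, 20, model_id = id)
  }
  # two well-separated pairs
  b1 <- cbind(1:4, 1:4); b2 <- cbind(11:14, 11:14)
  maps4 <- list(mkmap(1, b1, cbind(5, 5)), mkmap(2, b1, cbind(6, 6)),
                mkmap(3, b2, cbind(15, 15)), mkmap(4, b2, cbind(16, 16)))
  cl <- complete_link_cluster(maps4, n_clusters = 2)
  expect_identical(partition_sets(cl$assign$cluster), list(1:2, 3:4))
  # identical maps collapse at any positive threshold
  same <- lapply(1:5, function(i) mkmap(i, b1, b1[0, , drop = FALSE]))
  cl_same <- complete_link_cluster(same, h = 0.01)
  expect_equal(length(unique(cl_same$assign$cluster)), 1)
  # as many clusters as maps -> singletons
  cl_single <- complete_link_cluster(maps4, n_clusters = 4)
  expect_equal(length(unique(cl_single$assign$cluster)), 4)
  # random instances vs naive agglomeration
  for (rep_i in 1:5) {
    n <- 8
    maps <- lapply(seq_len(n), function(i) {
      k <- sample(3:8, 1)
      contact_map(sample(1:5, k, replace = TRUE),
                  sample(1:8, k, replace = TRUE), 5, 8, model_id = i)
    })
    k <- sample(2:4, 1)
    cl_r <- complete_link_cluster(maps, n_clusters = k)
    D <- cgdock:::jaccard_matrix(maps)
    if (any(duplicated(signif(D[upper.tri(D)], 8)))) next  # tie: skip draw
    bf <- bf_complete_link(D, k)
    expect_identical(partition_sets(cl_r$assign$cluster), partition_sets(bf))
  }
  # input order does not change the partition
  sh <- sample(4)
  cl_sh <- complete_link_cluster(maps4[sh], n_clusters = 2)
  expect_identical(partition_sets(cl_sh$assign$cluster),
                   partition_sets(cl$assign$cluster))
})

test_that("density ranking follows count over mean distance", {
  # five maps sharing 6 contacts with one unique contact each: every
  # pairwise Jaccard distance is 1 - 6/8 = 0.25, density 5/0.25 = 20
  base <- cbind(1:6, 1:6)
  m5 <- lapply(1:5, function(i) contact_map(c(base[, 1], 10), c(base[, 2], i),
                                            20, 20, model_id = i))
  # a looser quintet-of-four on a disjoint 6-contact core with three unique
  # contacts each: pairwise distance 1 - 6/12 = 0.5, density 4/0.5 = 8
  base2 <- cbind(11:16, 11:16)
  m4 <- lapply(1:4, function(i)
    contact_map(c(base2[, 1], 17, 18, 19), c(base2[, 2], 3 * i, 3 * i + 1,
                                             3 * i + 2),
                20, 20, model_id = 5 + i))
  # one singleton far from both cores
  m1 <- list(contact_map(20, 20, 20, 20, model_id = 10))
  cl <- complete_link_cluster(c(m5, m4, m1), n_clusters = 3)
  sel <- rank_and_select(cl, k = 3)
  expect_equal(sel$density[1], 20)
  expect_equal(sel$size[1], 5)
  expect_equal(sel$density[2], 8)
  expect_equal(sel$density[3], 0)  # singleton convention, ranked last
  expect_true(sel$representative[1] %in% 1:5)
  expect_warning(rank_and_select(cl, k = 10), "returning all")
  td <- tidy(sel)
  expect_s3_class(td, "tbl_df")
  expect_false("members" %in% names(td))
  gl <- glance(sel)
  expect_equal(gl$n_models, 10)
})

test_that("the filter + cluster pipeline yields at most k representatives", {
  tc <- toy3()
  dec <- make_decoy_ensemble(tc$reference, n = 30, seed = 4)
  maps <- lapply(seq_along(dec$models), function(i)
    compute_contact_map(dec$models[[i]], model_id = i))
  kept <- suppressWarnings(contact_count_filter(maps, keep = 25))
  sel <- rank_and_select(complete_link_cluster(kept, n_clusters = 12), k = 10)
  expect_lte(nrow(sel), 10)
  expect_equal(anyDuplicated(sel$representative), 0)
})
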