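# Energy terms: restraint generation and flat-bottom penalty, contacts,
# hydrogen bonds, local bias, decomposition and incremental evaluation.

test_that("restraint generation applies the separation and distance windows", {
  # ideal helix: pair (i, i+4) sits ~6.2 A apart (inside the distance
  # window) but at separation 4 -> excluded; (i, i+6) ~9.8 A, sep 6 -> kept
  n <- 12
  xyz <- helix_ca(n)
  d59 <- sqrt(sum((xyz[5, ] - xyz[9, ])^2))
  d511 <- sqrt(sum((xyz[5, ] - xyz[11, ])^2))
  expect_true(d59 >= 5 && d59 <= 15)
  expect_true(d511 >= 5 && d511 <= 15)

  rs <- generate_restraints(xyz, min_seq_sep = 5, dmin = 5, dmax = 15)
  r <- rs$restraints
  expect_false(any(r$i == 5 & r$j == 9))     # separation 4: excluded
  hit <- r[r$i == 5 & r$j == 11, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$d0, d511)
  # brute-force enumeration of the qualifying pairs
  bf <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dd <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (j - i >= 5 && dd >= 5 && dd <= 15) bf <- rbind(bf, c(i, j, dd))
  }
  expect_equal(nrow(r), nrow(bf))
  expect_equal(cbind(r$i, r$j, r$d0), unname(bf))
})

test_that("a fully extended chain yields an empty restraint set", {
  xyz <- cbind(seq_len(30) * 3.8, 0, 0)
  expect_warning(rs <- generate_restraints(xyz), "empty restraint set")
  expect_equal(nrow(rs$restraints), 0)
  expect_equal(restraint_energy(xyz, rs), 0)
})

test_that("flat-bottom restraint energy is zero inside and linear outside", {
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  rs <- structure(list(
    restraints = tibble::tibble(i = 1L, j = 2L, d0 = 10, tol = 1, weight = 1),
    molecule = "receptor", weight_scale = 1), class = "restraint_set")
  expect_equal(restraint_energy(xyz, rs), 0)
  expect_equal(restraint_energy(rbind(c(0, 0, 0), c(10.8, 0, 0)), rs), 0)
  expect_equal(restraint_energy(rbind(c(0, 0, 0), c(12.5, 0, 0)), rs), 1.5)
  expect_equal(restraint_energy(rbind(c(0, 0, 0), c(8.2, 0, 0)), rs), 0.8)
  # continuity at the flat-bottom edge
  eps <- 1e-9
  e1 <- restraint_energy(rbind(c(0, 0, 0), c(11 - eps, 0, 0)), rs)
  e2 <- restraint_energy(rbind(c(0, 0, 0), c(11 + eps, 0, 0)), rs)
  expect_lt(abs(e2 - e1), 1e-6)
})

test_that("contact energy matches a brute-force pair loop", {
  ff <- default_forcefield()
  # two chains far apart everywhere (and no eligible intra pair in range)
  sc_far <- rbind(extended_ca(5), extended_ca(5) + 50)
  expect_equal(contact_energy(sc_far, rep("L", 10), ff,
                              chain = rep(1:2, each = 5)), 0)
  # single Leu-Leu inter-chain pair just inside the cutoff
  sc2 <- rbind(c(0, 0, 0), c(ff$contact_cutoff - 0.1, 0, 0))
  expect_equal(contact_energy(sc2, c("L", "L"), ff, chain = c(1, 2)),
               ff$contact_matrix["L", "L"])
  # and just outside
  sc3 <- rbind(c(0, 0, 0), c(ff$contact_cutoff + 0.1, 0, 0))
  expect_equal(contact_energy(sc3, c("L", "L"), ff, chain = c(1, 2)), 0)
  # random toy vs oracle, including hard-core overlaps
  set.seed(42)
  for (rep_i in 1:5) {
    sc <- matrix(runif(30, 0, 8), 10, 3)
    ca <- sc + matrix(rnorm(30, 0, 0.5), 10, 3)
    seq <- sample(AA_CODES, 10, replace = TRUE)
    chain <- rep(1:2, each = 5)
    expect_equal(contact_energy(sc, seq, ff, chain, ca = ca),
                 bf_contact_energy(sc, seq, ff, chain, ca = ca),
                 tolerance = 1e-9)
  }
})

test_that("hydrogen bonding favours the helix over the extended chain", {
  ff <- default_forcefield()
  energy_of <- function(ca, n) {
    ch <- project_to_lattice(ca, role = "receptor")
    ps <- rebuild_pseudo_atoms(ch)
    xyz <- ca_xyz(ch)
    hbond_energy(ps$pb, ff, bond_vectors = xyz[-1, ] - xyz[-n, ])
  }
  e_helix <- energy_of(helix_ca(16), 16)
  e_ext <- energy_of(extended_ca(16), 16)
  expect_lt(e_helix, e_ext)
  expect_equal(e_ext, 0)
})

test_that("local bias vanishes without a complete 4-mer and penalizes kinks", {
  ff <- default_forcefield()
  expect_equal(local_bias_energy(helix_ca(3), NULL, ff), 0)
  expect_equal(local_bias_energy(helix_ca(12), NULL, ff), 0)  # ideal helix
  expect_gt(local_bias_energy(rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0),
                                    c(0, 3.8, 0.2)), NULL, ff), 0)
})

test_that("all energy terms are invariant under rigid transformations", {
  ff <- default_forcefield()
  tc <- toy3()
  sys <- tc$reference
  rsets <- list(generate_restraints(ca_xyz(sys$receptor)),
                generate_restraints(ca_xyz(sys$ligand), molecule = "ligand"))
  e0 <- total_energy(sys, ff, rsets)
  ca_r <- ca_xyz(sys$receptor); ca_l <- ca_xyz(sys$ligand)
  seq_all <- c(sys$receptor$seq, sys$ligand$seq)
  chain <- rep(1:2, c(nrow(ca_r), nrow(ca_l)))
  set.seed(11)
  for (k in 1:20) {
    R <- random_rotation(); tr <- rnorm(3, sd = 20)
    xf <- function(x) x %*% t(R) + matrix(tr, nrow(x), 3, byrow = TRUE)
    pr <- rebuild_pseudo_atoms(xf(ca_r), sys$receptor$seq)
    pl <- rebuild_pseudo_atoms(xf(ca_l), sys$ligand$seq)
    e_ct <- contact_energy(rbind(pr$sc, pl$sc), seq_all, ff, chain,
                           ca = rbind(xf(ca_r), xf(ca_l)))
    expect_equal(e_ct, e0$contact, tolerance = 1e-9)
    e_lb <- local_bias_energy(rbind(xf(ca_r), xf(ca_l)), NULL, ff, chain)
    expect_equal(e_lb, e0$local, tolerance = 1e-9)
  }
})

test_that("the decomposition is additive and matches the sampler cache", {
  ff <- default_forcefield()
  tc <- toy3()
  sys <- tc$reference
  rsets <- list(generate_restraints(ca_xyz(sys$receptor)),
                generate_restraints(ca_xyz(sys$ligand), molecule = "ligand"))
  e <- total_energy(sys, ff, rsets)
  expect_equal(e$total, e$local + e$hbond + e$contact + e$restraint,
               tolerance = 1e-9)
  st <- sampler_state(sys, ff, rsets)
  expect_equal(st$energy$total, e$total, tolerance = 1e-9)
  # without restraints that component is exactly zero
  e2 <- total_energy(sys, ff, list())
  expect_identical(e2$restraint, 0)
})

test_that("single-move energy deltas equal full recomputation", {
  ff <- default_forcefield()
  tc <- toy3()
  sys <- tc$reference
  rsets <- list(generate_restraints(ca_xyz(sys$receptor)),
                generate_restraints(ca_xyz(sys$ligand), molecule = "ligand"))
  st <- sampler_state(sys, ff, rsets)
  mv <- cgdock:::resolve_moveset(st, default_moveset())
  set.seed(5)
  n_checked <- 0
  while (n_checked < 30) {
    pr <- cgdock:::draw_proposal(st, mv)
    if (is.null(pr)) next
    e_before <- cgdock:::state_full_energy(st)$total
    res <- cgdock:::state_try_move(st, pr$A, pr$new_ca)
    if (is.null(res)) next
    e_after <- cgdock:::state_full_energy(st)$total
    expect_equal(sum(res$delta), e_after - e_before, tolerance = 1e-6)
    cgdock:::state_commit(st, res$delta)
    n_checked <- n_checked + 1
  }
  expect_equal(st$energy$total, cgdock:::state_full_energy(st)$total,
               tolerance = 1e-6)
})

test_that("incremental energy does not drift over a long move sequence", {
  ff <- default_forcefield()
  tc <- toy3()
  sys <- tc$reference
  rsets <- list(generate_restraints(ca_xyz(sys$receptor)),
                generate_restraints(ca_xyz(sys$ligand), molecule = "ligand"))
  st <- sampler_state(sys, ff, rsets)
  mv <- cgdock:::resolve_moveset(st, default_moveset())
  set.seed(99)
  accepted <- 0
  tries <- 0
  while (accepted < 1000 && tries < 30000) {
    tries <- tries + 1
    pr <- cgdock:::draw_proposal(st, mv)
    if (is.null(pr)) next
    res <- cgdock:::state_try_move(st, pr$A, pr$new_ca)
    if (is.null(res)) next
    de <- sum(res$delta)
    if (de <= 0 || runif(1) < exp(-de / 2)) {
      cgdock:::state_commit(st, res$delta)
      accepted <- accepted + 1
    } else {
      cgdock:::state_revert(st, res$undo)
    }
  }
  expect_gte(accepted, 1000)
  expect_lt(abs(st$energy$total - cgdock:::state_full_energy(st)$total), 1e-4)
})

test_that("restraint sets survive a TSV round-trip", {
  rs <- generate_restraints(helix_ca(20), molecule = "ligand")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(rs, f)
  back <- read_restraints(f)
  expect_equal(back$molecule, "ligand")
  expect_equal(back$weight_scale, rs$weight_scale)
  expect_equal(as.data.frame(back$restraints), as.data.frame(rs$restraints),
               tolerance = 1e-6)
})
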