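# Monte Carlo machinery: temperature ladder, Metropolis rule, move
# proposals, replica exchange and the annealed REMC driver.

test_that("geometric temperature ladder hits both ends and the increment law", {
  tl <- build_temperature_ladder(1, 2, n = 3, r = 2)
  expect_equal(tl$temps, c(1, 4 / 3, 2))
  tl1 <- build_temperature_ladder(1, 3.5, n = 8, r = 1)
  expect_equal(diff(tl1$temps), rep(2.5 / 7, 7))
  tl20 <- build_temperature_ladder(1, 3.5, n = 20, r = 1.1)
  expect_length(tl20$temps, 20)
  expect_true(all(diff(tl20$temps) > 0))
  expect_equal(tl20$temps[1], 1)
  expect_equal(tl20$temps[20], 3.5)
  inc <- diff(tl20$temps)
  expect_equal(inc[-1] / inc[-length(inc)], rep(1.1, 18), tolerance = 1e-9)
  expect_error(build_temperature_ladder(2, 2, 5), "degenerate")
})

test_that("Metropolis acceptance reproduces its analytic rate", {
  set.seed(123)
  expect_true(all(vapply(1:50, function(i)
    metropolis_accept(-abs(rnorm(1)), runif(1, 0.1, 5)), TRUE)))
  hits <- sum(vapply(1:10000, function(i)
    metropolis_accept(1.7 * log(2), 1.7), TRUE))
  expect_equal(hits / 10000, 0.5, tolerance = 0.02)
})

test_that("a two-state system equilibrates to Boltzmann occupancy", {
  # states E = 0 and E = 1 at T = 1; target occupancy ratio exp(1)
  set.seed(7)
  state <- 0L
  counts <- c(0L, 0L)
  n <- 1e5
  for (i in seq_len(n)) {
    prop <- 1L - state
    de <- ifelse(prop == 1L, 1, -1)
    if (metropolis_accept(de, 1)) state <- prop
    counts[state + 1L] <- counts[state + 1L] + 1L
  }
  p <- 1 / (1 + exp(-1))  # closed-form occupancy of the ground state
  sd3 <- 3 * sqrt(p * (1 - p) * n)
  expect_lt(abs(counts[1] - p * n), sd3 * 3)  # wide: sweeps are correlated
  expect_equal(counts[1] / counts[2], exp(1), tolerance = 0.1)
})

test_that("move proposals have the declared footprints", {
  tc <- toy3()
  rsets <- list(generate_restraints(ca_xyz(tc$reference$receptor)))
  st <- sampler_state(tc$reference, rsets = rsets)
  set.seed(21)
  seen <- character(0)
  for (k in 1:400) {
    pr <- propose_move(st)
    if (!isTRUE(pr$valid)) next
    seen <- union(seen, pr$kind)
    nrec <- length(tc$reference$receptor$seq)
    nlig <- length(tc$reference$ligand$seq)
    if (pr$kind == "single") expect_length(pr$residues, 1)
    if (pr$kind == "single")
      expect_false(pr$residues[1] %in% c(1, nrec, nrec + 1, nrec + nlig))
    if (pr$kind == "end")
      expect_true(pr$residues[1] %in% c(1, nrec, nrec + 1, nrec + nlig))
    if (pr$kind == "shift2") expect_length(pr$residues, 2)
    if (pr$kind %in% c("lig_translate", "lig_rotate"))
      expect_identical(pr$residues, (nrec + 1L):(nrec + nlig))
    # proposing must not mutate the state
    expect_equal(st$energy$total, cgdock:::state_full_energy(st)$total,
                 tolerance = 1e-6)
  }
  expect_setequal(seen, c("single", "shift2", "end", "lig_translate",
                          "lig_rotate"))
})

test_that("single-bead proposals are symmetric (equal candidate sets)", {
  # the candidate set for a single-bead move depends only on the fixed
  # neighbours, so forward and reverse proposal probabilities coincide;
  # verify the candidate count is conserved across accepted moves
  tc <- toy3()
  st <- sampler_state(tc$reference)
  lat <- st$lattice
  count_cands <- function(i) {
    d <- st$ca[i + 1L, ] - st$ca[i - 1L, ]
    ok <- cgdock:::key_is_allowed(
      cgdock:::vec_key(matrix(d, nrow(lat$vectors), 3, byrow = TRUE) -
                         lat$vectors), lat)
    sum(ok)
  }
  set.seed(31)
  checked <- 0
  while (checked < 100) {
    i <- sample(2:(st$n - 1), 1)
    if (i == st$chain_end[1] || i == st$chain_start[2]) next
    before <- count_cands(i)
    # try a random candidate write
    d <- st$ca[i + 1L, ] - st$ca[i - 1L, ]
    ok <- cgdock:::key_is_allowed(
      cgdock:::vec_key(matrix(d, nrow(lat$vectors), 3, byrow = TRUE) -
                         lat$vectors), lat)
    cand <- lat$vectors[ok, , drop = FALSE]
    new_ca <- matrix(st$ca[i - 1L, ] + cand[sample.int(nrow(cand), 1), ], 1, 3)
    res <- cgdock:::state_try_move(st, i, new_ca)
    if (is.null(res)) next
    expect_identical(count_cands(i), before)
    cgdock:::state_revert(st, res$undo)
    checked <- checked + 1
  }
})

test_that("replica exchange preserves conformations and follows the criterion", {
  ladder <- build_temperature_ladder(1, 2, n = 2, r = 1)
  mk <- function(e, rung, id) list(energy = e, rung = rung, id = id)
  # equal energies: always swap
  set.seed(1)
  for (k in 1:20) {
    out <- replica_exchange_sweep(list(mk(-5, 1L, "a"), mk(-5, 2L, "b")),
                                  ladder, parity = 1)
    expect_equal(vapply(out, `[[`, 1L, "rung"), c(2L, 1L))
  }
  # energies strongly ordered with temperature: acceptance -> 0
  swaps <- 0
  for (k in 1:200) {
    out <- replica_exchange_sweep(list(mk(-100, 1L, "a"), mk(100, 2L, "b")),
                                  ladder, parity = 1)
    if (out[[1]]$rung == 2L) swaps <- swaps + 1
  }
  expect_equal(swaps, 0)
  # permutation and multiset conservation over many random sweeps
  ladder4 <- build_temperature_ladder(1, 3, n = 4, r = 1.2)
  reps <- lapply(1:4, function(k) mk(rnorm(1), k, letters[k]))
  for (k in 1:50) {
    reps <- replica_exchange_sweep(reps, ladder4, parity = k)
    rungs <- vapply(reps, `[[`, 1L, "rung")
    expect_setequal(rungs, 1:4)
    expect_identical(sort(vapply(reps, `[[`, "", "id")), letters[1:4])
  }
  expect_error(replica_exchange_sweep(list(mk(0, 1L, "a"), mk(0, 1L, "b")),
                                      ladder), "one replica per rung")
})

test_that("the REMC driver honours pool size, schedule and determinism", {
  tc <- make_toy_complex(receptor_size = 14, ligand_size = 8, seed = 2)
  sys <- tc$reference
  rsets <- list(generate_restraints(ca_xyz(sys$receptor)),
                generate_restraints(ca_xyz(sys$ligand), molecule = "ligand"))
  cfg <- remc_config(n_replicas = 3, t_min = 0.8, t_max = 2.5, ratio = 1.2,
                     annealing_steps = 4, cooling = 0.9,
                     snapshot_per_replica = 8, snapshot_fraction = 0.2,
                     seed = 17)
  pool <- run_remc(sys, rsets = rsets, config = cfg)
  # pool size and snapshot fraction are exact
  expect_equal(nrow(pool), 3 * 8)
  expect_equal(nrow(pool) / (3 * cfg$total_sweeps), cfg$snapshot_fraction)
  expect_setequal(unique(pool$replica), 1:3)
  expect_true(all(table(pool$replica) == 8))
  # annealing cools the whole ladder monotonically
  by_stage <- tapply(pool$temp, pool$stage, max)
  expect_true(all(diff(by_stage) < 0))
  # every snapshot satisfies the model invariants (constructor validates)
  for (r in sample(nrow(pool), 10))
    expect_s3_class(pool_system(pool, r), "cg_system")
  # bit-identical replay under the same master seed
  pool2 <- run_remc(sys, rsets = rsets, config = cfg)
  expect_identical(pool$coords, pool2$coords)
  expect_identical(pool$e_total, pool2$e_total)
  # different seed gives a different trajectory
  cfg2 <- remc_config(n_replicas = 3, t_min = 0.8, t_max = 2.5, ratio = 1.2,
                      annealing_steps = 4, cooling = 0.9,
                      snapshot_per_replica = 8, snapshot_fraction = 0.2,
                      seed = 18)
  pool3 <- run_remc(sys, rsets = rsets, config = cfg2)
  expect_false(identical(pool$coords, pool3$coords))
})

test_that("hotter rungs sample higher average energies", {
  tc <- make_toy_complex(receptor_size = 14, ligand_size = 8, seed = 2)
  sys <- tc$reference
  rsets <- list(generate_restraints(ca_xyz(sys$receptor)),
                generate_restraints(ca_xyz(sys$ligand), molecule = "ligand"))
  cfg <- remc_config(n_replicas = 4, t_min = 0.7, t_max = 4, ratio = 1,
                     annealing_steps = 1, cooling = 1,
                     snapshot_per_replica = 40, snapshot_fraction = 0.5,
                     seed = 5)
  pool <- run_remc(sys, rsets = rsets, config = cfg)
  # drop the first half as burn-in, average by rung
  eq <- pool[pool$sweep > max(pool$sweep) / 2, ]
  avg <- tapply(eq$e_total, eq$rung, mean)
  expect_length(avg, 4)
  expect_true(all(diff(avg) > 0))
})
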