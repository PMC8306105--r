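#' Temperature ladder with geometrically increasing increments
#'
#' Builds the `n` replica temperatures between `t_min` and `t_max` so that
#' the increment between consecutive rungs grows geometrically with ratio
#' `r`: the first increment is solved from the geometric-series sum so the
#' last rung lands exactly on `t_max`. `r = 1` reduces to the classical
#' constant-increment ladder; `r > 1` concentrates rungs at the cold end,
#' which helps cold replicas exchange while the hottest rungs stay far
#' apart for large-scale motion.
#'
#' @param t_min,t_max coldest and hottest temperatures (kT scale),
#'   `t_min < t_max`.
#' @param n number of rungs (>= 2); default 20.
#' @param r geometric ratio of successive increments (> 0); default 1.1.
#' @return A `temperature_ladder`: list with `temps` (strictly increasing),
#'   `r`, `t_min`, `t_max`.
#' @examples
#' build_temperature_ladder(1, 2, n = 3, r = 2)$temps  # 1, 4/3, 2
#' @export
build_temperature_ladder <- function(t_min, t_max, n = 20L, r = 1.1) {
  stopifnot(n >= 2L, r > 0)
  if (!(t_min < t_max)) stop("degenerate ladder: t_min must be < t_max")
  d0 <- if (abs(r - 1) < 1e-12) (t_max - t_min) / (n - 1)
  else (t_max - t_min) * (1 - r) / (1 - r^(n - 1))
  temps <- t_min + cumsum(c(0, d0 * r^(0:(n - 2))))
  temps[n] <- t_max
  structure(list(temps = temps, r = r, t_min = t_min, t_max = t_max),
            class = "temperature_ladder")
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("<temperature_ladder> %d rungs, %.3g .. %.3g (r = %.3g)\n",
              length(x$temps), x$t_min, x$t_max, x$r))
  invisible(x)
}

#' Metropolis acceptance
#'
#' Accepts with probability `min(1, exp(-delta_e / temp))`.
#'
#' @param delta_e proposed energy change (kT).
#' @param temp temperature (kT scale, > 0).
#' @return Logical.
#' @export
metropolis_accept <- function(delta_e, temp) {
  stopifnot(temp > 0)
  delta_e <= 0 || stats::runif(1) < exp(-delta_e / temp)
}

#' One replica-exchange attempt over adjacent rung pairs
#'
#' Attempts swaps between the replicas occupying adjacent temperature rungs
#' of one parity (even or odd pair starts), with the usual exchange
#' criterion `min(1, exp((beta_i - beta_j) (E_i - E_j)))`. Only the rung
#' assignment moves between replicas, so the multiset of conformations is
#' preserved and the assignment stays a permutation.
#'
#' @param replicas list of replicas; each must carry numeric `energy` and
#'   integer `rung` fields (other fields are passed through).
#' @param ladder a [build_temperature_ladder()] result (possibly cooled).
#' @param parity 0 attempts pairs (1,2), (3,4), ...; 1 attempts (2,3),
#'   (4,5), ...
#' @return The replica list with updated `rung` fields.
#' @export
replica_exchange_sweep <- function(replicas, ladder, parity = 0L) {
  temps <- ladder$temps
  n <- length(replicas)
  rungs <- vapply(replicas, `[[`, 1L, "rung")
  if (!setequal(rungs, seq_len(n)))
    stop("need exactly one replica per rung")
  at <- match(seq_len(n), rungs)  # replica index occupying each rung
  for (p in seq_len(n - 1L)) {
    if (p %% 2L != parity %% 2L) next
    a <- at[p]; b <- at[p + 1L]
    ea <- replicas[[a]]$energy; eb <- replicas[[b]]$energy
    larg <- (1 / temps[p] - 1 / temps[p + 1L]) * (ea - eb)
    if (larg >= 0 || stats::runif(1) < exp(larg)) {
      replicas[[a]]$rung <- p + 1L
      replicas[[b]]$rung <- p
      at[p] <- b; at[p + 1L] <- a
    }
  }
  replicas
}

#' Configuration for a replica-exchange simulated-annealing run
#'
#' Defaults follow the docking protocol: 20 replicas, 20 annealing stages,
#' 500 saved snapshots per replica amounting to 2% of generated models.
#' The temperature ladder and annealing cooling factor are model-scale
#' choices: the default cold end freezes a restrained toy complex while the
#' hot end allows ligand unfolding.
#'
#' @param n_replicas number of replicas (ladder rungs).
#' @param t_min,t_max,ratio ladder parameters, see
#'   [build_temperature_ladder()].
#' @param annealing_steps number of annealing stages.
#' @param cooling multiplicative factor applied to the whole ladder at each
#'   stage after the first (in (0, 1]).
#' @param snapshot_per_replica snapshots saved per replica.
#' @param snapshot_fraction fraction of generated models saved (snapshots
#'   are taken every `1/snapshot_fraction` sweeps); together with
#'   `snapshot_per_replica` this fixes the total sweep count.
#' @param exchange_every attempt replica exchanges every this many sweeps.
#' @param seed master seed; all replica streams derive from it.
#' @param moveset a [default_moveset()].
#' @param verify_every full-energy audits of the incremental energy cache
#'   every this many sweeps (0 = at snapshots only).
#' @return A `remc_config` list.
#' @export
remc_config <- function(n_replicas = 20L, t_min = 1.0, t_max = 3.5,
                        ratio = 1.1, annealing_steps = 20L, cooling = 0.95,
                        snapshot_per_replica = 500L,
                        snapshot_fraction = 0.02, exchange_every = 5L,
                        seed = 1L, moveset = default_moveset(),
                        verify_every = 0L) {
  stopifnot(n_replicas >= 1L, annealing_steps >= 1L,
            cooling > 0, cooling <= 1,
            snapshot_fraction > 0, snapshot_fraction <= 1)
  save_every <- 1 / snapshot_fraction
  if (abs(save_every - round(save_every)) > 1e-9)
    stop("1/snapshot_fraction must be an integer number of sweeps")
  total_sweeps <- snapshot_per_replica * round(save_every)
  if (total_sweeps %% annealing_steps != 0)
    stop("total sweeps (snapshot_per_replica / snapshot_fraction) must be ",
         "divisible by annealing_steps")
  structure(list(
    n_replicas = as.integer(n_replicas), t_min = t_min, t_max = t_max,
    ratio = ratio, annealing_steps = as.integer(annealing_steps),
    cooling = cooling,
    snapshot_per_replica = as.integer(snapshot_per_replica),
    snapshot_fraction = snapshot_fraction,
    save_every = as.integer(round(save_every)),
    total_sweeps = as.integer(total_sweeps),
    sweeps_per_stage = as.integer(total_sweeps / annealing_steps),
    exchange_every = as.integer(exchange_every), seed = as.integer(seed),
    moveset = moveset, verify_every = as.integer(verify_every)
  ), class = "remc_config")
}

#' Replica Exchange Monte Carlo with simulated annealing
#'
#' Runs `n_replicas` coupled Monte Carlo simulations over the geometric
#' temperature ladder, cooling the whole ladder by the configured factor at
#' every annealing stage, attempting adjacent-rung exchanges periodically,
#' and saving the configured fraction of generated models as snapshots.
#' Each replica consumes an independent L'Ecuyer-CMRG substream derived
#' from the master seed, so runs are exactly reproducible. At every
#' snapshot the incrementally maintained energy of each replica is audited
#' against a from-scratch recomputation; divergence beyond 1e-4 kT is a
#' hard failure.
#'
#' @param systems a single [cg_system()] (used for every replica) or a list
#'   of `n_replicas` systems (each replica its own starting arrangement).
#' @param ff force field.
#' @param rsets list of `restraint_set`s.
#' @param config an [remc_config()].
#' @return A `dock_pool` tibble: one row per saved snapshot with replica,
#'   sweep, stage, rung, temperature, energy decomposition and lattice
#'   coordinates (`coords` list-column), plus attributes `template` (chain
#'   templates), `ladder` and `log` (per-stage acceptance statistics).
#' @export
run_remc <- function(systems, ff = default_forcefield(), rsets = list(),
                     config = remc_config()) {
  stopifnot(inherits(config, "remc_config"))
  R <- config$n_replicas
  if (inherits(systems, "cg_system"))
    systems <- rep(list(systems), R)
  if (length(systems) != R)
    stop("need one starting system per replica (", R, ")")

  ladder <- build_temperature_ladder(config$t_min, config$t_max, R,
                                     config$ratio)

  # reproducible independent substreams per replica + one for exchanges
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(config$seed)
  s <- get(".Random.seed", .GlobalEnv)
  ex_stream <- parallel::nextRNGStream(s)
  streams <- vector("list", R)
  s2 <- ex_stream
  for (k in seq_len(R)) {
    s2 <- parallel::nextRNGStream(s2)
    streams[[k]] <- s2
  }

  states <- lapply(systems, sampler_state, ff = ff, rsets = rsets)
  mvs <- lapply(states, resolve_moveset, moveset = config$moveset)
  rung <- seq_len(R)

  n_snap_rows <- R * config$snapshot_per_replica
  snap <- vector("list", n_snap_rows)
  srow <- 0L
  log_rows <- list()
  ex_attempt <- 0L
  gsweep <- 0L

  for (stage in seq_len(config$annealing_steps)) {
    temps <- ladder$temps * config$cooling^(stage - 1L)
    acc_stage <- integer(R)
    for (sw in seq_len(config$sweeps_per_stage)) {
      gsweep <- gsweep + 1L
      for (k in seq_len(R)) {
        assign(".Random.seed", streams[[k]], .GlobalEnv)
        acc_stage[k] <- acc_stage[k] +
          sweep_state(states[[k]], temps[rung[k]], mvs[[k]])
        streams[[k]] <- get(".Random.seed", .GlobalEnv)
      }
      if (gsweep %% config$exchange_every == 0L) {
        assign(".Random.seed", ex_stream, .GlobalEnv)
        reps <- lapply(seq_len(R), function(k)
          list(energy = states[[k]]$energy$total, rung = rung[k]))
        reps <- replica_exchange_sweep(
          reps, list(temps = temps), parity = ex_attempt %% 2L)
        rung <- vapply(reps, `[[`, 1L, "rung")
        ex_attempt <- ex_attempt + 1L
        ex_stream <- get(".Random.seed", .GlobalEnv)
      }
      if (gsweep %% config$save_every == 0L) {
        for (k in seq_len(R)) {
          st <- states[[k]]
          full <- state_full_energy(st)
          if (abs(full$total - st$energy$total) > 1e-4)
            stop(sprintf(
              "energy cache divergence on replica %d at sweep %d: %.3g kT",
              k, gsweep, abs(full$total - st$energy$total)))
          e <- st$energy
          co <- list(receptor = st$ca[st$chain_start[1]:st$chain_end[1], ,
                                      drop = FALSE])
          if (st$nch > 1L)
            co$ligand <- st$ca[st$chain_start[2]:st$chain_end[2], ,
                               drop = FALSE]
          srow <- srow + 1L
          snap[[srow]] <- list(
            replica = k, sweep = gsweep, stage = stage, rung = rung[k],
            temp = temps[rung[k]], e_local = e$local, e_hbond = e$hbond,
            e_contact = e$contact, e_restraint = e$restraint,
            e_total = e$total, coords = co
          )
        }
      }
    }
    log_rows[[stage]] <- tibble::tibble(
      stage = stage, replica = seq_len(R), rung = rung,
      temp = temps[rung],
      acceptance = acc_stage / (config$sweeps_per_stage *
                                  vapply(states, function(s) s$n, 1L))
    )
  }

  pool <- tibble::tibble(
    replica = vapply(snap, `[[`, 1L, "replica"),
    sweep = vapply(snap, `[[`, 1L, "sweep"),
    stage = vapply(snap, `[[`, 1L, "stage"),
    rung = vapply(snap, `[[`, 1L, "rung"),
    temp = vapply(snap, `[[`, 0, "temp"),
    e_local = vapply(snap, `[[`, 0, "e_local"),
    e_hbond = vapply(snap, `[[`, 0, "e_hbond"),
    e_contact = vapply(snap, `[[`, 0, "e_contact"),
    e_restraint = vapply(snap, `[[`, 0, "e_restraint"),
    e_total = vapply(snap, `[[`, 0, "e_total"),
    coords = lapply(snap, `[[`, "coords")
  )
  pool <- pool[order(pool$replica, pool$sweep), ]
  pool$model_id <- seq_len(nrow(pool))
  tpl <- systems[[1]]
  attr(pool, "template") <- list(receptor = tpl$receptor,
                                 ligand = tpl$ligand)
  attr(pool, "ladder") <- ladder
  attr(pool, "log") <- dplyr::bind_rows(log_rows)
  class(pool) <- c("dock_pool", class(pool))
  pool
}
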