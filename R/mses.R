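#' @useDynLib vaemses, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Boltzmann's constant in kcal/mol/K
#' @export
kB <- 0.0019872041

#' Bead-model force field
#'
#' Harmonic bonds along the chain, elastic-network contacts, and a soft
#' (WCA-like) excluded-volume repulsion that vanishes beyond `sigma`.
#' Optionally per-bead harmonic position tethers (used for the harmonic-well
#' reference systems in the integrator checks).
#'
#' @param bonds Integer matrix `m x 2` of bonded bead pairs (1-based).
#' @param bond_r0,bond_k Equilibrium lengths (Angstrom) and spring constants
#'   (kcal/mol/A^2), recycled to `nrow(bonds)`.
#' @param contacts Integer matrix of elastic-network pairs (may have 0 rows).
#' @param contact_r0,contact_k As for bonds.
#' @param sigma Excluded-volume diameter (Angstrom).
#' @param eps Excluded-volume strength (kcal/mol).
#' @param pos_k Optional per-bead tether constants (kcal/mol/A^2).
#' @param pos_ref Tether reference coordinates (`n x 3`), required with
#'   `pos_k`.
#' @return Object of class `bead_forcefield`.
#' @export
bead_forcefield <- function(bonds, bond_r0, bond_k,
                            contacts = matrix(integer(0), 0, 2),
                            contact_r0 = numeric(0), contact_k = numeric(0),
                            sigma = 3.8, eps = 0.3,
                            pos_k = NULL, pos_ref = NULL) {
  bonds <- rbind(bonds); contacts <- rbind(contacts)
  storage.mode(bonds) <- "integer"; storage.mode(contacts) <- "integer"
  bond_r0 <- rep_len(bond_r0, nrow(bonds))
  bond_k <- rep_len(bond_k, nrow(bonds))
  if (nrow(contacts)) {
    contact_r0 <- rep_len(contact_r0, nrow(contacts))
    contact_k <- rep_len(contact_k, nrow(contacts))
  }
  if (any(c(bond_k, contact_k) <= 0) || sigma <= 0 || eps < 0)
    stop("force constants must be positive")
  if (!is.null(pos_k) && is.null(pos_ref))
    stop("pos_ref is required with pos_k")
  structure(list(bonds = bonds, bond_r0 = bond_r0, bond_k = bond_k,
                 contacts = contacts, contact_r0 = contact_r0,
                 contact_k = contact_k, dual = FALSE,
                 sigma = sigma, eps = eps,
                 pos_k = pos_k, pos_ref = pos_ref),
            class = "bead_forcefield")
}

#' Single-basin elastic network from a reference structure
#'
#' Chain bonds connect consecutive beads; contacts are all bead pairs
#' separated by more than one bond whose reference distance is below
#' `cutoff`, plus any `extra_pairs` (e.g. an inter-domain lattice), all with
#' equilibrium lengths taken from the reference.
#'
#' @param reference `n x 3` coordinate matrix (Angstrom).
#' @param cutoff Contact cutoff (Angstrom).
#' @param k_bond,k_en Bond / contact spring constants (kcal/mol/A^2).
#' @param extra_pairs Optional integer matrix of additional contact pairs.
#' @param k_extra Spring constant for the extra pairs.
#' @param stiffness_scale Multiplies every spring constant (the holo
#'   rigidification proxy uses 2).
#' @inheritParams bead_forcefield
#' @return A [bead_forcefield()].
#' @export
elastic_network <- function(reference, cutoff = 10, k_bond = 100, k_en = 2,
                            extra_pairs = NULL, k_extra = k_en,
                            stiffness_scale = 1, sigma = 3.8, eps = 0.3) {
  reference <- as.matrix(reference)
  n <- nrow(reference)
  dm <- as.matrix(stats::dist(reference))
  bonds <- cbind(seq_len(n - 1L), 2:n)
  idx <- which(upper.tri(dm) & dm < cutoff, arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] > 1L, , drop = FALSE]
  k_con <- rep(k_en, nrow(idx))
  if (!is.null(extra_pairs)) {
    ep <- rbind(extra_pairs)
    ep <- t(apply(ep, 1, sort))
    dup <- paste(ep[, 1], ep[, 2]) %in% paste(idx[, 1], idx[, 2])
    ep <- ep[!dup, , drop = FALSE]
    idx <- rbind(idx, ep)
    k_con <- c(k_con, rep(k_extra, nrow(ep)))
  }
  bead_forcefield(bonds, dm[bonds], k_bond * stiffness_scale,
                  idx, dm[idx], k_con * stiffness_scale,
                  sigma = sigma, eps = eps)
}

#' Dual-basin force field embedding two reference structures
#'
#' The contact term becomes the log-sum-exp mixture
#' `V = -(1/beta_mix) log(exp(-beta_mix V_a) + exp(-beta_mix V_b))` of the
#' elastic networks of the two references (shared contact topology, two sets
#' of equilibrium lengths); bonds and excluded volume are common. In the
#' `beta_mix -> Inf` limit this tends to `min(V_a, V_b)` pointwise.
#'
#' @param ff_a A single-basin [bead_forcefield()] (defines the topology and
#'   basin-A equilibrium lengths).
#' @param reference_b `n x 3` coordinates of the second basin.
#' @param beta_mix Mixing inverse-temperature (1/(kcal/mol)); smaller values
#'   smooth the crossing region, larger values sharpen the barrier.
#' @return A `bead_forcefield` with `dual = TRUE`.
#' @export
dual_basin_forcefield <- function(ff_a, reference_b, beta_mix = 0.2) {
  stopifnot(inherits(ff_a, "bead_forcefield"), beta_mix > 0)
  dmb <- as.matrix(stats::dist(as.matrix(reference_b)))
  ff <- ff_a
  ff$dual <- TRUE
  ff$contact_r0_b <- dmb[ff$contacts]
  ff$beta_mix <- beta_mix
  ff
}

ff_to_cpp <- function(ff) {
  list(bonds = ff$bonds, bond_r0 = ff$bond_r0, bond_k = ff$bond_k,
       contacts = ff$contacts, contact_r0 = ff$contact_r0,
       contact_k = ff$contact_k, dual = isTRUE(ff$dual),
       contact_r0_b = ff$contact_r0_b, beta_mix = ff$beta_mix,
       sigma = ff$sigma, eps = ff$eps,
       pos_k = ff$pos_k,
       pos_ref = if (!is.null(ff$pos_k)) as.matrix(ff$pos_ref))
}

#' Potential energy and forces of a bead force field
#'
#' @param coords `n x 3` coordinates (Angstrom).
#' @param ff A [bead_forcefield()].
#' @return List with `$energy` (kcal/mol) and `$forces` (`n x 3`,
#'   kcal/mol/A).
#' @export
forcefield_energy <- function(coords, ff) {
  cpp_ff_energy(as.matrix(coords), ff_to_cpp(ff))
}

#' Harmonic distance-restraint coupling energy
#'
#' `E = k * sum_p (d_p(coords) - target_p)^2` over the restrained pairs,
#' with analytic forces; identically zero for the unbiased `k = 0` replica.
#'
#' @param coords `n x 3` bead coordinates (Angstrom).
#' @param restraint_row Target distances, one per pair (Angstrom).
#' @param pairs Integer matrix `n_pairs x 2` of bead indices (1-based).
#' @param k Coupling constant (kcal/mol/A^2).
#' @return List with `$energy` and `$forces`.
#' @export
coupling_energy <- function(coords, restraint_row, pairs, k) {
  pairs <- rbind(pairs); storage.mode(pairs) <- "integer"
  if (length(restraint_row) != nrow(pairs))
    stop("restraint_row length must equal the number of pairs")
  if (k < 0) stop("k must be nonnegative")
  cpp_coupling_energy(as.matrix(coords), pairs, as.numeric(restraint_row), k)
}

pair_distances <- function(coords, pairs) {
  pairs <- rbind(pairs)
  sqrt(rowSums((coords[pairs[, 1], , drop = FALSE] -
                coords[pairs[, 2], , drop = FALSE])^2))
}

#' Maxwell-Boltzmann velocities
#'
#' @param n Number of beads.
#' @param mass Per-bead masses (amu), recycled.
#' @param temperature K.
#' @return `n x 3` velocity matrix (A/ps). Uses the current R RNG stream.
#' @export
maxwell_velocities <- function(n, mass, temperature) {
  mass <- rep_len(mass, n)
  matrix(stats::rnorm(n * 3, sd = sqrt(kB * temperature * 418.4 / rep(mass, 3))),
         n, 3)
}

#' Run Langevin dynamics (BAOAB)
#'
#' One stretch of BAOAB-discretized Langevin dynamics under the force field
#' plus an optional fixed distance-restraint coupling. With `friction = 0`
#' no thermostat is applied and the update reduces to velocity Verlet.
#'
#' @param coords `n x 3` starting coordinates.
#' @param ff A [bead_forcefield()].
#' @param n_steps Number of steps.
#' @param dt Timestep (ps).
#' @param friction Collision frequency (1/ps).
#' @param temperature K.
#' @param mass Per-bead masses (amu), recycled.
#' @param seed Integer seed of the integrator's noise stream (bitwise
#'   deterministic given the same seed on one platform).
#' @param vels Starting velocities; Maxwell-Boltzmann drawn from the current
#'   R RNG stream when `NULL`.
#' @param restraints Optional list `(pairs, target, k)` for the coupling.
#' @param save_every Save a frame every this many steps (0 = none).
#' @return List: `$coords`, `$vels`, `$energy` (final potential), and with
#'   `save_every > 0` `$frames` (`n_saved x n x 3`) and `$epot`.
#' @export
run_langevin <- function(coords, ff, n_steps, dt = 0.01, friction = 1,
                         temperature = 300, mass = 110, seed = 1,
                         vels = NULL, restraints = NULL, save_every = 0L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  mass <- rep_len(mass, n)
  if (dt <= 0) stop("dt must be positive")
  if (is.null(vels)) vels <- maxwell_velocities(n, mass, temperature)
  if (is.null(restraints)) {
    pairs <- matrix(integer(0), 0, 2); target <- numeric(0); k <- 0
  } else {
    pairs <- rbind(restraints$pairs); storage.mode(pairs) <- "integer"
    target <- as.numeric(restraints$target); k <- restraints$k
    if (length(target) != nrow(pairs))
      stop("restraint target length must equal the number of pairs")
  }
  cpp_run_langevin(coords, as.matrix(vels), mass, ff_to_cpp(ff),
                   pairs, target, k, as.integer(n_steps), dt, friction,
                   temperature, as.numeric(seed), as.integer(save_every))
}

#' Replica-exchange ladder configuration
#'
#' @param k_values Ascending coupling constants (kcal/mol/A^2); the first
#'   must be exactly 0 (the unbiased replica).
#' @param exchange_interval ps of dynamics between exchange sweeps.
#' @param n_exchanges Number of exchange windows.
#' @param temperature K.
#' @param friction 1/ps.
#' @param timestep ps.
#' @return Object of class `ladder_config`.
#' @export
ladder_config <- function(k_values = default_ladder_k(), exchange_interval = 40,
                          n_exchanges = 100L, temperature = 300, friction = 1,
                          timestep = 0.01) {
  if (k_values[1] != 0) stop("the first ladder rung must be k = 0")
  if (length(k_values) > 1 && any(diff(k_values) <= 0))
    stop("k_values must be strictly increasing")
  if (n_exchanges < 1) stop("n_exchanges must be >= 1")
  stopifnot(exchange_interval > 0, timestep > 0, temperature >= 0, friction >= 0)
  structure(list(k_values = as.numeric(k_values),
                 exchange_interval = exchange_interval,
                 n_exchanges = as.integer(n_exchanges),
                 temperature = temperature, friction = friction,
                 timestep = timestep),
            class = "ladder_config")
}

#' The reference 10-rung coupling ladder
#'
#' The reference ladder for the full-size problem (14,448 restrained pairs);
#' for systems with far fewer restrained pairs rescale with
#' [scale_ladder_k()] so the total coupling energy is comparable.
#'
#' @return Numeric vector of 10 coupling constants (kcal/mol/A^2).
#' @export
default_ladder_k <- function() {
  c(0, 0.000008, 0.000014, 0.000025, 0.000043, 0.000072, 0.000119,
    0.000194, 0.000312, 0.00049)
}

#' @rdname default_ladder_k
#' @param k_values Ladder to rescale.
#' @param n_pairs Number of restrained pairs in the target system.
#' @param n_pairs_ref Pair count the ladder was designed for.
#' @export
scale_ladder_k <- function(k_values, n_pairs, n_pairs_ref = 14448) {
  k_values * n_pairs_ref / n_pairs
}

#' Replica state
#'
#' @param coords,vels `n x 3` matrices.
#' @param k Current coupling constant.
#' @param ladder_pos Current rung index (1 = unbiased).
#' @param restraint_index Current schedule row.
#' @return Object of class `replica_state`.
#' @export
replica_state <- function(coords, vels, k, ladder_pos, restraint_index = 1L) {
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (k < 0) stop("k must be nonnegative")
  structure(list(coords = as.matrix(coords), vels = as.matrix(vels),
                 k = k, ladder_pos = as.integer(ladder_pos),
                 restraint_index = as.integer(restraint_index)),
            class = "replica_state")
}

#' Metropolis exchange attempt between ladder neighbours
#'
#' Evaluates `delta = beta * [(E_c(x_i; k_j) + E_c(x_j; k_i)) -
#' (E_c(x_i; k_i) + E_c(x_j; k_j))]` where `E_c` is the coupling energy
#' (the system potentials cancel because only `k` is swapped) and accepts
#' with probability `min(1, exp(-delta))`. Uses the current R RNG stream.
#'
#' @param state_i,state_j [replica_state()]s on adjacent ladder rungs.
#' @param restraint_row Current target distances.
#' @param pairs Restrained pair matrix.
#' @param temperature K.
#' @return Logical `accepted`, with attributes `delta` and `prob`.
#' @export
attempt_exchange <- function(state_i, state_j, restraint_row, pairs,
                             temperature) {
  if (abs(state_i$ladder_pos - state_j$ladder_pos) != 1L)
    stop("exchange is only defined between adjacent ladder rungs")
  si <- coupling_energy(state_i$coords, restraint_row, pairs, 1)$energy
  sj <- coupling_energy(state_j$coords, restraint_row, pairs, 1)$energy
  beta <- 1 / (kB * temperature)
  delta <- beta * (state_j$k - state_i$k) * (si - sj)
  prob <- min(1, exp(-delta))
  accepted <- stats::runif(1) < prob
  attr(accepted, "delta") <- delta
  attr(accepted, "prob") <- prob
  accepted
}

#' Hamiltonian replica-exchange MSES run
#'
#' Replicas of the bead system are restrained toward the time-dependent
#' target distances `d_output(t)` with ladder-dependent coupling constants.
#' Dynamics windows of `exchange_interval` ps alternate with even/odd
#' neighbour exchange sweeps; on acceptance the coupling constants (ladder
#' positions) are swapped, not the coordinates. All replicas see the same
#' schedule row within a window; the row advances once per window (recycled
#' cyclically with a warning if the schedule is shorter than the run). The
#' ensemble of the `k = 0` rung is the primary, unbiased output.
#'
#' @param ff A [bead_forcefield()] (the simulated system's own potential).
#' @param schedule A [decode_to_restraints()] schedule whose `step_duration`
#'   must equal the ladder's `exchange_interval`. Pairs index beads directly.
#' @param ladder A [ladder_config()].
#' @param init_coords Starting `n x 3` coordinates (all replicas), or a list
#'   of one matrix per replica.
#' @param mass Per-bead masses (amu).
#' @param seed Master seed (controls velocities, thermostat streams and
#'   exchange decisions).
#' @return List of class `mses_run`: `$k0_frames` (`n_windows x n x 3`
#'   unbiased ensemble, one frame per window), `$exchange_log` (data frame),
#'   `$acceptance` (overall), `$acceptance_by_pair`, `$k_trace`
#'   (`n_windows x n_replicas` rung index per replica), `$final_states`,
#'   `$recycled`.
#' @export
run_mses <- function(ff, schedule, ladder, init_coords, mass = 110, seed = 1) {
  stopifnot(inherits(schedule, "restraint_schedule"),
            inherits(ladder, "ladder_config"))
  if (!isTRUE(all.equal(schedule$step_duration, ladder$exchange_interval)))
    stop("schedule step_duration must equal the ladder exchange_interval")
  n_rep <- length(ladder$k_values)
  n_win <- ladder$n_exchanges
  n_sched <- nrow(schedule$d)
  recycled <- n_sched < n_win
  if (recycled)
    warning(sprintf("schedule has %d rows < %d windows; recycling cyclically",
                    n_sched, n_win))
  pairs <- schedule$pairs; storage.mode(pairs) <- "integer"

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  if (!is.list(init_coords)) init_coords <- rep(list(as.matrix(init_coords)), n_rep)
  n <- nrow(init_coords[[1]])
  mass <- rep_len(mass, n)
  reps <- lapply(seq_len(n_rep), function(r)
    replica_state(init_coords[[r]],
                  maxwell_velocities(n, mass, ladder$temperature),
                  ladder$k_values[r], r))

  steps <- max(1L, round(ladder$exchange_interval / ladder$timestep))
  k0_frames <- array(NA_real_, c(n_win, n, 3))
  k_trace <- matrix(NA_integer_, n_win, n_rep)
  log_rows <- vector("list", n_win)
  seed_base <- as.numeric(seed) %% 2^20

  for (w in seq_len(n_win)) {
    row <- (w - 1L) %% n_sched + 1L
    target <- schedule$d[row, ]
    for (r in seq_len(n_rep)) {
      res <- run_langevin(reps[[r]]$coords, ff, steps, dt = ladder$timestep,
                          friction = ladder$friction,
                          temperature = ladder$temperature, mass = mass,
                          seed = seed_base * 1e7 + w * 100 + r,
                          vels = reps[[r]]$vels,
                          restraints = list(pairs = pairs, target = target,
                                            k = reps[[r]]$k))
      reps[[r]]$coords <- res$coords
      reps[[r]]$vels <- res$vels
      reps[[r]]$restraint_index <- row
    }
    # even/odd alternating sweep over adjacent rungs
    if (n_rep > 1) {
      first <- if (w %% 2L == 1L) 1L else 2L
      at_pos <- order(vapply(reps, function(s) s$ladder_pos, integer(1)))
      sweep_rows <- lapply(if (first <= n_rep - 1L) seq(first, n_rep - 1L, by = 2L) else integer(0), function(p) {
        i <- at_pos[p]; j <- at_pos[p + 1L]
        acc <- attempt_exchange(reps[[i]], reps[[j]], target, pairs,
                                ladder$temperature)
        if (acc) {
          ki <- reps[[i]]$k
          reps[[i]]$k <<- reps[[j]]$k; reps[[j]]$k <<- ki
          pi <- reps[[i]]$ladder_pos
          reps[[i]]$ladder_pos <<- reps[[j]]$ladder_pos
          reps[[j]]$ladder_pos <<- pi
        }
        data.frame(window = w, pair = p, delta = attr(acc, "delta"),
                   accepted = as.logical(acc))
      })
      log_rows[[w]] <- do.call(rbind, sweep_rows)
    }
    pos <- vapply(reps, function(s) s$ladder_pos, integer(1))
    k_trace[w, ] <- pos
    k0_frames[w, , ] <- reps[[which(pos == 1L)]]$coords
  }
  exchange_log <- do.call(rbind, log_rows)
  acc_by_pair <- if (!is.null(exchange_log))
    tapply(exchange_log$accepted, exchange_log$pair, mean) else numeric(0)
  structure(list(
    k0_frames = k0_frames, exchange_log = exchange_log,
    acceptance = if (!is.null(exchange_log)) mean(exchange_log$accepted) else NA_real_,
    acceptance_by_pair = acc_by_pair, k_trace = k_trace,
    final_states = reps, ladder = ladder, recycled = recycled, seed = seed),
    class = "mses_run")
}

#' @export
print.mses_run <- function(x, ...) {
  cat(sprintf("<mses_run> %d windows x %d replicas, overall acceptance %.3f\n",
              nrow(x$k_trace), ncol(x$k_trace), x$acceptance))
  invisible(x)
}

#' Original-style MSES with a driven coarse-grained copy
#'
#' A single coarse-grained (CG) copy evolves on a dual-basin potential at
#' high temperature with heavy beads (adiabatic separation) and feels no
#' counterforce from the replicas; at every window its instantaneous pair
#' distances become the restraint targets of the replica ladder. The CG
#' trajectory is therefore identical with or without the coupled replicas
#' for a given seed (one-way coupling).
#'
#' @param ff_mm System force field for the replicas.
#' @param ff_cg Dual-basin [dual_basin_forcefield()] for the CG driver.
#' @param ladder A [ladder_config()] (replica conditions).
#' @param pairs Restrained pair matrix shared by CG and the replicas.
#' @param init_mm,init_cg Starting coordinates.
#' @param cg_temperature CG temperature (K), default 1000.
#' @param cg_mass CG bead mass (amu), default 10000.
#' @param cg_friction CG collision frequency (1/ps).
#' @param mass Replica bead masses.
#' @param seed Master seed.
#' @return As [run_mses()], plus `$cg_frames` (CG coordinates per window).
#' @export
run_original_mses <- function(ff_mm, ff_cg, ladder, pairs, init_mm, init_cg,
                              cg_temperature = 1000, cg_mass = 10000,
                              cg_friction = 1, mass = 110, seed = 1) {
  stopifnot(inherits(ladder, "ladder_config"))
  n_rep <- length(ladder$k_values)
  n_win <- ladder$n_exchanges
  pairs <- rbind(pairs); storage.mode(pairs) <- "integer"

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  n_cg <- nrow(init_cg)
  cg <- list(coords = as.matrix(init_cg),
             vels = maxwell_velocities(n_cg, cg_mass, cg_temperature))
  n <- nrow(init_mm)
  mass <- rep_len(mass, n)
  reps <- lapply(seq_len(n_rep), function(r)
    replica_state(as.matrix(init_mm),
                  maxwell_velocities(n, mass, ladder$temperature),
                  ladder$k_values[r], r))

  steps <- max(1L, round(ladder$exchange_interval / ladder$timestep))
  cg_frames <- array(NA_real_, c(n_win, n_cg, 3))
  k0_frames <- array(NA_real_, c(n_win, n, 3))
  k_trace <- matrix(NA_integer_, n_win, n_rep)
  log_rows <- vector("list", n_win)
  seed_base <- as.numeric(seed) %% 2^20

  for (w in seq_len(n_win)) {
    cres <- run_langevin(cg$coords, ff_cg, steps, dt = ladder$timestep,
                         friction = cg_friction, temperature = cg_temperature,
                         mass = cg_mass, seed = seed_base * 1e7 + 5e6 + w,
                         vels = cg$vels)
    cg$coords <- cres$coords; cg$vels <- cres$vels
    cg_frames[w, , ] <- cg$coords
    target <- pair_distances(cg$coords, pairs)
    for (r in seq_len(n_rep)) {
      res <- run_langevin(reps[[r]]$coords, ff_mm, steps, dt = ladder$timestep,
                          friction = ladder$friction,
                          temperature = ladder$temperature, mass = mass,
                          seed = seed_base * 1e7 + w * 100 + r,
                          vels = reps[[r]]$vels,
                          restraints = list(pairs = pairs, target = target,
                                            k = reps[[r]]$k))
      reps[[r]]$coords <- res$coords
      reps[[r]]$vels <- res$vels
    }
    if (n_rep > 1) {
      first <- if (w %% 2L == 1L) 1L else 2L
      at_pos <- order(vapply(reps, function(s) s$ladder_pos, integer(1)))
      sweep_rows <- lapply(if (first <= n_rep - 1L) seq(first, n_rep - 1L, by = 2L) else integer(0), function(p) {
        i <- at_pos[p]; j <- at_pos[p + 1L]
        acc <- attempt_exchange(reps[[i]], reps[[j]], target, pairs,
                                ladder$temperature)
        if (acc) {
          ki <- reps[[i]]$k
          reps[[i]]$k <<- reps[[j]]$k; reps[[j]]$k <<- ki
          pi <- reps[[i]]$ladder_pos
          reps[[i]]$ladder_pos <<- reps[[j]]$ladder_pos
          reps[[j]]$ladder_pos <<- pi
        }
        data.frame(window = w, pair = p, delta = attr(acc, "delta"),
                   accepted = as.logical(acc))
      })
      log_rows[[w]] <- do.call(rbind, sweep_rows)
    }
    pos <- vapply(reps, function(s) s$ladder_pos, integer(1))
    k_trace[w, ] <- pos
    k0_frames[w, , ] <- reps[[which(pos == 1L)]]$coords
  }
  exchange_log <- do.call(rbind, log_rows)
  structure(list(
    k0_frames = k0_frames, cg_frames = cg_frames, exchange_log = exchange_log,
    acceptance = if (!is.null(exchange_log)) mean(exchange_log$accepted) else NA_real_,
    acceptance_by_pair = if (!is.null(exchange_log))
      tapply(exchange_log$accepted, exchange_log$pair, mean) else numeric(0),
    k_trace = k_trace, final_states = reps, ladder = ladder, seed = seed),
    class = "mses_run")
}

#' Count basin transitions of a trajectory between two references
#'
#' Frames are assigned to the basin of the nearer reference (C-alpha RMSD
#' after optimal superposition) with a hysteresis margin; a transition is a
#' change of assigned basin.
#'
#' @param frames `n_frames x n x 3` array.
#' @param ref_a,ref_b Reference coordinate matrices.
#' @param margin RMSD hysteresis (Angstrom): a frame switches basin only if
#'   it is nearer the other reference by more than `margin`.
#' @return Integer transition count, with attribute `states` (per-frame
#'   basin labels, `"a"`/`"b"`).
#' @export
count_transitions <- function(frames, ref_a, ref_b, margin = 1) {
  nf <- dim(frames)[1]
  s <- vapply(seq_len(nf), function(f) {
    xyz <- frames[f, , ]
    superimpose(xyz, ref_a)$rmsd - superimpose(xyz, ref_b)$rmsd
  }, numeric(1))
  states <- character(nf)
  cur <- if (s[1] <= 0) "a" else "b"
  for (f in seq_len(nf)) {
    if (s[f] < -margin) cur <- "a"
    else if (s[f] > margin) cur <- "b"
    states[f] <- cur
  }
  n_tr <- sum(states[-1] != states[-nf])
  attr(n_tr, "states") <- states
  n_tr
}
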