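harmonic_dimer <- function(k_bond = 5, r0 = 10) {
  bead_forcefield(cbind(1L, 2L), r0, k_bond, sigma = 0.1, eps = 0)
}

test_that("coupling energy and forces follow the harmonic restraint form", {
  x <- rbind(c(0, 0, 0), c(12, 0, 0))
  pairs <- cbind(1L, 2L)
  expect_equal(coupling_energy(x, 10, pairs, 0)$energy, 0)
  expect_equal(coupling_energy(x, 10, pairs, 0.5)$energy, 2)
  # forces match central differences on random configurations
  set.seed(11)
  coords <- matrix(rnorm(15, sd = 5), 5, 3)
  pr <- rbind(c(1L, 3L), c(2L, 5L), c(4L, 5L))
  target <- runif(3, 2, 8)
  ce <- coupling_energy(coords, target, pr, 0.7)
  h <- 1e-6
  for (i in 1:5) for (a in 1:3) {
    xp <- coords; xp[i, a] <- xp[i, a] + h
    xm <- coords; xm[i, a] <- xm[i, a] - h
    num <- -(coupling_energy(xp, target, pr, 0.7)$energy -
             coupling_energy(xm, target, pr, 0.7)$energy) / (2 * h)
    expect_equal(ce$forces[i, a], num, tolerance = 1e-5)
  }
  expect_error(coupling_energy(x, c(1, 2), pairs, 1), "length")
})

test_that("force-field forces match central differences, including dual basin", {
  spec <- toy_spec(n_per_domain = 6L)
  ffs <- list(single = toy_forcefield(spec, "closed"),
              dual = toy_dual_forcefield(spec))
  set.seed(12)
  x <- toy_reference(spec, 40) + matrix(rnorm(42, sd = 0.3), 14, 3)
  for (ff in ffs) {
    ef <- forcefield_energy(x, ff)
    h <- 1e-6
    for (i in c(1, 7, 14)) for (a in 1:3) {
      xp <- x; xp[i, a] <- xp[i, a] + h
      xm <- x; xm[i, a] <- xm[i, a] - h
      num <- -(forcefield_energy(xp, ff)$energy -
               forcefield_energy(xm, ff)$energy) / (2 * h)
      expect_equal(ef$forces[i, a], num, tolerance = 1e-4)
    }
  }
})

test_that("dual-basin mixing tends to the pointwise minimum as beta_mix grows", {
  spec <- toy_spec(n_per_domain = 6L)
  ffd <- toy_dual_forcefield(spec)
  ff1 <- ffd; ff1$dual <- FALSE                        # basin A network
  ff2 <- ffd; ff2$dual <- FALSE; ff2$contact_r0 <- ffd$contact_r0_b
  ffinf <- ffd; ffinf$beta_mix <- 1e6
  for (ang in c(20, 45, 80)) {
    x <- toy_reference(spec, ang)
    v1 <- forcefield_energy(x, ff1)$energy
    v2 <- forcefield_energy(x, ff2)$energy
    vmin <- forcefield_energy(x, ffinf)$energy
    expect_equal(vmin, min(v1, v2), tolerance = 1e-6)
    # finite beta lies below both basins (log-sum-exp bound)
    vmix <- forcefield_energy(x, ffd)$energy
    expect_lte(vmix, min(v1, v2) + 1e-10)
  }
})

test_that("the integrator samples the Boltzmann variance of a harmonic well", {
  ff <- bead_forcefield(matrix(integer(0), 0, 2), numeric(0), numeric(0),
                        sigma = 0.1, eps = 0, pos_k = 5, pos_ref = rbind(c(0, 0, 0)))
  res <- run_langevin(rbind(c(0, 0, 0)), ff, n_steps = 200000, dt = 0.01,
                      friction = 2, temperature = 300, mass = 100, seed = 7,
                      vels = matrix(0, 1, 3), save_every = 20)
  v_obs <- apply(res$frames[, 1, ], 2, stats::var)
  v_th <- kB * 300 / (2 * 5)
  se <- v_th * sqrt(2 / (length(res$frames[, 1, 1]) / 10))  # ~10-step correlation
  expect_true(all(abs(v_obs - v_th) < 3 * se))
})

test_that("zero friction and zero noise reduce to energy-conserving Verlet", {
  ff <- harmonic_dimer(k_bond = 10, r0 = 4)
  x0 <- rbind(c(0, 0, 0), c(4.5, 0, 0))
  e0 <- forcefield_energy(x0, ff)$energy
  r <- run_langevin(x0, ff, 2000, dt = 0.001, friction = 0, temperature = 0,
                    mass = 10, seed = 1, vels = matrix(0, 2, 3))
  ke <- 0.5 * 10 * sum(r$vels^2) / 418.4
  expect_lt(abs(forcefield_energy(r$coords, ff)$energy + ke - e0), 1e-4)
})

test_that("zero temperature with friction relaxes to the energy minimum", {
  ff <- harmonic_dimer(k_bond = 10, r0 = 4)
  r <- run_langevin(rbind(c(0, 0, 0), c(5.5, 0, 0)), ff, 20000, dt = 0.005,
                    friction = 5, temperature = 0, mass = 10, seed = 1,
                    vels = matrix(0, 2, 3))
  expect_equal(sqrt(sum((r$coords[1, ] - r$coords[2, ])^2)), 4, tolerance = 1e-4)
})

test_that("the noise stream is bitwise deterministic given its seed", {
  spec <- toy_spec(n_per_domain = 6L)
  ff <- toy_forcefield(spec, "closed")
  ref <- attr(ff, "reference")
  set.seed(9); v0 <- maxwell_velocities(nrow(ref), 110, 300)
  a <- run_langevin(ref, ff, 400, dt = 0.02, seed = 42, vels = v0)
  b <- run_langevin(ref, ff, 400, dt = 0.02, seed = 42, vels = v0)
  expect_identical(a$coords, b$coords)
  expect_identical(a$vels, b$vels)
})

test_that("exchange acceptance is Metropolis-exact on fixed states", {
  pairs <- cbind(1L, 2L)
  mk <- function(d, k, pos) replica_state(rbind(c(0, 0, 0), c(d, 0, 0)),
                                          matrix(0, 2, 3), k, pos)
  # symmetric cases always accepted
  set.seed(1)
  acc <- attempt_exchange(mk(11, 0.3, 1L), mk(11, 0.3, 2L), 12, pairs, 300)
  expect_true(as.logical(acc)); expect_equal(attr(acc, "delta"), 0)
  acc2 <- attempt_exchange(mk(11.5, 0.2, 1L), mk(11.5, 0.7, 2L), 12, pairs, 300)
  expect_true(as.logical(acc2))
  expect_error(attempt_exchange(mk(11, 0, 1L), mk(11, 0.5, 3L), 12, pairs, 300),
               "adjacent")
  # hand-computed delta: k_i = 0.4, k_j = 0, S_i = 0.25, S_j = 1
  si <- mk(11.5, 0.4, 1L); sj <- mk(13, 0, 2L)
  beta <- 1 / (kB * 300)
  delta <- beta * (0 - 0.4) * (0.25 - 1)
  p_exact <- exp(-delta)
  set.seed(123)
  n <- 20000
  hits <- vapply(seq_len(n), function(i)
    as.logical(attempt_exchange(si, sj, 12, pairs, 300)), logical(1))
  expect_equal(attr(attempt_exchange(si, sj, 12, pairs, 300), "delta"), delta)
  expect_lt(abs(mean(hits) - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / n))
})

test_that("acceptance decreases as the ladder gap grows on the harmonic toy", {
  ff <- harmonic_dimer()
  sch <- structure(list(d = matrix(12, 50, 1), pairs = cbind(1L, 2L),
                        step_duration = 4, provenance = list()),
                   class = "restraint_schedule")
  accs <- vapply(c(0.1, 0.4, 1.2), function(k1) {
    lad <- ladder_config(c(0, k1), exchange_interval = 4, n_exchanges = 50,
                         timestep = 0.01)
    run <- run_mses(ff, sch, lad, rbind(c(0, 0, 0), c(10, 0, 0)),
                    mass = 50, seed = 3)
    run$acceptance
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("a single-rung ladder reduces to plain Langevin dynamics", {
  ff <- harmonic_dimer()
  sch <- structure(list(d = matrix(12, 5, 1), pairs = cbind(1L, 2L),
                        step_duration = 4, provenance = list()),
                   class = "restraint_schedule")
  lad <- ladder_config(0, exchange_interval = 4, n_exchanges = 5,
                       timestep = 0.01)
  x0 <- rbind(c(0, 0, 0), c(10, 0, 0))
  run <- run_mses(ff, sch, lad, x0, mass = 50, seed = 21)
  # replay: same velocity draw and per-window seed derivation
  set.seed(21)
  vels <- maxwell_velocities(2, 50, 300)
  coords <- x0
  for (w in 1:5) {
    r <- run_langevin(coords, ff, 400, dt = 0.01, friction = 1,
                      temperature = 300, mass = 50,
                      seed = (21 %% 2^20) * 1e7 + w * 100 + 1, vels = vels)
    coords <- r$coords; vels <- r$vels
    expect_identical(run$k0_frames[w, , ], coords)
  }
})

test_that("ladder and schedule contracts are validated", {
  expect_error(ladder_config(c(0.1, 0.2)), "k = 0")
  expect_error(ladder_config(c(0, 0.2, 0.1)), "increasing")
  expect_error(ladder_config(0, n_exchanges = 0), "n_exchanges")
  ff <- harmonic_dimer()
  sch <- structure(list(d = matrix(12, 3, 1), pairs = cbind(1L, 2L),
                        step_duration = 10, provenance = list()),
                   class = "restraint_schedule")
  lad <- ladder_config(0, exchange_interval = 4, n_exchanges = 3, timestep = 0.01)
  expect_error(run_mses(ff, sch, lad, rbind(c(0, 0, 0), c(10, 0, 0))),
               "exchange_interval")
  sch$step_duration <- 4
  lad2 <- ladder_config(0, exchange_interval = 4, n_exchanges = 6, timestep = 0.01)
  expect_warning(run_mses(ff, sch, lad2, rbind(c(0, 0, 0), c(10, 0, 0)),
                          mass = 50, seed = 1), "recycling")
})

test_that("the driven CG copy is unaffected by the coupled replicas", {
  spec <- toy_spec(n_per_domain = 6L)
  ffd <- toy_dual_forcefield(spec)
  ref <- attr(ffd, "ref_closed")
  pairs <- select_interdomain_pairs(toy_domains(spec), 3)
  lad1 <- ladder_config(c(0, 0.01), exchange_interval = 2, n_exchanges = 8,
                        timestep = 0.01)
  lad2 <- ladder_config(c(0, 0.005, 0.01), exchange_interval = 2, n_exchanges = 8,
                        timestep = 0.01)
  r1 <- run_original_mses(ffd, ffd, lad1, pairs, ref, ref, seed = 5,
                          mass = spec$mass)
  r2 <- run_original_mses(ffd, ffd, lad2, pairs, ref, ref, seed = 5,
                          mass = spec$mass)
  expect_identical(r1$cg_frames, r2$cg_frames)
})

test_that("the hot heavy CG copy equilibrates across a two-basin 1-D landscape", {
  # dual-basin dimer: bond basins at 6 and 14 A; at 1000 K the copy must
  # populate both close to the Boltzmann ratio
  ff <- bead_forcefield(matrix(integer(0), 0, 2), numeric(0), numeric(0),
                        contacts = cbind(1L, 2L), contact_r0 = 6,
                        contact_k = 0.4, sigma = 0.1, eps = 0)
  ff$dual <- TRUE; ff$contact_r0_b <- 14; ff$beta_mix <- 2
  set.seed(31)
  x <- rbind(c(0, 0, 0), c(6, 0, 0))
  res <- run_langevin(x, ff, 400000, dt = 0.05, friction = 1,
                      temperature = 1000, mass = 1000, seed = 17,
                      vels = matrix(0, 2, 3), save_every = 40)
  d <- sqrt(rowSums((res$frames[, 1, ] - res$frames[, 2, ])^2))
  p_a <- mean(d < 10)
  # Boltzmann populations from the radial density r^2 exp(-beta V(r))
  r <- seq(2, 20, by = 0.005)
  v1 <- 0.4 * (r - 6)^2; v2 <- 0.4 * (r - 14)^2
  vmix <- -log(exp(-2 * v1) + exp(-2 * v2)) / 2
  w <- r^2 * exp(-vmix / (kB * 1000))
  p_th <- sum(w[r < 10]) / sum(w)
  n_eff <- 50    # conservative effective sample size for the slow hops
  expect_lt(abs(p_a - p_th), 3 * sqrt(p_th * (1 - p_th) / n_eff))
})
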