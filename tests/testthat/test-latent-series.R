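test_that("linear interpolation hits anchors and midpoints exactly", {
  a <- rbind(c(0, 0)); b <- rbind(c(1, 1))
  s <- interpolate_series(a, b, n_intervals = 2, n_anchors = 2, seed = 1)
  expect_equal(s$z, rbind(c(0, 0), c(0.5, 0.5), c(1, 1)))
  s1 <- interpolate_series(a, b, n_intervals = 1, n_anchors = 4, seed = 1)
  expect_equal(s1$z, rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1)))
  # series length (n_anchors - 1) * n_intervals + 1
  set.seed(2)
  pa <- matrix(rnorm(40), 20, 2); pb <- matrix(rnorm(40, 3), 20, 2)
  s2 <- interpolate_series(pa, pb, n_intervals = 25, n_anchors = 9, seed = 7)
  expect_identical(nrow(s2$z), 201L)
  expect_error(interpolate_series(pa[0, , drop = FALSE], pb, 25), "non-empty")
})

test_that("anchors alternate pools, drawn without replacement with reshuffle", {
  set.seed(3)
  pa <- cbind(1:4, 0); pb <- cbind(-(1:3), 0)
  s <- interpolate_series(pa, pb, n_intervals = 1, n_anchors = 10, seed = 9)
  odd <- s$z[seq(1, 10, 2), 1]; even <- s$z[seq(2, 10, 2), 1]
  expect_true(all(odd > 0) && all(even < 0))
  # first pass through pool a uses each point exactly once
  expect_setequal(odd[1:4], 1:4)
  expect_setequal(even[1:3], -(1:3))
  # deterministic given seed
  s2 <- interpolate_series(pa, pb, n_intervals = 1, n_anchors = 10, seed = 9)
  expect_identical(s$z, s2$z)
})

test_that("interpolated series is continuous at the anchor-gap scale", {
  set.seed(5)
  pa <- matrix(rnorm(30), 15, 2); pb <- matrix(rnorm(30, 4), 15, 2)
  n_int <- 10
  s <- interpolate_series(pa, pb, n_intervals = n_int, seed = 2)
  steps <- sqrt(rowSums(diff(s$z)^2))
  max_gap <- max(sqrt(rowSums((rbind(pa, pb)[rep(1:30, 30), ] -
                               rbind(pa, pb)[rep(1:30, each = 30), ])^2)))
  expect_lte(max(steps), max_gap / n_int)
})

test_that("extrapolation follows the mean-shift formula exactly", {
  # single-member pools: z_ext = z_close + alpha (mean_close - mean_holo)
  s <- extrapolate_series(rbind(c(1, 0)), rbind(c(0, 0)), alpha = 5,
                          n_intervals = 1, n_anchors = 2, seed = 1)
  expect_equal(s$z_ext_pool, rbind(c(6, 0)))
  # zero displacement degenerates to within-pool interpolation
  set.seed(6)
  pool <- matrix(rnorm(20), 10, 2)
  s0 <- extrapolate_series(pool, pool, alpha = 3, n_intervals = 2, seed = 4)
  expect_equal(colMeans(s0$z_ext_pool), colMeans(pool))
  expect_equal(s0$z_ext_pool, pool)
  # linearity of the mean, exact on random pools
  for (alpha in c(0.5, 2, 7)) {
    ph <- matrix(rnorm(16, 1), 8, 2)
    se <- extrapolate_series(pool, ph, alpha, n_intervals = 1, seed = 1)
    expect_equal(colMeans(se$z_ext_pool),
                 colMeans(pool) + alpha * (colMeans(pool) - colMeans(ph)))
  }
  expect_error(extrapolate_series(pool, pool, alpha = 0), "positive")
  expect_error(extrapolate_series(pool, pool, alpha = -1), "positive")
})

test_that("alpha determination finds the largest scale below the hinge cap", {
  # hand-built decoder: y = sigmoid(-0.5 z + 1), so the decoded distance of
  # every feature grows monotonically with z
  dec <- make_linear_decoder(W = cbind(-0.5, -0.5), b = c(1, 1))
  pairs <- rbind(c(1L, 10L), c(2L, 20L))
  z_close <- rbind(1); z_holo <- rbind(0)   # shift = +1 per unit alpha
  d_at <- function(a) denormalize_distances(vae_decode(dec, rbind(1 + a)))[1, 1]
  grid <- seq(0.5, 10, by = 0.5)
  d_max <- 30
  a <- determine_alpha(dec, z_close, z_holo, c(1, 10), pairs,
                       d_max = d_max, alpha_grid = grid)
  # bisection oracle for the crossing point
  lo <- 0; hi <- 20
  for (i in 1:60) { mid <- (lo + hi) / 2; if (d_at(mid) < d_max) lo <- mid else hi <- mid }
  expect_equal(as.numeric(a), max(grid[grid <= lo]))
  expect_true(d_at(a) < d_max && d_at(a + 0.5) >= d_max)
  # unconstrained cap returns the top of the grid
  expect_equal(as.numeric(determine_alpha(dec, z_close, z_holo, c(1, 10), pairs,
                                          d_max = Inf, alpha_grid = grid)), 10)
  # singleton grid, satisfied
  expect_equal(as.numeric(determine_alpha(dec, z_close, z_holo, c(1, 10), pairs,
                                          d_max = Inf, alpha_grid = 5)), 5)
  # violated even at the smallest grid value -> warning
  expect_warning(
    a_min <- determine_alpha(dec, z_close, z_holo, c(1, 10), pairs,
                             d_max = 1e-9, alpha_grid = grid), "returning")
  expect_equal(as.numeric(a_min), 0.5)
  expect_error(determine_alpha(dec, z_close, z_holo, c(3, 4), pairs,
                               d_max = 30, alpha_grid = grid), "hinge pair")
})

test_that("decoding a latent series yields an aligned restraint schedule", {
  ch <- toy_chain()
  s <- interpolate_series(ch$z_closed, ch$z_open, n_intervals = 5,
                          n_anchors = 4, seed = 3)
  sch <- decode_to_restraints(ch$model, s, ch$fs$pairs)
  expect_identical(nrow(sch$d), nrow(s$z))
  expect_identical(ncol(sch$d), ch$fs$n_pairs)
  expect_identical(sch$step_duration, s$step_duration)
  expect_true(all(sch$d > 0 & sch$d <= 10 / 0.14))
  # identical steps decode to identical restraint rows
  s2 <- s; s2$z <- rbind(s$z[1, ], s$z[1, ])
  sch2 <- decode_to_restraints(ch$model, s2, ch$fs$pairs)
  expect_identical(sch2$d[1, ], sch2$d[2, ])
  # a training frame's posterior mean decodes near that frame's distances
  f <- 25
  s3 <- s; s3$z <- ch$z[f, , drop = FALSE]
  sch3 <- decode_to_restraints(ch$model, s3, ch$fs$pairs)
  med_err <- stats::median(abs(sch3$d[1, ] - ch$fs$distances[f, ]))
  expect_lt(med_err, 1)
  expect_error(decode_to_restraints(ch$model,
                                    structure(list(z = cbind(1, 2, 3),
                                                   step_duration = 40,
                                                   provenance = list()),
                                              class = "latent_series"),
                                    ch$fs$pairs), "dimension")
})

test_that("the interpolated series covers both latent pools", {
  ch <- toy_chain()
  s <- interpolate_series(ch$z_closed, ch$z_open, n_intervals = 25, seed = 5)
  expect_gte(coverage_fraction(ch$z_closed, s$z), 0.95)
  expect_gte(coverage_fraction(ch$z_open, s$z), 0.95)
})
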