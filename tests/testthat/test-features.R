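test_that("inter-domain pair selection enumerates cross pairs with the separation rule", {
  d <- domain_definition(list(c(1, 2)), list(c(5, 6)))
  expect_equal(select_interdomain_pairs(d, 3),
               cbind(i = c(1L, 1L, 2L, 2L), j = c(5L, 6L, 5L, 6L)))
  # only candidate pair excluded by |i - j| >= 3
  d2 <- domain_definition(1, 2)
  expect_equal(nrow(select_interdomain_pairs(d2, 3)), 0L)
  # full-size domain bookkeeping vs brute-force double loop
  d3 <- domain_definition(list(c(10, 30), c(39, 102), c(234, 262)),
                          list(c(103, 233)))
  expect_length(d3$residues1, 114)
  expect_length(d3$residues2, 131)
  p <- select_interdomain_pairs(d3, 1)
  brute <- 0L
  for (i in d3$residues1) for (j in d3$residues2)
    if (abs(i - j) >= 1) brute <- brute + 1L
  expect_identical(nrow(p), brute)
  expect_identical(nrow(p), 114L * 131L)
  # lexicographic ordering
  expect_true(!is.unsorted(p[, 1]))
  expect_true(all(diff(order(p[, 1], p[, 2])) == 1))
})

test_that("pair selection size matches brute force on random small domains", {
  set.seed(7)
  for (rep in 1:10) {
    a <- sort(sample(1:40, 2)); b <- sort(sample(41:80, 2))
    sep <- sample(1:5, 1)
    d <- domain_definition(list(a), list(b))
    p <- select_interdomain_pairs(d, sep)
    brute <- sum(outer(a[1]:a[2], b[1]:b[2],
                       function(i, j) abs(i - j) >= sep))
    expect_equal(nrow(p), brute)
  }
})

test_that("invalid domain definitions are rejected", {
  expect_error(domain_definition(list(), list(c(1, 5))), "at least one")
  expect_error(domain_definition(list(c(1, 5)), list(c(3, 8))), "overlap")
  expect_error(domain_definition(list(c(1, 5)), list(c(6, 8)),
                                 removed = list(c(5, 5))), "removed")
  expect_error(select_interdomain_pairs(domain_definition(1, 5), 0),
               "min_seq_sep")
})

test_that("distances are Euclidean, symmetric in pair order and name-checked", {
  coords <- array(0, c(1, 3, 3))
  coords[1, 2, ] <- c(3, 4, 0)
  tr <- trajectory_ensemble(coords, residue_ids = c(10L, 20L, 30L))
  expect_equal(unname(compute_distances(tr, cbind(10L, 20L))[1, 1]), 5)
  expect_equal(unname(compute_distances(tr, cbind(10L, 30L))[1, 1]), 0)
  expect_equal(unname(compute_distances(tr, cbind(20L, 10L))[1, 1]), 5)
  expect_error(compute_distances(tr, cbind(10L, 99L)), "99")
})

test_that("distance matrix matches a per-frame brute-force loop", {
  set.seed(1)
  coords <- array(rnorm(10 * 6 * 3, sd = 5), c(10, 6, 3))
  tr <- trajectory_ensemble(coords)
  pairs <- cbind(c(1L, 2L, 1L), c(4L, 6L, 6L))
  d <- compute_distances(tr, pairs)
  for (f in 1:10) for (p in 1:3)
    expect_equal(unname(d[f, p]),
                 sqrt(sum((coords[f, pairs[p, 1], ] - coords[f, pairs[p, 2], ])^2)))
})

test_that("distances are invariant under rigid motion of each frame", {
  set.seed(2)
  coords <- array(rnorm(5 * 8 * 3, sd = 4), c(5, 8, 3))
  moved <- coords
  for (f in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    moved[f, , ] <- sweep(coords[f, , ] %*% t(Rz %*% Rx), 2, runif(3, -20, 20), "+")
  }
  pairs <- cbind(c(1L, 3L), c(5L, 8L))
  expect_lt(max(abs(compute_distances(trajectory_ensemble(coords), pairs) -
                    compute_distances(trajectory_ensemble(moved), pairs))),
            1e-8)
})

test_that("normalization follows the reciprocal map and clips out-of-range values", {
  expect_equal(normalize_distances(10)[1], 0.344)           # f(1 nm)
  expect_equal(normalize_distances(10 / 0.14)[1], 0, tolerance = 1e-12)
  expect_equal(suppressMessages(normalize_distances(10 / 2.64))[1], 1)
  expect_message(out <- normalize_distances(c(2, 10)), "clipped")
  expect_equal(attr(out, "n_clipped"), 1L)
  expect_equal(out[1], 1)   # 2 A maps above 1 -> clipped
  expect_error(normalize_distances(c(1, -1)), "positive")
  expect_error(normalize_distances(0), "positive")
})

test_that("denormalization inverts normalization on the invertible range", {
  expect_equal(denormalize_distances(0.344)[1], 10, tolerance = 1e-12)
  expect_equal(denormalize_distances(0)[1], 10 / 0.14, tolerance = 1e-9)
  d <- seq(3.8, 71.4, length.out = 500)
  expect_lt(max(abs(denormalize_distances(normalize_distances(d)) - d)), 1e-10)
  # strictly decreasing in d
  x <- normalize_distances(d)
  expect_true(all(diff(as.numeric(x)) < 0))
  expect_error(denormalize_distances(-0.1), "0, 1")
  expect_error(denormalize_distances(1.1), "0, 1")
})

test_that("feature_set pools frames, orders pairs and records clipping", {
  ch <- toy_chain()
  fs <- ch$fs
  expect_identical(fs$n_pairs, nrow(fs$pairs))
  expect_identical(dim(fs$distances), dim(fs$normalized))
  expect_identical(nrow(fs$distances), 800L)
  expect_true(all(fs$normalized >= 0 & fs$normalized <= 1))
  expect_true(all(fs$distances > 0))
  expect_identical(unique(fs$state), c("closed", "open"))
  expect_true(all(abs(fs$pairs[, 1] - fs$pairs[, 2]) >= 3))
})

test_that("trajectory PDB writer and reader round-trip coordinates", {
  spec <- toy_spec(n_per_domain = 6L)
  tr <- simulate_toy_state(spec, "closed", n_frames = 4, seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_beads_pdb(tr, f)
  back <- read_ca_trajectory(f, state_label = "closed")
  expect_identical(dim(back$coords), dim(tr$coords))
  expect_lt(max(abs(back$coords - tr$coords)), 1e-2)  # PDB fixed-precision
})
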