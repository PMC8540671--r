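#' Interpolated latent time series between two state pools
#'
#' Builds a discrete anchor sequence by alternately drawing latent points
#' from pool A and pool B (uniformly without replacement, reshuffling a pool
#' once exhausted), then connects consecutive anchors by linear interpolation
#' with `n_intervals` equally spaced steps. Segment endpoints equal the
#' anchors exactly, so the series has `(n_anchors - 1) * n_intervals + 1`
#' steps. One step corresponds to one replica-exchange window.
#'
#' @param z_pool_a,z_pool_b Matrices `n x L` of latent coordinates (pools
#'   from the two states).
#' @param n_intervals Interpolation steps per anchor segment (default 25,
#'   i.e. 25 x 40 ps = 1 ns per segment).
#' @param n_anchors Number of anchors; default uses every pool point once
#'   (`2 * min(nrow(a), nrow(b))`).
#' @param seed Integer seed for anchor sampling.
#' @param step_duration ps per step (the exchange window).
#' @return Object of class `latent_series`: `$z` (`steps x L`),
#'   `$step_duration`, `$provenance`.
#' @export
interpolate_series <- function(z_pool_a, z_pool_b, n_intervals = 25L,
                               n_anchors = NULL, seed = 1L,
                               step_duration = 40) {
  z_pool_a <- rbind(z_pool_a); z_pool_b <- rbind(z_pool_b)
  if (nrow(z_pool_a) == 0L || nrow(z_pool_b) == 0L)
    stop("latent pools must be non-empty")
  if (ncol(z_pool_a) != ncol(z_pool_b)) stop("pools must share latent dimension")
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L) stop("n_intervals must be >= 1")
  if (is.null(n_anchors)) n_anchors <- 2L * min(nrow(z_pool_a), nrow(z_pool_b))
  n_anchors <- as.integer(n_anchors)
  if (n_anchors < 2L) stop("need at least 2 anchors")

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  draw_order <- function(n, k) {        # k draws without replacement, reshuffle
    reps <- ceiling(k / n)
    unlist(lapply(seq_len(reps), function(i) sample.int(n)))[seq_len(k)]
  }
  n_a <- ceiling(n_anchors / 2); n_b <- floor(n_anchors / 2)
  ia <- draw_order(nrow(z_pool_a), n_a)
  ib <- draw_order(nrow(z_pool_b), n_b)
  anchors <- matrix(0, n_anchors, ncol(z_pool_a))
  anchors[seq(1, n_anchors, by = 2), ] <- z_pool_a[ia, , drop = FALSE]
  if (n_b > 0)
    anchors[seq(2, n_anchors, by = 2), ] <- z_pool_b[ib, , drop = FALSE]

  steps <- (n_anchors - 1L) * n_intervals + 1L
  z <- matrix(0, steps, ncol(anchors))
  z[1, ] <- anchors[1, ]
  w <- seq_len(n_intervals) / n_intervals
  for (k in seq_len(n_anchors - 1L)) {
    seg <- outer(1 - w, anchors[k, ]) + outer(w, anchors[k + 1L, ])
    z[(k - 1L) * n_intervals + 1L + seq_len(n_intervals), ] <- seg
  }
  structure(list(z = z, step_duration = step_duration,
                 provenance = list(kind = "interpolation",
                                   n_anchors = n_anchors,
                                   n_intervals = n_intervals, seed = seed)),
            class = "latent_series")
}

#' @export
print.latent_series <- function(x, ...) {
  cat(sprintf("<latent_series> %d steps x L=%d (%s), %g ps/step\n",
              nrow(x$z), ncol(x$z), x$provenance$kind, x$step_duration))
  invisible(x)
}

#' Extrapolated latent series beyond the closed state
#'
#' Implements the linear-response extrapolation: with componentwise pool
#' means `<z>_close` and `<z>_holo`, every closed-pool member is displaced by
#' `alpha * (<z>_close - <z>_holo)` to form the extrapolated pool
#' `z_ext = z_close + alpha (<z>_close - <z>_holo)`, which stands in for the
#' unseen open state. The closed and extrapolated pools are then interleaved
#' with [interpolate_series()].
#'
#' @param z_pool_close,z_pool_holo Latent pools (`n x L`).
#' @param alpha Positive scaling factor (the hinge-capped value can be
#'   found with [determine_alpha()]).
#' @inheritParams interpolate_series
#' @return A `latent_series`; `$provenance` records `alpha` and the pool
#'   means, and `$z_ext_pool` holds the extrapolated pool.
#' @export
extrapolate_series <- function(z_pool_close, z_pool_holo, alpha,
                               n_intervals = 25L, n_anchors = NULL, seed = 1L,
                               step_duration = 40) {
  z_pool_close <- rbind(z_pool_close); z_pool_holo <- rbind(z_pool_holo)
  if (nrow(z_pool_close) == 0L || nrow(z_pool_holo) == 0L)
    stop("latent pools must be non-empty")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("alpha must be a positive scalar")
  shift <- colMeans(z_pool_close) - colMeans(z_pool_holo)
  z_ext <- sweep(z_pool_close, 2, alpha * shift, "+")
  out <- interpolate_series(z_pool_close, z_ext, n_intervals = n_intervals,
                            n_anchors = n_anchors, seed = seed,
                            step_duration = step_duration)
  out$provenance$kind <- "extrapolation"
  out$provenance$alpha <- alpha
  out$provenance$mean_close <- colMeans(z_pool_close)
  out$provenance$mean_holo <- colMeans(z_pool_holo)
  out$z_ext_pool <- z_ext
  out
}

#' Choose the extrapolation scale from a hinge-distance cap
#'
#' Scans an increasing grid of `alpha` values and returns the largest one for
#' which the decoded extrapolated pool mean keeps the hinge residue pair
#' below `d_max` Angstrom (the point at which the inter-domain hinge would be
#' fully extended). If even the smallest grid value violates the cap it is
#' returned with a warning.
#'
#' @param model A [vae_train()] model.
#' @param z_pool_close,z_pool_holo Latent pools (`n x L`).
#' @param hinge_pair Length-2 vector of residue ids; must be one of the
#'   feature pairs.
#' @param pairs The feature pair matrix the model was trained on.
#' @param d_max Distance cap in Angstrom (default 30).
#' @param alpha_grid Increasing grid of candidate scales.
#' @return The selected `alpha` (attribute `hinge_distance` gives the decoded
#'   hinge distance at that alpha).
#' @export
determine_alpha <- function(model, z_pool_close, z_pool_holo, hinge_pair,
                            pairs, d_max = 30,
                            alpha_grid = seq(0.5, 10, by = 0.5)) {
  pairs <- rbind(pairs)
  hit <- which(pairs[, 1] == hinge_pair[1] & pairs[, 2] == hinge_pair[2] |
               pairs[, 1] == hinge_pair[2] & pairs[, 2] == hinge_pair[1])
  if (length(hit) == 0L)
    stop(sprintf("hinge pair (%d, %d) is not among the feature pairs",
                 hinge_pair[1], hinge_pair[2]))
  if (is.unsorted(alpha_grid, strictly = TRUE))
    stop("alpha_grid must be strictly increasing")
  mc <- colMeans(rbind(z_pool_close))
  mh <- colMeans(rbind(z_pool_holo))
  shift <- mc - mh
  hinge_d <- vapply(alpha_grid, function(a) {
    y <- vae_decode(model, mc + a * shift)
    denormalize_distances(y)[1, hit[1]]
  }, numeric(1))
  ok <- hinge_d < d_max
  if (!any(ok)) {
    warning(sprintf(
      "hinge distance exceeds %g A even at alpha = %g; returning it", d_max,
      alpha_grid[1]))
    alpha <- alpha_grid[1]
  } else {
    alpha <- alpha_grid[max(which(ok))]
  }
  attr(alpha, "hinge_distance") <- hinge_d[match(alpha, alpha_grid)]
  alpha
}

#' Decode a latent series into a restraint schedule
#'
#' Each latent step is decoded to normalized features and mapped back to
#' target distances (`d_output(t)` in Angstrom), one row per exchange window.
#'
#' @param model A [vae_train()] model.
#' @param series A [interpolate_series()] / [extrapolate_series()] result.
#' @param pairs Feature pair matrix (carried into the schedule).
#' @return Object of class `restraint_schedule`: `$d` (`steps x n_pairs`,
#'   Angstrom), `$pairs`, `$step_duration`, `$provenance`.
#' @export
decode_to_restraints <- function(model, series, pairs) {
  stopifnot(inherits(series, "latent_series"))
  if (ncol(series$z) != model$latent_dim)
    stop("series latent dimension does not match the model")
  pairs <- rbind(pairs)
  y <- vae_decode(model, series$z)
  if (ncol(y) != nrow(pairs))
    stop("pair list length does not match the model's feature dimension")
  d <- denormalize_distances(y)
  colnames(d) <- paste0(pairs[, 1], "-", pairs[, 2])
  structure(list(d = d, pairs = pairs,
                 step_duration = series$step_duration,
                 provenance = series$provenance),
            class = "restraint_schedule")
}

#' @export
print.restraint_schedule <- function(x, ...) {
  cat(sprintf("<restraint_schedule> %d windows x %d pairs, %g ps/window\n",
              nrow(x$d), nrow(x$pairs), x$step_duration))
  invisible(x)
}

#' Write a latent series or restraint schedule preview as TSV
#'
#' @param x A `latent_series` or `restraint_schedule`.
#' @param file Output path.
#' @param n_steps Number of leading steps to write (default all).
#' @export
write_series_tsv <- function(x, file, n_steps = Inf) {
  m <- if (inherits(x, "latent_series")) x$z else x$d
  m <- m[seq_len(min(nrow(m), n_steps)), , drop = FALSE]
  utils::write.table(m, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
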