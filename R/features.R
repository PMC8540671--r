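#' Trajectory ensemble of C-alpha coordinates
#'
#' Container for one conformational state's trajectory at C-alpha resolution.
#' Coordinates are stored as a `frames x n_residues x 3` array in Angstrom.
#'
#' @param coords Numeric array `frames x n_residues x 3` (Angstrom), or a
#'   single `n_residues x 3` matrix for a one-frame ensemble.
#' @param residue_ids Integer vector of 1-based residue labels, strictly
#'   increasing. Defaults to `1:n_residues`.
#' @param state_label One of `"closed"`, `"open"`, `"holo"`, `"other"`.
#' @param frame_interval Time between stored frames in ps.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(coords, residue_ids = NULL,
                                state_label = c("other", "closed", "open", "holo"),
                                frame_interval = 10) {
  state_label <- match.arg(state_label)
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x n_residues x 3 array")
  if (!all(is.finite(coords)))
    stop("coords must be finite")
  n_res <- dim(coords)[2]
  if (is.null(residue_ids)) residue_ids <- seq_len(n_res)
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n_res)
    stop("residue_ids length must equal the number of residues")
  if (any(diff(residue_ids) <= 0))
    stop("residue_ids must be strictly increasing")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  structure(
    list(coords = coords, residue_ids = residue_ids,
         state_label = state_label, frame_interval = frame_interval),
    class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d frames, %d residues, state '%s', dt %g ps\n",
              dim(x$coords)[1], dim(x$coords)[2], x$state_label, x$frame_interval))
  invisible(x)
}

#' @export
dim.trajectory_ensemble <- function(x) dim(x$coords)

expand_ranges <- function(ranges) {
  if (length(ranges) == 0L) return(integer(0))
  out <- unlist(lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || r[2] < r[1])
      stop("each range must be c(lo, hi) with hi >= lo")
    seq.int(r[1], r[2])
  }))
  sort(unique(out))
}

# minimal inclusive interval list covering an integer set
residues_to_ranges <- function(res) {
  res <- sort(unique(as.integer(res)))
  if (length(res) == 0L) return(list())
  brk <- c(0L, which(diff(res) > 1L), length(res))
  lapply(seq_len(length(brk) - 1L), function(k)
    c(res[brk[k] + 1L], res[brk[k + 1L]]))
}

#' Two-domain definition with removed flexible regions
#'
#' Domains are given as lists of inclusive 1-based residue intervals,
#' e.g. `list(c(10, 30), c(39, 102))`. The two domains must be disjoint and
#' removed regions may overlap neither.
#'
#' @param domain1,domain2 Lists of `c(lo, hi)` residue intervals (a bare
#'   `c(lo, hi)` or single residue id is also accepted).
#' @param removed Optional list of intervals excluded as flexible regions.
#' @return An object of class `domain_definition` with `$domain1`,
#'   `$domain2`, `$removed` (interval lists) and expanded `$residues1`,
#'   `$residues2`, `$residues_removed`.
#' @export
domain_definition <- function(domain1, domain2, removed = list()) {
  norm <- function(x) if (is.list(x)) x else list(x)
  d1 <- expand_ranges(norm(domain1))
  d2 <- expand_ranges(norm(domain2))
  rm_ <- expand_ranges(norm(removed))
  if (length(d1) == 0L || length(d2) == 0L)
    stop("both domains must contain at least one residue")
  if (length(intersect(d1, d2)) > 0L)
    stop("domain1 and domain2 overlap")
  if (length(intersect(rm_, c(d1, d2))) > 0L)
    stop("removed regions overlap a domain")
  structure(
    list(domain1 = residues_to_ranges(d1), domain2 = residues_to_ranges(d2),
         removed = residues_to_ranges(rm_),
         residues1 = d1, residues2 = d2, residues_removed = rm_),
    class = "domain_definition")
}

#' @export
print.domain_definition <- function(x, ...) {
  fmt <- function(rs) paste(vapply(rs, function(r)
    if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "-", r[2]),
    character(1)), collapse = ", ")
  cat(sprintf("<domain_definition> domain1 (%d res): %s\n", length(x$residues1), fmt(x$domain1)))
  cat(sprintf("                    domain2 (%d res): %s\n", length(x$residues2), fmt(x$domain2)))
  if (length(x$residues_removed))
    cat(sprintf("                    removed (%d res): %s\n",
                length(x$residues_removed), fmt(x$removed)))
  invisible(x)
}

#' Select inter-domain residue pairs
#'
#' All residue pairs `(i, j)` with `i` in domain 1 and `j` in domain 2 whose
#' sequence separation `|i - j|` is at least `min_seq_sep`. The default
#' `min_seq_sep = 3` excludes 1-2 (virtual bond) and 1-3 (virtual angle)
#' neighbours, counted in the original residue numbering. Pairs are returned
#' sorted lexicographically by `(i, j)` so feature indices are reproducible.
#'
#' @param domains A [domain_definition()].
#' @param min_seq_sep Minimum `|i - j|` retained (>= 1).
#' @return Integer matrix with columns `i`, `j`; zero rows if every pair is
#'   excluded by the separation rule.
#' @export
select_interdomain_pairs <- function(domains, min_seq_sep = 3L) {
  stopifnot(inherits(domains, "domain_definition"))
  min_seq_sep <- as.integer(min_seq_sep)
  if (min_seq_sep < 1L) stop("min_seq_sep must be >= 1")
  i <- rep(domains$residues1, each = length(domains$residues2))
  j <- rep(domains$residues2, times = length(domains$residues1))
  keep <- abs(i - j) >= min_seq_sep
  pairs <- cbind(i = i[keep], j = j[keep])
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  storage.mode(pairs) <- "integer"
  pairs
}

#' Per-frame Euclidean distances for a list of residue pairs
#'
#' @param traj A [trajectory_ensemble()].
#' @param pairs Integer matrix of residue-id pairs (columns `i`, `j`).
#' @return `frames x n_pairs` matrix of distances in Angstrom; columns named
#'   `"i-j"`.
#' @export
compute_distances <- function(traj, pairs) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  pairs <- rbind(pairs)
  idx_of <- match(c(pairs[, 1L], pairs[, 2L]), traj$residue_ids)
  if (anyNA(idx_of)) {
    missing <- unique(c(pairs)[is.na(idx_of)])
    stop("residue id(s) not present in trajectory: ",
         paste(missing, collapse = ", "))
  }
  np <- nrow(pairs)
  ii <- idx_of[seq_len(np)]
  jj <- idx_of[np + seq_len(np)]
  nf <- dim(traj$coords)[1]
  d <- matrix(0, nf, np)
  for (ax in 1:3) {
    delta <- traj$coords[, ii, ax, drop = FALSE] - traj$coords[, jj, ax, drop = FALSE]
    d <- d + matrix(delta, nf, np)^2
  }
  d <- sqrt(d)
  colnames(d) <- paste0(pairs[, 1L], "-", pairs[, 2L])
  d
}

#' Normalize distances to the unit interval
#'
#' Applies `x = 0.4 * (1/d - 0.14)` with `d` in nm (inputs are Angstrom and
#' converted internally), the reciprocal-distance map that weights close
#' contacts most heavily. Values falling outside `[0, 1]` are clipped and the
#' clip count is attached as attribute `n_clipped` (with a message when
#' nonzero).
#'
#' @param d Distances in Angstrom, strictly positive (vector or matrix).
#' @return Same shape as `d`, values in `[0, 1]`, attribute `n_clipped`.
#' @seealso [denormalize_distances()]
#' @export
normalize_distances <- function(d) {
  if (any(!is.finite(d)) || any(d <= 0))
    stop("distances must be finite and strictly positive")
  x <- 0.4 * (1 / (d / 10) - 0.14)
  n_clip <- sum(x < 0 | x > 1)
  if (n_clip > 0) {
    message(sprintf("normalize_distances: clipped %d value(s) to [0, 1]", n_clip))
    x[x < 0] <- 0
    x[x > 1] <- 1
  }
  if (is.matrix(d)) dimnames(x) <- dimnames(d)
  attr(x, "n_clipped") <- n_clip
  x
}

#' Invert the distance normalization
#'
#' Exact inverse of [normalize_distances()] on `(0, 1]`; `x = 0` maps to the
#' root of the map, `1/0.14` nm (71.43 Angstrom).
#'
#' @param x Normalized values in `[0, 1]`.
#' @return Distances in Angstrom, same shape as `x`.
#' @export
denormalize_distances <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("normalized values must lie in [0, 1]")
  d <- 10 / (x / 0.4 + 0.14)
  attr(d, "n_clipped") <- NULL
  d
}

#' Build the feature set of normalized inter-domain distances
#'
#' Convenience wrapper: select pairs, compute per-frame distances and
#' normalize them, returning the `feature_set` consumed by [vae_train()].
#'
#' @param traj A [trajectory_ensemble()] or list of them (frames pooled, in
#'   the order given).
#' @param domains A [domain_definition()].
#' @param min_seq_sep Passed to [select_interdomain_pairs()].
#' @return Object of class `feature_set`: `$pairs`, `$distances` (Angstrom),
#'   `$normalized` (the VAE input `x`), `$n_pairs`, `$state` (per-frame state
#'   label), `$n_clipped`.
#' @export
feature_set <- function(traj, domains, min_seq_sep = 3L) {
  if (inherits(traj, "trajectory_ensemble")) traj <- list(traj)
  pairs <- select_interdomain_pairs(domains, min_seq_sep)
  if (nrow(pairs) == 0L) stop("no inter-domain pairs survive the separation rule")
  d <- do.call(rbind, lapply(traj, compute_distances, pairs = pairs))
  state <- unlist(lapply(traj, function(t) rep(t$state_label, dim(t$coords)[1])))
  x <- normalize_distances(d)
  structure(
    list(pairs = pairs, distances = d, normalized = x,
         n_pairs = nrow(pairs), state = state,
         n_clipped = attr(x, "n_clipped")),
    class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d frames x %d pairs (%d clipped)\n",
              nrow(x$distances), x$n_pairs, x$n_clipped))
  invisible(x)
}

#' Write a feature matrix as delimited text
#'
#' Header row names the pairs `"i-j"`.
#'
#' @param features A `feature_set`.
#' @param file Output path (TSV).
#' @param what `"normalized"` (default) or `"distances"`.
#' @export
write_features_tsv <- function(features, file, what = c("normalized", "distances")) {
  what <- match.arg(what)
  m <- features[[what]]
  utils::write.table(m, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read C-alpha trajectory from PDB (and optionally DCD)
#'
#' Reads a single- or multi-model PDB (topology) and, if given, a DCD
#' trajectory using that topology; only C-alpha atoms are retained.
#'
#' @param pdb Path to a PDB file.
#' @param dcd Optional path to a DCD trajectory.
#' @param state_label Passed to [trajectory_ensemble()].
#' @param frame_interval ps between frames.
#' @return A [trajectory_ensemble()].
#' @export
read_ca_trajectory <- function(pdb, dcd = NULL,
                               state_label = "other", frame_interval = 10) {
  p <- bio3d::read.pdb(pdb, multi = TRUE)
  sel <- bio3d::atom.select(p, elety = "CA", verbose = FALSE)
  resid <- p$atom$resno[sel$atom]
  if (!is.null(dcd)) {
    xyz <- bio3d::read.dcd(dcd, verbose = FALSE)
    xyz <- xyz[, sel$xyz, drop = FALSE]
  } else {
    xyz <- p$xyz[, sel$xyz, drop = FALSE]
  }
  nf <- nrow(xyz)
  n <- length(resid)
  coords <- aperm(array(t(xyz), dim = c(3, n, nf)), c(3, 2, 1))
  trajectory_ensemble(coords, residue_ids = resid,
                      state_label = state_label, frame_interval = frame_interval)
}
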