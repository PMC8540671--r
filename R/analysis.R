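#' Least-squares superposition (Kabsch)
#'
#' Optimal proper rotation + translation of `mobile` onto `reference`,
#' fitted over `fit_sel` (all points by default) and applied to all points.
#'
#' @param mobile,reference `n x 3` coordinate matrices.
#' @param fit_sel Indices of the points used for the fit (>= 3).
#' @return List: `$coords` (transformed mobile), `$rmsd` (over `fit_sel`,
#'   Angstrom), `$rotation` (3 x 3), `$translation`.
#' @export
superimpose <- function(mobile, reference, fit_sel = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(mobile))
  if (length(fit_sel) < 3) stop("need at least 3 fit points")
  A <- mobile[fit_sel, , drop = FALSE]
  B <- reference[fit_sel, , drop = FALSE]
  if (nrow(A) != nrow(B)) stop("fit selections must be matched")
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  out <- sweep(mobile, 2, ca) %*% t(R)
  out <- sweep(out, 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((out[fit_sel, , drop = FALSE] - B)^2)))
  list(coords = out, rmsd = rmsd, rotation = R,
       translation = cb - as.vector(R %*% ca))
}

#' Principal component analysis of inter-domain motion
#'
#' Every frame is superimposed on the large domain (domain 2) of a common
#' reference (the ensemble mean after one alignment pass), then the
#' variance-covariance matrix of the small-domain (domain 1) bead
#' coordinates is diagonalized. Contributions are eigenvalue fractions of
#' the trace.
#'
#' @param ensembles A [trajectory_ensemble()] or list of them (pooled).
#' @param domains A [domain_definition()]; domain 2 is the fit selection,
#'   domain 1 carries the analyzed fluctuations.
#' @return Object of class `pca_result`: `$eigenvectors` (columns, over
#'   domain-1 xyz), `$eigenvalues`, `$contributions`, `$projections`
#'   (`frames x n_modes`), `$mean_structure`, `$degenerate`.
#' @export
domain_pca <- function(ensembles, domains) {
  if (inherits(ensembles, "trajectory_ensemble")) ensembles <- list(ensembles)
  ids <- ensembles[[1]]$residue_ids
  coords <- do.call(abind_frames, lapply(ensembles, function(e) e$coords))
  nf <- dim(coords)[1]
  if (nf < 2) stop("need at least 2 frames")
  i1 <- match(domains$residues1, ids)
  i2 <- match(domains$residues2, ids)
  if (anyNA(c(i1, i2))) stop("domain residues missing from the ensemble")

  align_all <- function(ref) {
    out <- coords
    for (f in seq_len(nf))
      out[f, , ] <- superimpose(coords[f, , ], ref, fit_sel = i2)$coords
    out
  }
  # two-pass Procrustes: align to the first frame, then to the mean
  pass1 <- align_all(coords[1, , ])
  ref <- apply(pass1, c(2, 3), mean)
  aligned <- align_all(ref)
  mean_struct <- apply(aligned, c(2, 3), mean)

  X <- matrix(aligned[, i1, ], nf, length(i1) * 3)
  Xc <- sweep(X, 2, colMeans(X))
  covm <- crossprod(Xc) / nf
  eg <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tr <- sum(ev)
  degenerate <- tr <= 1e-12
  contrib <- if (degenerate) rep(0, length(ev)) else ev / tr
  proj <- Xc %*% eg$vectors
  structure(list(eigenvectors = eg$vectors, eigenvalues = ev,
                 contributions = contrib, projections = proj,
                 mean_structure = mean_struct, fit_indices = i2,
                 mobile_indices = i1, degenerate = degenerate),
            class = "pca_result")
}

abind_frames <- function(...) {
  parts <- list(...)
  n <- dim(parts[[1]])[2]
  nf <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(NA_real_, c(nf, n, 3))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

#' Project frames onto existing principal components
#'
#' @param pca A [domain_pca()] result.
#' @param frames `n_frames x n x 3` array (full residue set, same ordering
#'   used to build the PCA).
#' @return `n_frames x n_modes` projection matrix.
#' @export
pca_project <- function(pca, frames) {
  if (length(dim(frames)) == 2L) frames <- array(frames, c(1, dim(frames)))
  nf <- dim(frames)[1]
  X <- matrix(NA_real_, nf, length(pca$mobile_indices) * 3)
  for (f in seq_len(nf)) {
    al <- superimpose(frames[f, , ], pca$mean_structure,
                      fit_sel = pca$fit_indices)$coords
    X[f, ] <- as.vector(al[pca$mobile_indices, ])
  }
  mu <- as.vector(pca$mean_structure[pca$mobile_indices, ])
  sweep(X, 2, mu) %*% pca$eigenvectors
}

#' Two-dimensional free-energy surface from samples
#'
#' Histogram-based estimate `F = -ln(count / max_count)` in units of kB*T,
#' so the global minimum over occupied bins is exactly 0 and empty bins are
#' `NA`.
#'
#' @param samples `n x 2` matrix of coordinates (e.g. PC1/PC2 or z0/z1).
#' @param bins Number of bins per axis (default 50) or a list of two break
#'   vectors.
#' @param pad Fractional padding of the data range when computing breaks.
#' @return Object of class `fes_2d`: `$F` (bins x bins, kB*T), `$counts`,
#'   `$xbreaks`, `$ybreaks`.
#' @export
fes_2d <- function(samples, bins = 50L, pad = 0.05) {
  samples <- rbind(samples)
  if (nrow(samples) < 1) stop("need at least one sample")
  if (ncol(samples) != 2) stop("samples must be n x 2")
  if (is.list(bins)) {
    xb <- bins[[1]]; yb <- bins[[2]]
  } else {
    padded <- function(v) {
      r <- range(v); w <- diff(r)
      if (w == 0) w <- max(abs(r[1]), 1)   # degenerate single-point cloud
      seq(r[1] - pad * w, r[2] + pad * w, length.out = bins + 1L)
    }
    xb <- padded(samples[, 1]); yb <- padded(samples[, 2])
  }
  ix <- findInterval(samples[, 1], xb, rightmost.closed = TRUE)
  iy <- findInterval(samples[, 2], yb, rightmost.closed = TRUE)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  counts <- matrix(0L, nx, ny)
  tab <- table(factor(ix[ok], levels = seq_len(nx)),
               factor(iy[ok], levels = seq_len(ny)))
  counts[] <- as.integer(tab)
  F <- -log(counts / max(counts))
  F[counts == 0L] <- NA_real_
  structure(list(F = F, counts = counts, xbreaks = xb, ybreaks = yb),
            class = "fes_2d")
}

#' @export
print.fes_2d <- function(x, ...) {
  cat(sprintf("<fes_2d> %d x %d bins, %d occupied, max F %.2f kBT\n",
              nrow(x$F), ncol(x$F), sum(!is.na(x$F)), max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Write a free-energy surface as a delimited text grid
#'
#' @param fes A [fes_2d()] result.
#' @param file Output path (TSV; empty bins written as NA).
#' @export
write_fes_tsv <- function(fes, file) {
  utils::write.table(fes$F, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Fraction of reference samples covered by a series' occupancy
#'
#' Shared 2-D bins are computed from both sample sets; the returned value is
#' the fraction of `reference` samples that land in bins occupied by at
#' least one `series` sample — the operational form of "the series' surface
#' covers the reference's".
#'
#' @param reference,series `n x 2` sample matrices.
#' @param bins Bins per axis, or a list of two shared break vectors.
#' @return Fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(reference, series, bins = 50L) {
  reference <- rbind(reference); series <- rbind(series)
  if (is.list(bins)) {
    xb <- bins[[1]]; yb <- bins[[2]]
  } else {
    both <- rbind(reference, series)
    padded <- function(v) {
      r <- range(v); w <- diff(r); if (w == 0) w <- max(abs(r[1]), 1)
      seq(r[1] - 0.05 * w, r[2] + 0.05 * w, length.out = bins + 1L)
    }
    xb <- padded(both[, 1]); yb <- padded(both[, 2])
  }
  bin_id <- function(s) {
    ix <- findInterval(s[, 1], xb, rightmost.closed = TRUE)
    iy <- findInterval(s[, 2], yb, rightmost.closed = TRUE)
    ix + (length(xb)) * iy
  }
  mean(bin_id(reference) %in% unique(bin_id(series)))
}
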