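#' Specification of the two-domain bead protein
#'
#' A surrogate two-domain binding protein: two helical arms of
#' `n_per_domain` beads joined by `n_hinge` linker beads, with the first arm
#' rigidly rotated about the hinge to set the opening angle. The closed and
#' open angles are chosen so the inter-domain distances span the invertible
#' range of the distance normalization; the holo state is slightly more
#' closed and stiffer than apo-closed (ligand clamping/rigidification
#' proxy), so the closed-minus-holo ensemble shift points along the opening
#' direction.
#'
#' @param n_per_domain Beads per arm (default 24).
#' @param n_hinge Linker beads (default 2).
#' @param angle_closed,angle_open Opening angles in degrees (must differ).
#' @param angle_holo Opening angle of the ligand-bound state: slightly more
#'   closed than apo-closed (the ligand clamps the domains), so the
#'   closed-minus-holo response points toward opening.
#' @param bond_length Virtual bond length, Angstrom.
#' @param cutoff Elastic-network contact cutoff, Angstrom.
#' @param k_bond,k_en Bond / intra-network spring constants (kcal/mol/A^2).
#' @param k_inter Spring constant of the sparse inter-domain lattice that
#'   pins the opening angle within one basin (the soft mode).
#' @param beta_mix Dual-basin mixing parameter, 1/(kcal/mol).
#' @param holo_stiffness Stiffness multiplier of the holo state.
#' @param mass Bead mass, amu.
#' @param dt Integrator timestep, ps.
#' @param temperature Sampling temperature, K.
#' @param seed Default seed for trajectory generation.
#' @return Object of class `toy_spec`.
#' @export
toy_spec <- function(n_per_domain = 24L, n_hinge = 2L,
                     angle_closed = 25, angle_open = 70, angle_holo = 10,
                     bond_length = 3.8, cutoff = 10,
                     k_bond = 50, k_en = 2, k_inter = 0.02,
                     beta_mix = 0.2, holo_stiffness = 2,
                     mass = 110, dt = 0.02, temperature = 300, seed = 1L) {
  if (angle_closed == angle_open) stop("state opening angles must differ")
  stopifnot(n_per_domain >= 4, n_hinge >= 1, bond_length > 0,
            k_bond > 0, k_en > 0, k_inter > 0, holo_stiffness > 0)
  structure(as.list(environment()), class = "toy_spec")
}

# helix along +x with its first bead exactly at `start`: consecutive-bead
# distance ~ bond_length for the default rise/radius/turn
# (1.5 A, 2.3 A, 100 deg per bead)
helix_arm <- function(n, start, scale = 1) {
  rise <- 1.5 * scale; radius <- 2.3 * scale; turn <- 100 * pi / 180
  i <- seq_len(n) - 1
  raw <- cbind(rise * i, radius * cos(turn * i), radius * sin(turn * i))
  sweep(raw, 2, raw[1, ] - start, "-")
}

rot_z <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' Toy reference structure at a given opening angle
#'
#' Arm 2 (domain 2) lies along +x from the origin; hinge beads step along +y;
#' arm 1 (domain 1) is the canonical parallel arm rotated rigidly about a
#' pivot just above the first hinge bead by the opening angle (degrees,
#' about z).
#'
#' @param spec A [toy_spec()].
#' @param angle Opening angle in degrees.
#' @return `n x 3` coordinate matrix; bead order is arm-1 outer end to
#'   root (1..n_per_domain), hinge, arm-2 root to outer end.
#' @export
toy_reference <- function(spec, angle) {
  np <- spec$n_per_domain; nh <- spec$n_hinge; b <- spec$bond_length
  sc <- b / 3.8
  arm2 <- helix_arm(np, c(0, 0, 0), sc)
  hinge <- cbind(0, b * seq_len(nh), 0)[rev(seq_len(nh)), , drop = FALSE]
  root1 <- c(0, b * (nh + 1), 0)
  arm1 <- helix_arm(np, root1, sc)[rev(seq_len(np)), , drop = FALSE]
  # rotation centre between the arm-1 root and the first hinge bead: no bead
  # sits exactly at the pivot, so every bead's distance fluctuations identify
  # its rigid body unambiguously
  pivot <- (hinge[1, ] + root1) / 2
  R <- rot_z(angle * pi / 180)
  arm1 <- sweep(sweep(arm1, 2, pivot) %*% t(R), 2, pivot, "+")
  coords <- rbind(arm1, hinge, arm2)
  dm <- stats::dist(coords)
  if (min(dm) < 1)
    stop(sprintf("beads too close (min distance %.2f A) at angle %g", min(dm), angle))
  coords
}

#' Closed and open reference structures
#'
#' The two conformers are identical within each domain (the open form is the
#' closed form with domain 1 rigidly rotated about the hinge by the angle
#' difference).
#'
#' @param spec A [toy_spec()].
#' @return List with `$closed`, `$open` coordinate matrices and `$spec`.
#' @export
make_references <- function(spec) {
  list(closed = toy_reference(spec, spec$angle_closed),
       open = toy_reference(spec, spec$angle_open),
       spec = spec)
}

#' Ground-truth domain definition of the toy system
#'
#' Domain 1 is the rotated arm; the hinge beads move with the static body
#' and belong to domain 2.
#'
#' @param spec A [toy_spec()].
#' @return A [domain_definition()].
#' @export
toy_domains <- function(spec) {
  np <- spec$n_per_domain; nh <- spec$n_hinge
  domain_definition(list(c(1, np)), list(c(np + 1, 2 * np + nh)))
}

# sparse inter-domain lattice pinning the opening angle (the slow mode)
toy_lattice_pairs <- function(spec) {
  np <- spec$n_per_domain; nh <- spec$n_hinge
  i1 <- seq(2L, np - 2L, by = 4L)
  i2 <- seq(np + nh + 2L, 2L * np + nh - 2L, by = 4L)
  as.matrix(expand.grid(i = i1, j = i2))
}

#' Single-basin toy force field
#'
#' Elastic network of the given state's reference plus the inter-domain
#' lattice; the holo state uses the slightly tighter holo geometry with
#' every spring stiffened by `holo_stiffness` (ligand rigidification).
#'
#' @param spec A [toy_spec()].
#' @param state `"closed"`, `"open"` or `"holo"`.
#' @return A [bead_forcefield()] with attribute `reference`.
#' @export
toy_forcefield <- function(spec, state = c("closed", "open", "holo")) {
  state <- match.arg(state)
  ang <- switch(state, open = spec$angle_open, holo = spec$angle_holo,
                spec$angle_closed)
  ref <- toy_reference(spec, ang)
  scale <- if (state == "holo") spec$holo_stiffness else 1
  ff <- elastic_network(ref, cutoff = spec$cutoff, k_bond = spec$k_bond,
                        k_en = spec$k_en,
                        extra_pairs = toy_lattice_pairs(spec),
                        k_extra = spec$k_inter,
                        stiffness_scale = scale,
                        sigma = spec$bond_length, eps = 0.3)
  attr(ff, "reference") <- ref
  ff
}

#' Dual-basin toy force field
#'
#' Contact topology is the union of the closed and open elastic networks
#' (plus the inter-domain lattice); basin A equilibrium lengths come from
#' the closed reference, basin B from the open, mixed with
#' [dual_basin_forcefield()].
#'
#' @param spec A [toy_spec()].
#' @return A dual-basin `bead_forcefield` with attributes `ref_closed`,
#'   `ref_open`.
#' @export
toy_dual_forcefield <- function(spec) {
  refc <- toy_reference(spec, spec$angle_closed)
  refo <- toy_reference(spec, spec$angle_open)
  dmc <- as.matrix(stats::dist(refc))
  dmo <- as.matrix(stats::dist(refo))
  n <- nrow(refc)
  near <- (dmc < spec$cutoff | dmo < spec$cutoff) & upper.tri(dmc)
  idx <- which(near, arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] > 1L, , drop = FALSE]
  k_con <- rep(spec$k_en, nrow(idx))
  lat <- toy_lattice_pairs(spec)
  dup <- paste(lat[, 1], lat[, 2]) %in% paste(idx[, 1], idx[, 2])
  idx <- rbind(as.matrix(idx), as.matrix(lat[!dup, , drop = FALSE]))
  k_con <- c(k_con, rep(spec$k_inter, sum(!dup)))
  bonds <- cbind(seq_len(n - 1L), 2:n)
  # bonds whose length differs between the states (the cross-hinge bond)
  # join the state-mixed contact set so neither basin is strained
  moved <- abs(dmc[bonds] - dmo[bonds]) > 0.01
  if (any(moved)) {
    idx <- rbind(idx, bonds[moved, , drop = FALSE])
    k_con <- c(k_con, rep(spec$k_bond, sum(moved)))
    bonds <- bonds[!moved, , drop = FALSE]
  }
  ff <- bead_forcefield(bonds, dmc[bonds], spec$k_bond,
                        idx, dmc[idx], k_con,
                        sigma = spec$bond_length, eps = 0.3)
  ff$dual <- TRUE
  ff$contact_r0_b <- dmo[idx]
  ff$beta_mix <- spec$beta_mix
  attr(ff, "ref_closed") <- refc
  attr(ff, "ref_open") <- refo
  ff
}

#' Sample a single-basin surrogate trajectory
#'
#' Langevin dynamics around one reference under its single-basin network,
#' after a short equilibration. Warns if the ensemble drifts from the basin.
#'
#' @param reference `n x 3` starting/reference coordinates.
#' @param ff A single-basin [bead_forcefield()].
#' @param n_frames Frames to keep (>= 2).
#' @param temperature K.
#' @param seed Integer seed.
#' @param frame_interval ps between saved frames.
#' @param equil Equilibration time, ps.
#' @param dt Timestep, ps.
#' @param mass Bead mass, amu.
#' @param friction 1/ps.
#' @param state_label Stored on the returned ensemble.
#' @param escape_rmsd Warn if any frame's RMSD from the reference exceeds
#'   this (Angstrom).
#' @return A [trajectory_ensemble()].
#' @export
simulate_basin <- function(reference, ff, n_frames = 1000L, temperature = 300,
                           seed = 1L, frame_interval = 1, equil = 20,
                           dt = 0.02, mass = 110, friction = 1,
                           state_label = "other", escape_rmsd = 8) {
  if (n_frames < 2) stop("need at least 2 frames")
  reference <- as.matrix(reference)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  n <- nrow(reference)
  vels <- maxwell_velocities(n, mass, temperature)
  eq <- run_langevin(reference, ff, n_steps = max(1L, round(equil / dt)),
                     dt = dt, friction = friction, temperature = temperature,
                     mass = mass, seed = as.numeric(seed) %% 2^20 * 1e7 + 1,
                     vels = vels)
  save_every <- max(1L, round(frame_interval / dt))
  res <- run_langevin(eq$coords, ff, n_steps = n_frames * save_every,
                      dt = dt, friction = friction, temperature = temperature,
                      mass = mass, seed = as.numeric(seed) %% 2^20 * 1e7 + 2,
                      vels = eq$vels, save_every = save_every)
  frames <- res$frames
  if (temperature > 0) {
    worst <- max(vapply(seq_len(dim(frames)[1]), function(f)
      superimpose(frames[f, , ], reference)$rmsd, numeric(1)))
    if (worst > escape_rmsd)
      warning(sprintf("trajectory strayed %.1f A RMSD from the reference", worst))
  }
  trajectory_ensemble(frames, state_label = state_label,
                      frame_interval = frame_interval)
}

#' Sample one toy state end-to-end
#'
#' Builds the state's single-basin force field and simulates around its
#' reference; for `"holo"` the closed geometry with a stiffer network.
#'
#' @param spec A [toy_spec()].
#' @param state `"closed"`, `"open"` or `"holo"`.
#' @param n_frames,seed Passed to [simulate_basin()].
#' @param ... Further arguments to [simulate_basin()].
#' @return A [trajectory_ensemble()] labeled with the state.
#' @export
simulate_toy_state <- function(spec, state = c("closed", "open", "holo"),
                               n_frames = 1000L, seed = spec$seed, ...) {
  state <- match.arg(state)
  ff <- toy_forcefield(spec, state)
  simulate_basin(attr(ff, "reference"), ff, n_frames = n_frames,
                 temperature = spec$temperature, seed = seed,
                 dt = spec$dt, mass = spec$mass,
                 state_label = if (state == "holo") "holo" else state, ...)
}

#' Write bead coordinates or a trajectory as (multi-model) PDB
#'
#' Beads are written as C-alpha atoms of sequential glycine residues so any
#' standard trajectory reader can consume the file.
#'
#' @param x `n x 3` matrix or a [trajectory_ensemble()].
#' @param file Output path.
#' @export
write_beads_pdb <- function(x, file) {
  frames <- if (inherits(x, "trajectory_ensemble")) {
    nf <- dim(x$coords)[1]
    lapply(seq_len(nf), function(f) as.vector(t(x$coords[f, , ])))
  } else list(as.vector(t(as.matrix(x))))
  n <- length(frames[[1]]) / 3
  ids <- if (inherits(x, "trajectory_ensemble")) x$residue_ids else seq_len(n)
  write_one <- function(xyz) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    bio3d::write.pdb(file = tmp, xyz = xyz, resno = ids,
                     resid = rep("GLY", n), elety = rep("CA", n),
                     chain = rep("A", n))
    grep("^(ATOM|TER)", readLines(tmp), value = TRUE)
  }
  if (length(frames) == 1L) {
    writeLines(c(write_one(frames[[1]]), "END"), file)
  } else {
    blocks <- unlist(lapply(seq_along(frames), function(f)
      c(sprintf("MODEL     %4d", f), write_one(frames[[f]]), "ENDMDL")))
    writeLines(c(blocks, "END"), file)
  }
  invisible(file)
}
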