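#' Pipeline run configuration
#'
#' Collects every stage parameter with reproducible seeds. Unknown keys are
#' rejected. The configuration is echoed (as YAML) into every output
#' directory.
#'
#' @param ... Overrides of the defaults listed below.
#' @return Object of class `run_config`.
#' @details Keys: `toy` (toy_spec arguments, list), `n_frames` per state,
#'   `min_seq_sep`, `min_domain_size`, `latent_dim`, `epochs`,
#'   `hidden_dims`, `batch_size`, `learning_rate`, `n_intervals`,
#'   `n_anchors`, `alpha`, `alpha_grid`, `d_max`, `hinge_pair`,
#'   `ladder_k` (`NULL` = rescaled reference ladder), `n_exchanges`,
#'   `exchange_interval`, `temperature`, `friction`, `timestep`,
#'   `fes_bins`, `seed`.
#' @export
run_config <- function(...) {
  cfg <- list(
    toy = list(), n_frames = 400L, min_seq_sep = 3L, min_domain_size = 5L,
    latent_dim = 2L, epochs = 300L, hidden_dims = c(256L, 256L),
    batch_size = 256L, learning_rate = 1e-3,
    n_intervals = 25L, n_anchors = 9L,
    alpha = NULL, alpha_grid = seq(0.5, 10, by = 0.5), d_max = 30,
    hinge_pair = NULL,
    ladder_k = NULL, n_exchanges = 125L, exchange_interval = 40,
    temperature = 300, friction = 1, timestep = 0.02,
    fes_bins = 50L, seed = 1L)
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots)))
    dots <- dots[[1]]
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param file YAML path.
#' @export
read_run_config <- function(file) run_config(yaml::read_yaml(file))

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s | %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full enhanced-sampling pipeline on the toy system
#'
#' Executes: toy trajectory generation, Motion Tree domain decomposition,
#' feature extraction, VAE training, latent series generation
#' (interpolation between closed and open, or extrapolation from closed +
#' holo with the open state withheld), decoding to a restraint schedule,
#' the replica-exchange MSES run on the dual-basin system, and free-energy
#' analysis. Artifacts and a JSON manifest are written under `out_dir`.
#'
#' @param config A [run_config()].
#' @param mode `"interpolate"`, `"extrapolate"` or `"original-cg"`.
#' @param out_dir Output directory (created; must not exist or be empty).
#' @return Invisibly, a list with the in-memory results (`$domains`,
#'   `$model`, `$series`, `$schedule`, `$mses`, `$fes`, `$manifest_path`).
#' @export
run_pipeline <- function(config = run_config(),
                         mode = c("interpolate", "extrapolate", "original-cg"),
                         out_dir = tempfile("vaemses_run_")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  artifacts <- character(0)
  keep <- function(path) { artifacts <<- c(artifacts, path); path }

  spec <- do.call(toy_spec, config$toy)
  refs <- make_references(spec)

  log_stage("toy", sprintf("simulating basins (%d frames each)", config$n_frames))
  traj_closed <- simulate_toy_state(spec, "closed", config$n_frames,
                                    seed = config$seed + 11)
  second_state <- if (mode == "extrapolate") "holo" else "open"
  traj_second <- simulate_toy_state(spec, second_state, config$n_frames,
                                    seed = config$seed + 12)

  log_stage("motion_tree", "building fluctuation matrix and tree")
  fl <- fluctuation_matrix(list(traj_closed, traj_second))
  tree <- build_motion_tree(fl)
  domains <- extract_domains(tree, min_domain_size = config$min_domain_size)
  keep(write_motion_tree_newick(tree, file.path(out_dir, "motion_tree.nwk")))
  keep(write_domains_tsv(domains, file.path(out_dir, "domains.tsv")))

  log_stage("features", "computing inter-domain distances")
  fs <- feature_set(list(traj_closed, traj_second), domains, config$min_seq_sep)
  keep(write_features_tsv(fs, file.path(out_dir, "features.tsv")))

  log_stage("vae", sprintf("training (L = %d, %d epochs)", config$latent_dim,
                           config$epochs))
  model <- vae_train(fs$normalized, config$latent_dim, epochs = config$epochs,
                     seed = config$seed,
                     config = vae_config(hidden_dims = config$hidden_dims,
                                         learning_rate = config$learning_rate,
                                         batch_size = config$batch_size))
  keep(save_latent_model(model, file.path(out_dir, "vae_model.rds")))
  z <- vae_encode(model, fs$normalized)
  pool_closed <- z[fs$state == "closed", , drop = FALSE]
  pool_second <- z[fs$state == second_state, , drop = FALSE]

  log_stage("latent_series", mode)
  if (mode == "extrapolate") {
    alpha <- config$alpha
    if (is.null(alpha)) {
      hinge <- config$hinge_pair
      if (is.null(hinge))
        hinge <- c(spec$n_per_domain - 2L,
                   spec$n_per_domain + spec$n_hinge + 3L)
      alpha <- determine_alpha(model, pool_closed, pool_second, hinge,
                               fs$pairs, d_max = config$d_max,
                               alpha_grid = config$alpha_grid)
    }
    series <- extrapolate_series(pool_closed, pool_second, alpha,
                                 n_intervals = config$n_intervals,
                                 n_anchors = config$n_anchors,
                                 seed = config$seed,
                                 step_duration = config$exchange_interval)
  } else {
    alpha <- NA_real_
    series <- interpolate_series(pool_closed, pool_second,
                                 n_intervals = config$n_intervals,
                                 n_anchors = config$n_anchors,
                                 seed = config$seed,
                                 step_duration = config$exchange_interval)
  }
  schedule <- decode_to_restraints(model, series, fs$pairs)
  keep(write_series_tsv(series, file.path(out_dir, "latent_series.tsv")))

  log_stage("mses", sprintf("replica exchange, %d windows", config$n_exchanges))
  ladder_k <- config$ladder_k
  if (is.null(ladder_k))
    ladder_k <- scale_ladder_k(default_ladder_k(), nrow(fs$pairs))
  ladder <- ladder_config(ladder_k, exchange_interval = config$exchange_interval,
                          n_exchanges = config$n_exchanges,
                          temperature = config$temperature,
                          friction = config$friction,
                          timestep = config$timestep)
  ff_dual <- toy_dual_forcefield(spec)
  if (mode == "original-cg") {
    mses <- run_original_mses(ff_dual, ff_dual, ladder, fs$pairs,
                              refs$closed, refs$closed,
                              mass = spec$mass, seed = config$seed + 31)
  } else {
    mses <- run_mses(ff_dual, schedule, ladder, refs$closed,
                     mass = spec$mass, seed = config$seed + 31)
  }
  utils::write.table(mses$exchange_log,
                     keep(file.path(out_dir, "exchange_log.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("analysis", "free-energy surfaces in latent space")
  k0_traj <- trajectory_ensemble(mses$k0_frames, traj_closed$residue_ids,
                                 frame_interval = config$exchange_interval)
  z_mses <- vae_encode(model,
                       normalize_distances(compute_distances(k0_traj, fs$pairs)))
  zr <- rbind(z[, 1:2, drop = FALSE], series$z[, 1:2, drop = FALSE],
              z_mses[, 1:2, drop = FALSE])
  breaks <- list(seq(min(zr[, 1]), max(zr[, 1]), length.out = config$fes_bins + 1L),
                 seq(min(zr[, 2]), max(zr[, 2]), length.out = config$fes_bins + 1L))
  fes <- list(closed = fes_2d(pool_closed[, 1:2, drop = FALSE], breaks),
              second = fes_2d(pool_second[, 1:2, drop = FALSE], breaks),
              series = fes_2d(series$z[, 1:2, drop = FALSE], breaks),
              mses = fes_2d(z_mses[, 1:2, drop = FALSE], breaks))
  names(fes)[2] <- second_state
  for (nm in names(fes))
    keep(write_fes_tsv(fes[[nm]], file.path(out_dir, sprintf("fes_%s.tsv", nm))))

  manifest <- list(
    mode = mode, seed = config$seed, alpha = alpha,
    second_state = second_state,
    n_pairs = fs$n_pairs,
    acceptance = mses$acceptance,
    artifacts = lapply(stats::setNames(artifacts, basename(artifacts)),
                       function(p) list(md5 = unname(tools::md5sum(p)))),
    package_version = as.character(utils::packageVersion("vaemses")))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_stage("done", out_dir)

  invisible(list(spec = spec, refs = refs, domains = domains, features = fs,
                 model = model, series = series, schedule = schedule,
                 mses = mses, fes = fes, alpha = alpha, out_dir = out_dir,
                 manifest_path = manifest_path))
}
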