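# One shared end-to-end toy chain (basins -> Motion Tree -> features -> VAE),
# built lazily and reused by several test files to keep the suite fast.
.chain_cache <- new.env(parent = emptyenv())

toy_chain <- function() {
  if (!is.null(.chain_cache$chain)) return(.chain_cache$chain)
  spec <- toy_spec()
  traj_closed <- simulate_toy_state(spec, "closed", n_frames = 400L, seed = 11)
  traj_open <- simulate_toy_state(spec, "open", n_frames = 400L, seed = 12)
  fl <- fluctuation_matrix(list(traj_closed, traj_open))
  tree <- build_motion_tree(fl)
  domains <- extract_domains(tree, min_domain_size = 5L)
  fs <- suppressMessages(feature_set(list(traj_closed, traj_open), domains))
  model <- vae_train(fs$normalized, 2L, epochs = 300L, seed = 3,
                     config = vae_config(hidden_dims = c(256L, 256L)))
  z <- vae_encode(model, fs$normalized)
  .chain_cache$chain <- list(
    spec = spec, refs = make_references(spec),
    traj_closed = traj_closed, traj_open = traj_open,
    fluct = fl, tree = tree, domains = domains, fs = fs,
    model = model, z = z,
    z_closed = z[fs$state == "closed", , drop = FALSE],
    z_open = z[fs$state == "open", , drop = FALSE])
  .chain_cache$chain
}

# Shared VAE trained on the 2-D-manifold fixture (intrinsic dimension 2),
# reused by the autoencoding-consistency and adequacy checks.
manifold_model <- function() {
  if (!is.null(.chain_cache$manifold)) return(.chain_cache$manifold)
  fx <- make_manifold_fixture(n_frames = 2000L, n_features = 50L, seed = 42L)
  model <- vae_train(fx$x, 2L, epochs = 300L, seed = 7,
                     config = vae_config(hidden_dims = c(256L, 256L)))
  .chain_cache$manifold <- list(fx = fx, model = model,
                                z = vae_encode(model, fx$x))
  .chain_cache$manifold
}
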