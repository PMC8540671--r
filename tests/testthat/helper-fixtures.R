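# Shared fixtures, built in code at test time.

# Two-cluster data on a smooth 2-D manifold embedded in n_features dimensions:
# every feature is a nonlinear function of two latent parameters plus small
# noise, scaled into (0, 1). Intrinsic dimension 2 by construction.
make_manifold_fixture <- function(n_frames = 2000L, n_features = 50L,
                                  seed = 42L, noise_sd = 0.02) {
  set.seed(seed)
  half <- n_frames %/% 2L
  label <- rep(c("a", "b"), c(half, n_frames - half))
  t1 <- c(stats::rnorm(half, -1, 0.3), stats::rnorm(n_frames - half, 1, 0.3))
  t2 <- stats::rnorm(n_frames, 0, 0.6)
  w1 <- stats::runif(n_features, 0.6, 1.6)
  w2 <- stats::runif(n_features, 0.6, 1.6)
  p1 <- stats::runif(n_features, 0, 2 * pi)
  p2 <- stats::runif(n_features, 0, 2 * pi)
  a2 <- stats::runif(n_features, 0.8, 1.2)
  x <- vapply(seq_len(n_features), function(j)
    sin(w1[j] * t1 + p1[j]) + a2[j] * cos(w2[j] * t2 + p2[j]),
    numeric(n_frames))
  x <- x + matrix(stats::rnorm(length(x), sd = noise_sd), nrow(x), ncol(x))
  x <- apply(x, 2, function(col)
    0.05 + 0.9 * (col - min(col)) / (max(col) - min(col)))
  list(x = x, label = label, t = cbind(t1, t2))
}

# Minimal decoder-only latent model: y = sigmoid(z W + b), no hidden layers.
# Used to test alpha determination against a hand-controlled monotone decoder.
make_linear_decoder <- function(W, b) {
  W <- rbind(W)
  structure(list(enc = list(), dec = list(),
                 mu_layer = list(W = t(W), b = rep(0, nrow(W))),
                 lv_layer = list(W = t(W) * 0, b = rep(0, nrow(W))),
                 out_layer = list(W = W, b = b),
                 latent_dim = nrow(W), n_inp = ncol(W),
                 layer_sizes = c(ncol(W), nrow(W), ncol(W)),
                 config = vae_config(hidden_dims = integer(0)),
                 seed = NA_integer_),
            class = "latent_model")
}

# Mean silhouette width for a two-group labelling (Euclidean distances).
two_group_silhouette <- function(x, label) {
  x <- as.matrix(x)
  d <- as.matrix(stats::dist(x))
  groups <- unique(label)
  stopifnot(length(groups) == 2L)
  s <- vapply(seq_len(nrow(x)), function(i) {
    own <- label == label[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, !(label == label[i])])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
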