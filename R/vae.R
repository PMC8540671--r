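#' VAE training configuration
#'
#' The network is a fully connected autoencoder with a stochastic Gaussian
#' coding layer: `N_inp -> hidden -> ... -> L -> ... -> hidden -> N_inp`
#' (seven layers at the default two hidden layers per side). The output layer
#' is a sigmoid so reconstructions stay in `[0, 1]`, matching the normalized
#' distance features.
#'
#' @param hidden_dims Integer vector of encoder hidden widths (mirrored in
#'   the decoder). Default `c(1000, 1000)`.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param activation Hidden activation, `"relu"` or `"tanh"`.
#' @param loss Reconstruction loss: `"bce"` (Bernoulli cross-entropy, the
#'   default -- it balances the KL term well when most normalized distances
#'   are small) or `"mse"` (summed squared error).
#' @param kl_weight Weight on the KL divergence term; `0` disables the
#'   stochastic layer entirely, reducing training to a plain autoencoder.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(hidden_dims = c(1000L, 1000L), learning_rate = 1e-3,
                       batch_size = 256L, activation = c("relu", "tanh"),
                       loss = c("bce", "mse"), kl_weight = 1) {
  activation <- match.arg(activation)
  loss <- match.arg(loss)
  stopifnot(all(hidden_dims >= 1), learning_rate > 0, batch_size >= 1,
            kl_weight >= 0)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 activation = activation, loss = loss,
                 kl_weight = kl_weight),
            class = "vae_config")
}

act_fun <- function(a, name) switch(name, relu = pmax(a, 0), tanh = tanh(a))
act_grad <- function(h, name) switch(name, relu = (h > 0) * 1, tanh = 1 - h^2)
sigmoid <- function(a) 1 / (1 + exp(-a))

init_layer <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

affine <- function(x, layer) sweep(x %*% layer$W, 2, layer$b, "+")

# forward through encoder; returns hidden activations, mu, logvar
vae_forward_enc <- function(model, x) {
  cfg <- model$config
  h <- list()
  a <- x
  for (l in seq_along(model$enc)) {
    a <- act_fun(affine(a, model$enc[[l]]), cfg$activation)
    h[[l]] <- a
  }
  mu <- affine(a, model$mu_layer)
  logvar <- affine(a, model$lv_layer)
  logvar <- pmin(pmax(logvar, -12), 12)   # numerical guard
  list(h = h, mu = mu, logvar = logvar)
}

vae_forward_dec <- function(model, z) {
  cfg <- model$config
  h <- list()
  a <- z
  for (l in seq_along(model$dec)) {
    a <- act_fun(affine(a, model$dec[[l]]), cfg$activation)
    h[[l]] <- a
  }
  y <- sigmoid(affine(a, model$out_layer))
  list(h = h, y = y)
}

#' Train a variational autoencoder on normalized distance features
#'
#' Minimizes reconstruction loss plus the Kullback-Leibler divergence of the
#' Gaussian posterior from the standard-normal prior, with the Adam
#' optimizer and the reparameterization trick. Training is deterministic
#' given `seed`.
#'
#' @param x Numeric matrix `frames x N_inp` with entries in `[0, 1]`.
#' @param latent_dim Latent dimension `L` (must be `< N_inp`).
#' @param epochs Number of passes over the data (default 300).
#' @param seed Integer seed controlling initialization, shuffling and the
#'   reparameterization noise.
#' @param config A [vae_config()].
#' @return Object of class `latent_model` with `$layer_sizes`,
#'   `$training_log` (per-epoch total / reconstruction / KL loss), `$seed`,
#'   `$config` and opaque weights.
#' @export
vae_train <- function(x, latent_dim, epochs = 300L, seed = 1L,
                      config = vae_config()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("x must be finite")
  if (nrow(x) < 2) stop("need at least 2 frames")
  n_inp <- ncol(x)
  latent_dim <- as.integer(latent_dim)
  if (latent_dim < 1) stop("latent_dim must be >= 1")
  if (latent_dim >= n_inp)
    stop("latent_dim must be smaller than the feature dimension (not a compression)")

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  hd <- config$hidden_dims
  enc_sizes <- c(n_inp, hd)
  dec_sizes <- c(latent_dim, rev(hd))
  model <- list(
    enc = lapply(seq_along(hd), function(l) init_layer(enc_sizes[l], enc_sizes[l + 1])),
    mu_layer = init_layer(hd[length(hd)], latent_dim),
    lv_layer = init_layer(hd[length(hd)], latent_dim),
    dec = lapply(seq_along(hd), function(l) init_layer(dec_sizes[l], dec_sizes[l + 1])),
    out_layer = init_layer(hd[1], n_inp),
    latent_dim = latent_dim, n_inp = n_inp,
    layer_sizes = c(n_inp, hd, latent_dim, rev(hd), n_inp),
    config = config, seed = seed)
  # small variance at start: stabilizes early sampling
  model$lv_layer$W <- model$lv_layer$W * 0.01

  params <- c(
    stats::setNames(model$enc, paste0("enc", seq_along(model$enc))),
    list(mu_layer = model$mu_layer, lv_layer = model$lv_layer),
    stats::setNames(model$dec, paste0("dec", seq_along(model$dec))),
    list(out_layer = model$out_layer))
  adam_m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  adam_v <- adam_m
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  lr <- config$learning_rate
  klw <- config$kl_weight
  actn <- config$activation

  sync_model <- function() {
    for (l in seq_along(model$enc)) model$enc[[l]] <<- params[[paste0("enc", l)]]
    model$mu_layer <<- params$mu_layer
    model$lv_layer <<- params$lv_layer
    for (l in seq_along(model$dec)) model$dec[[l]] <<- params[[paste0("dec", l)]]
    model$out_layer <<- params$out_layer
  }

  nf <- nrow(x)
  bs <- min(config$batch_size, nf)
  log_total <- log_rec <- log_kl <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    idx <- sample.int(nf)
    ep_rec <- ep_kl <- 0; n_batch <- 0L
    for (start in seq(1, nf, by = bs)) {
      bi <- idx[start:min(start + bs - 1, nf)]
      xb <- x[bi, , drop = FALSE]
      B <- nrow(xb)
      sync_model()
      fe <- vae_forward_enc(model, xb)
      mu <- fe$mu; logvar <- fe$logvar
      if (klw > 0) {
        epsn <- matrix(stats::rnorm(B * latent_dim), B, latent_dim)
        z <- mu + exp(0.5 * logvar) * epsn
      } else {
        epsn <- NULL
        z <- mu
      }
      fd <- vae_forward_dec(model, z)
      y <- fd$y

      if (config$loss == "mse") {
        rec <- mean(rowSums((y - xb)^2))
        dY <- 2 * (y - xb) / B
      } else {
        yc <- pmin(pmax(y, 1e-7), 1 - 1e-7)
        rec <- mean(rowSums(-(xb * log(yc) + (1 - xb) * log(1 - yc))))
        dY <- (yc - xb) / (yc * (1 - yc)) / B
      }
      kl <- if (klw > 0)
        mean(-0.5 * rowSums(1 + logvar - mu^2 - exp(logvar))) else 0
      total <- rec + klw * kl
      if (!is.finite(total))
        stop(sprintf("training diverged (non-finite loss) at epoch %d; ",
                     ep), "reduce the learning rate or batch size")

      grads <- list()
      # --- decoder backprop ---
      d_pre <- dY * y * (1 - y)                      # sigmoid output layer
      a_prev <- if (length(model$dec)) fd$h[[length(fd$h)]] else z
      grads$out_layer <- list(W = crossprod(a_prev, d_pre), b = colSums(d_pre))
      d_a <- d_pre %*% t(params$out_layer$W)
      for (l in rev(seq_along(model$dec))) {
        d_pre <- d_a * act_grad(fd$h[[l]], actn)
        a_prev <- if (l > 1) fd$h[[l - 1]] else z
        grads[[paste0("dec", l)]] <- list(W = crossprod(a_prev, d_pre),
                                          b = colSums(d_pre))
        d_a <- d_pre %*% t(params[[paste0("dec", l)]]$W)
      }
      d_z <- d_a
      # --- latent layer ---
      if (klw > 0) {
        d_mu <- d_z + klw * mu / B
        d_lv <- d_z * epsn * 0.5 * exp(0.5 * logvar) +
          klw * 0.5 * (exp(logvar) - 1) / B
      } else {
        d_mu <- d_z
        d_lv <- matrix(0, B, latent_dim)
      }
      a_top <- fe$h[[length(fe$h)]]
      grads$mu_layer <- list(W = crossprod(a_top, d_mu), b = colSums(d_mu))
      grads$lv_layer <- list(W = crossprod(a_top, d_lv), b = colSums(d_lv))
      d_a <- d_mu %*% t(params$mu_layer$W) + d_lv %*% t(params$lv_layer$W)
      # --- encoder backprop ---
      for (l in rev(seq_along(model$enc))) {
        d_pre <- d_a * act_grad(fe$h[[l]], actn)
        a_prev <- if (l > 1) fe$h[[l - 1]] else xb
        grads[[paste0("enc", l)]] <- list(W = crossprod(a_prev, d_pre),
                                          b = colSums(d_pre))
        d_a <- d_pre %*% t(params[[paste0("enc", l)]]$W)
      }

      # --- Adam update ---
      t_step <- t_step + 1L
      corr1 <- 1 - b1^t_step
      corr2 <- 1 - b2^t_step
      for (nm in names(grads)) {
        for (fld in c("W", "b")) {
          g <- grads[[nm]][[fld]]
          adam_m[[nm]][[fld]] <- b1 * adam_m[[nm]][[fld]] + (1 - b1) * g
          adam_v[[nm]][[fld]] <- b2 * adam_v[[nm]][[fld]] + (1 - b2) * g^2
          mhat <- adam_m[[nm]][[fld]] / corr1
          vhat <- adam_v[[nm]][[fld]] / corr2
          params[[nm]][[fld]] <- params[[nm]][[fld]] -
            lr * mhat / (sqrt(vhat) + eps_adam)
        }
      }
      ep_rec <- ep_rec + rec; ep_kl <- ep_kl + kl; n_batch <- n_batch + 1L
    }
    log_rec[ep] <- ep_rec / n_batch
    log_kl[ep] <- ep_kl / n_batch
    log_total[ep] <- log_rec[ep] + klw * log_kl[ep]
  }
  sync_model()
  model$training_log <- data.frame(epoch = seq_len(epochs), total = log_total,
                                   reconstruction = log_rec, kl = log_kl)
  class(model) <- "latent_model"
  model
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("<latent_model> layers [%s], L = %d, %d epochs, final loss %.4g\n",
              paste(x$layer_sizes, collapse = ", "), x$latent_dim,
              nrow(x$training_log), utils::tail(x$training_log$total, 1)))
  invisible(x)
}

#' Encode features to latent coordinates
#'
#' Returns the posterior mean per frame (no sampling) so downstream
#' interpolation and free-energy estimates are deterministic.
#'
#' @param model A [vae_train()] model.
#' @param x Matrix `frames x N_inp` (a bare vector is taken as one frame).
#' @return Matrix `frames x L`.
#' @export
vae_encode <- function(model, x) {
  stopifnot(inherits(model, "latent_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$n_inp)
    stop(sprintf("x has %d columns but the model expects %d", ncol(x), model$n_inp))
  vae_forward_enc(model, x)$mu
}

#' Decode latent coordinates to reconstructed features
#'
#' Output passes through a sigmoid, so values always lie in `[0, 1]`.
#'
#' @param model A [vae_train()] model.
#' @param z Matrix `frames x L` (a bare vector is taken as one frame).
#' @return Matrix `frames x N_inp` in `[0, 1]`.
#' @export
vae_decode <- function(model, z) {
  stopifnot(inherits(model, "latent_model"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$latent_dim)
    stop(sprintf("z has %d columns but the model expects L = %d",
                 ncol(z), model$latent_dim))
  vae_forward_dec(model, z)$y
}

#' Per-feature reconstruction quality
#'
#' For each feature (column): the frame-averaged relative difference
#' `<|x - y| / x>` and the Pearson correlation of `x` and `y` across frames.
#' Features with zero variance in `x` get `NA` correlation and are flagged
#' rather than dropped.
#'
#' @param x Input features (`frames x N_inp`, strictly positive).
#' @param y Reconstructed features, same shape.
#' @return Object of class `reconstruction_report`: data frame with columns
#'   `feature`, `rel_diff`, `correlation`, `undefined_cor`.
#' @export
reconstruction_report <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("x and y must have the same shape")
  if (any(x <= 0)) stop("relative difference requires x > 0")
  rel <- colMeans(abs(x - y) / x)
  sx <- apply(x, 2, stats::sd)
  sy <- apply(y, 2, stats::sd)
  undef <- sx == 0 | sy == 0
  cc <- rep(NA_real_, ncol(x))
  ok <- !undef
  if (any(ok)) {
    xs <- scale(x[, ok, drop = FALSE])
    ys <- scale(y[, ok, drop = FALSE])
    cc[ok] <- colSums(xs * ys) / (nrow(x) - 1)
  }
  out <- data.frame(feature = if (!is.null(colnames(x))) colnames(x)
                              else seq_len(ncol(x)),
                    rel_diff = rel, correlation = cc, undefined_cor = undef,
                    row.names = NULL)
  class(out) <- c("reconstruction_report", "data.frame")
  out
}

#' Save / load a latent model
#'
#' Single-file checkpoint embedding layer sizes, seed and configuration.
#'
#' @param model A `latent_model`.
#' @param file Checkpoint path.
#' @export
save_latent_model <- function(model, file) {
  stopifnot(inherits(model, "latent_model"))
  saveRDS(model, file)
  invisible(file)
}

#' @rdname save_latent_model
#' @export
load_latent_model <- function(file) {
  m <- readRDS(file)
  stopifnot(inherits(m, "latent_model"))
  m
}
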