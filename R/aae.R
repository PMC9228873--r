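## Adversarial autoencoder with a 2-D latent space.
##
## A dense encoder maps each flattened 32x2 motion (64 values, row-major) to
## a 2-D latent point; a mirrored decoder reconstructs the motion; a
## discriminator is trained to tell prior samples (label 1) from encoder
## outputs (label 0), and the encoder is in turn updated to fool it, pulling
## the aggregated posterior toward the polar-rose prior.  In semi-supervised
## mode the discriminator additionally receives the one-hot motion label and
## prior samples are drawn from the label-matching component, which anchors
## each movement class to its own petal.

#' Hyperparameter configuration for the adversarial autoencoder
#'
#' @param widths integer vector of hidden-layer widths shared by encoder,
#'   (reversed) decoder and discriminator; values from
#'   {4, 8, 16, 32, 64, 128, 256, 512}, 2 or 3 layers.
#' @param ae_activation hidden activation of encoder/decoder:
#'   `"sigmoid"`, `"tanh"` or `"relu"`.
#' @param disc_activation hidden activation of the discriminator:
#'   `"sigmoid"` or `"relu"`.
#' @param learning_rate Adam learning rate for all three steps.
#' @param dropout dropout rate on hidden layers during training.
#' @param batch_size minibatch size (default 64).
#' @param latent_dim latent dimensionality (fixed at 2).
#' @param mode `"unsupervised"` or `"semi_supervised"`.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed integer seed driving initialisation, shuffling, prior draws
#'   and dropout.
#' @return an `aae_config` object.
#' @export
aae_config <- function(widths = c(64L, 64L), ae_activation = "relu",
                       disc_activation = "relu", learning_rate = 0.001,
                       dropout = 0, batch_size = 64L, latent_dim = 2L,
                       mode = c("unsupervised", "semi_supervised"),
                       max_epochs = 100L, patience = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(widths) %in% c(2L, 3L)) {
    stop_bad("widths must list 2 or 3 hidden layers")
  }
  if (!all(widths %in% c(4L, 8L, 16L, 32L, 64L, 128L, 256L, 512L))) {
    stop_bad("hidden widths must come from {4,8,...,512}")
  }
  if (!ae_activation %in% c("sigmoid", "tanh", "relu")) {
    stop_bad("ae_activation must be sigmoid, tanh or relu")
  }
  if (!disc_activation %in% c("sigmoid", "relu")) {
    stop_bad("disc_activation must be sigmoid or relu")
  }
  if (latent_dim != 2L) stop_bad("latent_dim is fixed at 2")
  stopifnot(learning_rate > 0, dropout >= 0, dropout < 1, batch_size >= 1,
            max_epochs >= 1, patience >= 1)
  structure(list(widths = as.integer(widths), ae_activation = ae_activation,
                 disc_activation = disc_activation,
                 learning_rate = learning_rate, dropout = dropout,
                 batch_size = as.integer(batch_size),
                 latent_dim = as.integer(latent_dim), mode = mode,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "aae_config")
}

#' Mean-squared reconstruction error
#'
#' Mean of squared coordinate differences over all entries.
#'
#' @param X,X_prime numeric matrices of identical shape.
#' @return non-negative scalar.
#' @export
reconstruction_loss <- function(X, X_prime) {
  if (!identical(dim(as.matrix(X)), dim(as.matrix(X_prime)))) {
    stop_bad("reconstruction_loss: shape mismatch")
  }
  mean((as.matrix(X_prime) - as.matrix(X))^2)
}

#' Mean binary cross-entropy
#'
#' Predictions outside (0, 1) are clamped at 1e-7 from the boundary (with a
#' warning) so the logarithms stay finite.
#'
#' @param targets 0/1 vector.
#' @param predictions vector of probabilities.
#' @return non-negative scalar.
#' @export
binary_cross_entropy <- function(targets, predictions) {
  stopifnot(length(targets) == length(predictions))
  if (!all(targets %in% c(0, 1))) stop_bad("targets must be 0 or 1")
  eps <- 1e-7
  if (any(predictions <= 0 | predictions >= 1)) {
    warning("predictions clamped away from {0,1} by 1e-7")
  }
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(targets * log(p) + (1 - targets) * log(1 - p))
}

## ---- data plumbing ---------------------------------------------------------

## flatten a list of motions into an n x 64 matrix (row-major per motion)
## plus labels and annotations
flatten_motions <- function(items) {
  X <- t(vapply(items, function(m) as.vector(t(m$points)),
                numeric(2L * nrow(items[[1L]]$points))))
  labels <- vapply(items, `[[`, "", "label")
  sched <- vapply(items, function(m) m$schedule_index %||% NA_integer_, 0L)
  noise <- vapply(items, function(m) m$noise_index %||% NA_integer_, 0L)
  list(X = X, labels = labels, schedule_index = sched, noise_index = noise)
}

label_index <- function(labels) {
  idx <- match(labels, motion_shapes())
  if (any(is.na(idx))) stop_bad("unknown label among: %s",
                                paste(unique(labels[is.na(idx)]),
                                      collapse = ", "))
  idx
}

one_hot <- function(idx, k = 6L) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Collect flattened train/validation/test matrices for one CV fold
#'
#' @param database a split `artificial_database` (see [split_database()]).
#' @param fold fold number, 1..5.
#' @return list of `train`, `validation`, `test`, each with `X` (n x 64),
#'   `labels`, `schedule_index`, `noise_index`, `dataset` (source dataset
#'   index per row).
#' @export
collect_fold <- function(database, fold = 1L) {
  if (is.null(database$split)) stop_bad("database has no split; call split_database()")
  f <- database$split$folds[[fold]]
  gather <- function(ids) {
    parts <- lapply(ids, function(i) {
      fl <- flatten_motions(database$datasets[[i]])
      fl$dataset <- rep(i, nrow(fl$X))
      fl
    })
    list(X = do.call(rbind, lapply(parts, `[[`, "X")),
         labels = unlist(lapply(parts, `[[`, "labels")),
         schedule_index = unlist(lapply(parts, `[[`, "schedule_index")),
         noise_index = unlist(lapply(parts, `[[`, "noise_index")),
         dataset = unlist(lapply(parts, `[[`, "dataset")))
  }
  list(train = gather(f$train), validation = gather(f$validation),
       test = gather(database$split$test))
}

## ---- training steps --------------------------------------------------------
## Each step takes and returns the full model bundle but touches only its
## own parameter set; the frozen sub-networks come back bit-identical.

## (i) reconstruction: update encoder + decoder to minimise the MSE
step_reconstruction <- function(model, Xb, config) {
  fe <- mlp_forward(model$enc, Xb, config$dropout, training = TRUE)
  fd <- mlp_forward(model$dec, fe$out, config$dropout, training = TRUE)
  err <- fd$out - Xb
  dz_dec <- 2 * err / length(err)
  gd <- mlp_backward(model$dec, fd, dz_dec)
  ge <- mlp_backward(model$enc, fe, gd$input)  # latent output is linear
  up <- adam_step(model$dec, gd, model$opt_dec, config$learning_rate)
  model$dec <- up$net; model$opt_dec <- up$state
  up <- adam_step(model$enc, ge, model$opt_enc, config$learning_rate)
  model$enc <- up$net; model$opt_enc <- up$state
  model$loss <- mean(err^2)
  model
}

## (ii) discriminator: prior draws labelled 1 vs encoder outputs labelled 0,
## encoder frozen
step_discriminator <- function(model, Xb, yb, config, mixture) {
  nb <- nrow(Xb)
  semi <- !is.null(yb)
  z_fake <- mlp_forward(model$enc, Xb)$out
  prior <- sample_prior(mixture, nb, labels = if (semi) yb else NULL)
  d_in_fake <- if (semi) cbind(z_fake, one_hot(yb)) else z_fake
  d_in_real <- if (semi) cbind(prior$z, one_hot(prior$component)) else prior$z
  Xd <- rbind(d_in_real, d_in_fake)
  yd <- c(rep(1, nb), rep(0, nb))
  fdx <- mlp_forward(model$disc, Xd, config$dropout, training = TRUE)
  p <- pmin(pmax(fdx$out[, 1L], 1e-7), 1 - 1e-7)
  dz_disc <- matrix((fdx$out[, 1L] - yd) / length(yd), ncol = 1L)
  gdx <- mlp_backward(model$disc, fdx, dz_disc)
  up <- adam_step(model$disc, gdx, model$opt_disc, config$learning_rate)
  model$disc <- up$net; model$opt_disc <- up$state
  model$loss <- binary_cross_entropy(yd, p)
  model
}

## (iii) generator: encoder updated so its outputs are scored 1 by the
## frozen discriminator (non-saturating convention)
step_generator <- function(model, Xb, yb, config) {
  nb <- nrow(Xb)
  semi <- !is.null(yb)
  fe <- mlp_forward(model$enc, Xb, config$dropout, training = TRUE)
  g_in <- if (semi) cbind(fe$out, one_hot(yb)) else fe$out
  fg <- mlp_forward(model$disc, g_in)
  pg <- pmin(pmax(fg$out[, 1L], 1e-7), 1 - 1e-7)
  dz_g <- matrix((fg$out[, 1L] - 1) / nb, ncol = 1L)
  gg <- mlp_backward(model$disc, fg, dz_g)
  dz_enc <- gg$input[, seq_len(config$latent_dim), drop = FALSE]
  ge <- mlp_backward(model$enc, fe, dz_enc)
  up <- adam_step(model$enc, ge, model$opt_gen, config$learning_rate)
  model$enc <- up$net; model$opt_gen <- up$state
  model$loss <- binary_cross_entropy(rep(1, nb), pg)
  model
}

## ---- training --------------------------------------------------------------

#' Train an adversarial autoencoder
#'
#' Each epoch alternates, per 64-sample minibatch, (i) a reconstruction step
#' minimising the mean squared error through encoder and decoder, (ii) a
#' discriminator step on prior draws (target 1) versus encoder outputs
#' (target 0) with the encoder frozen, and (iii) a generator step updating
#' only the encoder so its outputs are scored as 1 by the frozen
#' discriminator (non-saturating convention).  Training stops when the
#' validation metric (mean per-cluster KL divergence in semi-supervised
#' mode, validation reconstruction error in unsupervised mode) fails to
#' improve for `patience` epochs; the weights of the best validation epoch
#' are returned.
#'
#' @param data list with `train` and `validation`, each holding `X`
#'   (n x 64 matrix) and `labels`; see [collect_fold()].
#' @param config an [aae_config()].
#' @param mixture a [prior_mixture()].
#' @param verbose print per-epoch losses.
#' @return a `trained_aae`: encoder/decoder/discriminator networks, the
#'   config and mixture, and a history data frame with columns
#'   `epoch, L_AE, L_D, L_G, val_metric`.
#' @export
train_aae <- function(data, config, mixture = prior_mixture(),
                      verbose = FALSE) {
  stopifnot(inherits(config, "aae_config"), inherits(mixture, "prior_mixture"))
  Xtr <- data$train$X
  Xval <- data$validation$X
  if (is.null(Xtr) || nrow(Xtr) == 0L || is.null(Xval) || nrow(Xval) == 0L) {
    stop_bad("train and validation sets must be nonempty")
  }
  ytr <- label_index(data$train$labels)
  yval <- label_index(data$validation$labels)
  semi <- config$mode == "semi_supervised"
  n_in <- ncol(Xtr)
  d_in <- config$latent_dim + if (semi) mixture$n_components else 0L

  with_seed(config$seed, {
    enc <- mlp_init(c(n_in, config$widths, config$latent_dim),
                    config$ae_activation, "linear")
    dec <- mlp_init(c(config$latent_dim, rev(config$widths), n_in),
                    config$ae_activation, "linear")
    disc <- mlp_init(c(d_in, config$widths, 1L),
                     config$disc_activation, "sigmoid")
    opt_enc <- adam_init(enc); opt_dec <- adam_init(dec)
    opt_disc <- adam_init(disc); opt_gen <- adam_init(enc)
    lr <- config$learning_rate
    n <- nrow(Xtr)
    history <- data.frame(epoch = integer(), L_AE = numeric(),
                          L_D = numeric(), L_G = numeric(),
                          val_metric = numeric())
    best <- list(metric = Inf, epoch = 0L)
    wait <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_ae <- ep_d <- ep_g <- 0
      for (bi in batches) {
        model <- list(enc = enc, dec = dec, disc = disc,
                      opt_enc = opt_enc, opt_dec = opt_dec,
                      opt_disc = opt_disc, opt_gen = opt_gen)
        Xb <- Xtr[bi, , drop = FALSE]
        yb <- if (semi) ytr[bi] else NULL
        nb <- nrow(Xb)
        model <- step_reconstruction(model, Xb, config)
        ep_ae <- ep_ae + model$loss * nb
        model <- step_discriminator(model, Xb, yb, config, mixture)
        ep_d <- ep_d + model$loss * nb
        model <- step_generator(model, Xb, yb, config)
        ep_g <- ep_g + model$loss * nb
        enc <- model$enc; dec <- model$dec; disc <- model$disc
        opt_enc <- model$opt_enc; opt_dec <- model$opt_dec
        opt_disc <- model$opt_disc; opt_gen <- model$opt_gen
      }
      ep_ae <- ep_ae / n; ep_d <- ep_d / n; ep_g <- ep_g / n
      if (!all(is.finite(c(ep_ae, ep_d, ep_g)))) {
        cond <- structure(class = c("aae_divergence", "error", "condition"),
                          list(message = "training diverged (non-finite loss)",
                               call = NULL, history = history))
        stop(cond)
      }

      zval <- mlp_forward(enc, Xval)$out
      val_metric <- if (semi) {
        mean_cluster_kl(zval, data$validation$labels, mixture)
      } else {
        fdv <- mlp_forward(dec, zval)$out
        reconstruction_loss(Xval, fdv)
      }
      history <- rbind(history, data.frame(epoch = epoch, L_AE = ep_ae,
                                           L_D = ep_d, L_G = ep_g,
                                           val_metric = val_metric))
      if (verbose) {
        message(sprintf("epoch %3d  L_AE %.5f  L_D %.4f  L_G %.4f  val %.4f",
                        epoch, ep_ae, ep_d, ep_g, val_metric))
      }
      if (val_metric < best$metric - 1e-12) {
        best <- list(metric = val_metric, epoch = epoch,
                     enc = enc, dec = dec, disc = disc)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    if (is.null(best$enc)) best <- c(best, list(enc = enc, dec = dec,
                                                disc = disc))
    structure(list(encoder = best$enc, decoder = best$dec,
                   discriminator = best$disc, config = config,
                   mixture = mixture, history = history,
                   best_epoch = best$epoch,
                   val_metric = best$metric),
              class = "trained_aae")
  })
}

#' @export
print.trained_aae <- function(x, ...) {
  cat(sprintf("<trained_aae> mode %s, widths %s, %d epochs (best %d, val %.4f)\n",
              x$config$mode, paste(x$config$widths, collapse = "x"),
              nrow(x$history), x$best_epoch, x$val_metric))
  invisible(x)
}

#' Encode motions into the 2-D latent space
#'
#' Deterministic inference pass (dropout disabled).
#'
#' @param trained a `trained_aae` (or a bare encoder network).
#' @param motions a `motion_set`, a list of motions, or an n x 64 matrix of
#'   flattened motions.
#' @return n x 2 matrix of latent coordinates.
#' @export
encode <- function(trained, motions) {
  enc <- if (inherits(trained, "trained_aae")) trained$encoder else trained
  X <- if (is.matrix(motions)) motions else flatten_motions(motions)$X
  z <- mlp_forward(enc, X)$out
  if (any(!is.finite(z))) stop_bad("encoder produced non-finite coordinates")
  z
}

#' Reconstruct motions from latent coordinates
#' @param trained a `trained_aae`.
#' @param z n x 2 matrix of latent points.
#' @return n x 64 matrix of flattened reconstructions.
#' @export
decode <- function(trained, z) {
  mlp_forward(trained$decoder, as.matrix(z))$out
}

#' Write per-epoch training history to CSV
#' @param trained a `trained_aae`.
#' @param path output CSV path.
#' @export
write_training_log <- function(trained, path) {
  utils::write.csv(trained$history, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
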