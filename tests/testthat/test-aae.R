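# Prior sampling, loss primitives, gradient correctness, the three-step
# adversarial training procedure and encoding.

test_that("prior components sit on a circle with valid covariances", {
  mix <- prior_mixture()
  radii <- sqrt(rowSums(mix$means^2))
  expect_equal(radii, rep(4, 6L), tolerance = 1e-12)
  ang <- atan2(mix$means[, 2L], mix$means[, 1L])
  gaps <- sort((diff(c(ang, ang[1L] + 2 * pi)) + 2 * pi) %% (2 * pi))
  expect_equal(gaps, rep(pi / 3, 6L), tolerance = 1e-9)
  for (S in mix$covs) {
    expect_equal(S, t(S), tolerance = 1e-12)
    expect_true(all(eigen(S, symmetric = TRUE)$values > 0))
  }
})

test_that("prior sampling respects labels, counts and seeds", {
  degen <- prior_mixture(sigma_radial = 0, sigma_tangential = 0)
  d <- sample_prior(degen, 6L, labels = 1:6, seed = 1L)
  expect_equal(d$z, degen$means, tolerance = 1e-12)

  mix <- prior_mixture()
  big <- sample_prior(mix, 6000L, seed = 2L)
  counts <- tabulate(big$component, 6L)
  sigma <- sqrt(6000 * (1 / 6) * (5 / 6))
  expect_true(all(abs(counts - 1000) < 5 * sigma))

  a <- sample_prior(mix, 50L, seed = 3L)
  b <- sample_prior(mix, 50L, seed = 3L)
  expect_identical(a, b)
  expect_error(sample_prior(mix, 2L, labels = c(1L, 7L)), "out of range")
})

test_that("loss primitives match closed forms", {
  X <- matrix(0, 1L, 64L)
  Xp <- matrix(1, 1L, 64L)
  expect_equal(reconstruction_loss(X, X), 0)
  expect_equal(reconstruction_loss(X, Xp), 1)
  expect_equal(reconstruction_loss(X, 2 * Xp), 4 * reconstruction_loss(X, Xp))
  expect_error(reconstruction_loss(X, matrix(1, 2L, 64L)), "shape")

  expect_equal(binary_cross_entropy(1, 0.5), log(2), tolerance = 1e-12)
  expect_lt(binary_cross_entropy(c(0, 1), c(1e-7, 1 - 1e-7)), 1e-6)
  t <- c(1, 0, 1, 0)
  p <- c(0.9, 0.2, 0.6, 0.4)
  per <- vapply(seq_along(t), function(i) binary_cross_entropy(t[i], p[i]), 0)
  expect_equal(binary_cross_entropy(t, p), mean(per), tolerance = 1e-12)
  expect_warning(binary_cross_entropy(1, 1), "clamped")
})

test_that("backpropagated gradients match finite differences", {
  set.seed(9)
  net <- motionbandit:::mlp_init(c(5L, 4L, 3L), "tanh", "sigmoid")
  X <- matrix(stats::rnorm(10L), 2L, 5L)
  y <- matrix(stats::runif(6L), 2L, 3L)
  loss_of <- function(n) {
    out <- motionbandit:::mlp_forward(n, X)$out
    mean((out - y)^2)
  }
  fwd <- motionbandit:::mlp_forward(net, X)
  dz_out <- (2 * (fwd$out - y) / length(y)) *
    motionbandit:::act_grad("sigmoid", fwd$out)
  grads <- motionbandit:::mlp_backward(net, fwd, dz_out)
  h <- 1e-6
  for (l in 1:2) {
    for (idx in list(c(1L, 1L), c(2L, 3L))) {
      n2 <- net
      n2$W[[l]][idx[1L], idx[2L]] <- n2$W[[l]][idx[1L], idx[2L]] + h
      num <- (loss_of(n2) - loss_of(net)) / h
      expect_equal(grads$W[[l]][idx[1L], idx[2L]], num, tolerance = 1e-4)
    }
    n2 <- net
    n2$b[[l]][1L] <- n2$b[[l]][1L] + h
    expect_equal(grads$b[[l]][1L], (loss_of(n2) - loss_of(net)) / h,
                 tolerance = 1e-4)
  }
  # input gradient (used by the generator step)
  loss_of_x <- function(Xm) {
    out <- motionbandit:::mlp_forward(net, Xm)$out
    mean((out - y)^2)
  }
  X2 <- X
  X2[1L, 2L] <- X2[1L, 2L] + h
  expect_equal(grads$input[1L, 2L], (loss_of_x(X2) - loss_of_x(X)) / h,
               tolerance = 1e-4)
})

make_model <- function(semi = FALSE, seed = 5L) {
  set.seed(seed)
  enc <- motionbandit:::mlp_init(c(64L, 16L, 2L), "relu", "linear")
  dec <- motionbandit:::mlp_init(c(2L, 16L, 64L), "relu", "linear")
  disc <- motionbandit:::mlp_init(c(if (semi) 8L else 2L, 16L, 1L),
                                  "relu", "sigmoid")
  list(enc = enc, dec = dec, disc = disc,
       opt_enc = motionbandit:::adam_init(enc),
       opt_dec = motionbandit:::adam_init(dec),
       opt_disc = motionbandit:::adam_init(disc),
       opt_gen = motionbandit:::adam_init(enc))
}

test_that("each training step updates only its own parameter set", {
  cfg <- aae_config(widths = c(16L, 16L), max_epochs = 1L,
                    mode = "semi_supervised")
  mix <- prior_mixture()
  Xb <- matrix(stats::rnorm(8L * 64L), 8L, 64L)
  yb <- rep(1:2, 4L)
  m0 <- make_model(semi = TRUE)

  m1 <- motionbandit:::step_reconstruction(m0, Xb, cfg)
  expect_identical(m1$disc, m0$disc)          # discriminator frozen
  expect_false(identical(m1$enc, m0$enc))
  expect_false(identical(m1$dec, m0$dec))

  m2 <- motionbandit:::step_discriminator(m1, Xb, yb, cfg, mix)
  expect_identical(m2$enc, m1$enc)            # encoder frozen
  expect_identical(m2$dec, m1$dec)
  expect_false(identical(m2$disc, m1$disc))

  m3 <- motionbandit:::step_generator(m2, Xb, yb, cfg)
  expect_identical(m3$disc, m2$disc)          # discriminator frozen
  expect_identical(m3$dec, m2$dec)
  expect_false(identical(m3$enc, m2$enc))
  for (m in list(m1, m2, m3)) {
    expect_true(is.finite(m$loss))
    expect_gte(m$loss, 0)
  }
})

test_that("training reduces the reconstruction loss and stays finite", {
  data <- fixture_fold()
  small <- list(
    train = list(X = data$train$X[1:512, ], labels = data$train$labels[1:512]),
    validation = list(X = data$validation$X[1:128, ],
                      labels = data$validation$labels[1:128]))
  fit <- train_aae(small, aae_config(widths = c(32L, 32L), max_epochs = 10L,
                                     patience = 10L, seed = 6L),
                   prior_mixture())
  h <- fit$history
  expect_lt(h$L_AE[nrow(h)], h$L_AE[1L])
  expect_true(all(is.finite(c(h$L_AE, h$L_D, h$L_G))))
  expect_true(all(c(h$L_AE, h$L_D, h$L_G) >= 0))
})

test_that("encoding is deterministic, 2-D and total", {
  fit <- fixture_ssaae()
  data <- fixture_fold()
  z1 <- encode(fit, data$test$X)
  z2 <- encode(fit, data$test$X)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(nrow(data$test$X), 2L))
  expect_true(all(is.finite(z1)))
  # a full artificial dataset embeds to one point per motion
  db <- fixture_xyr_db()
  emb <- embed_dataset(fit, db$datasets[[1L]])
  expect_equal(nrow(emb$points), 360L)
})

test_that("checkpoints round-trip through JSON", {
  fit <- fixture_ssaae()
  data <- fixture_fold()
  f <- withr::local_tempfile(fileext = ".json")
  save_aae(fit, f)
  back <- load_aae(f)
  expect_equal(encode(back, data$test$X[1:20, ]),
               encode(fit, data$test$X[1:20, ]), tolerance = 1e-12)
  expect_equal(back$history$L_AE, fit$history$L_AE, tolerance = 1e-12)
})
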