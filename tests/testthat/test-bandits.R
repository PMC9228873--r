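# Softmax selection, the five agents' update rules, episode accounting and
# the hyperparameter grid search.

test_that("softmax probabilities match closed forms and limits", {
  expect_equal(softmax_probs(rep(2, 6L), 1), rep(1 / 6, 6L))
  p <- softmax_probs(c(1, 0), 1)
  expect_equal(p, c(exp(1), 1) / (1 + exp(1)), tolerance = 1e-12)
  # tau -> Inf approaches uniform; tau -> 0+ concentrates on the max
  expect_equal(softmax_probs(c(3, 1, 2), 1e6), rep(1 / 3, 3L),
               tolerance = 1e-5)
  expect_equal(softmax_probs(c(3, 1, 2), 1e-3)[1L], 1, tolerance = 1e-9)
  # overflow-safe for large magnitudes
  expect_prob_vector(softmax_probs(c(1e4, 0, -1e4), 1))
  expect_error(softmax_probs(c(1, 2), 0), "tau")
  expect_error(softmax_probs(c(1, Inf), 1), "finite")
})

test_that("the Boltzmann update is local and linear in the error", {
  cfg <- bandit_config("boltzmann")
  st <- bandit_state(cfg)
  st2 <- boltzmann_update(st, 3L, 2.5, alpha = 1)
  expect_equal(st2$mu_hat[3L], 2.5)            # alpha = 1 copies the reward
  expect_equal(st2$mu_hat[-3L], st$mu_hat[-3L])
  st$mu_hat[1L] <- 5
  expect_equal(boltzmann_update(st, 1L, 0, alpha = 0.1)$mu_hat[1L], 4.5)
})

test_that("UCB bonuses follow the radius formula", {
  cfg <- bandit_config("boltzmann_ucb")
  st <- bandit_state(cfg)
  st$counts <- rep(1L, 6L)
  st$t <- 10L
  expect_equal(ucb_values(st, c = 1e-12), st$mu_hat, tolerance = 1e-9)
  # closed form at t = e, N = 1, c = 1: bonus sqrt(1/2)
  st2 <- bandit_state(cfg)
  st2$counts <- rep(1L, 6L)
  st2$t <- exp(1)
  expect_equal(ucb_values(st2, c = 1), st2$mu_hat + sqrt(0.5),
               tolerance = 1e-12)
  # bonus decreases with the pull count at fixed t
  st3 <- bandit_state(cfg)
  st3$t <- 20L
  st3$counts <- c(1L, 2L, 4L, 8L, 16L, 32L)
  bon <- ucb_values(st3, c = 1) - st3$mu_hat
  expect_true(all(diff(bon) < 0))
  # unpulled arms force exploration
  st3$counts[2L] <- 0L
  expect_equal(ucb_values(st3, c = 1)[2L], Inf)
})

test_that("Kalman updates follow the gain algebra", {
  expect_equal(kalman_gain(1, 0, 1), 0.5)
  cfg <- bandit_config("kalman", sigma2_xi = 0, sigma2_eps = 1)
  st <- bandit_state(cfg)
  st$var_hat <- rep(1, 6L)
  st$mu_hat <- rep(2, 6L)
  st2 <- kalman_update(st, 1L, 4, 0, 1)
  expect_equal(st2$mu_hat[1L], 2 + 0.5 * (4 - 2))   # G = 0.5
  expect_equal(st2$var_hat[1L], 0.5)                # (1 - G)(var + xi)
  # untested arms: estimate unchanged, variance grows by sigma2_xi per step
  st3 <- kalman_update(st, 1L, 4, 0.25, 1)
  expect_equal(st3$mu_hat[-1L], st$mu_hat[-1L])
  expect_equal(st3$var_hat[-1L], st$var_hat[-1L] + 0.25)
  u <- 5L
  stu <- st
  for (i in seq_len(u)) stu <- kalman_update(stu, 1L, 4, 0.25, 1)
  expect_equal(stu$var_hat[2L], 1 + u * 0.25)
  # noiseless observation: gain 1, estimate equals the reward
  st4 <- kalman_update(st, 2L, 7, 0, 1e-12)
  expect_equal(st4$mu_hat[2L], 7, tolerance = 1e-9)
  # pulled-arm variance bounded by sigma2_eps after any update
  set.seed(21)
  for (i in 1:20) {
    v0 <- stats::runif(1, 0, 10)
    xi <- stats::runif(1, 0, 2)
    eps <- stats::runif(1, 0.01, 2)
    stx <- st
    stx$var_hat <- rep(v0, 6L)
    upd <- kalman_update(stx, 1L, 1, xi, eps)
    expect_lte(upd$var_hat[1L], eps + 1e-12)
  }
})

test_that("IUCB bonuses combine posterior and observation uncertainty", {
  cfg <- bandit_config("kalman_iucb")
  st <- bandit_state(cfg)
  expect_equal(iucb_values(st, c = 1e-12, cfg$sigma2_eps), st$mu_hat,
               tolerance = 1e-6)
  st$var_hat <- rep(3, 6L)
  expect_equal(iucb_values(st, c = 2, 1) - st$mu_hat, rep(4, 6L))
  # arms left untested accumulate a larger bonus
  st2 <- kalman_update(st, 1L, 1, 0.5, 1)
  b <- iucb_values(st2, c = 1, 1) - st2$mu_hat
  expect_gt(b[2L], b[1L])
})

test_that("Thompson samples come from the per-arm posteriors", {
  cfg <- bandit_config("kalman_ts")
  st <- bandit_state(cfg)
  st$mu_hat <- c(1, 2, 3, 4, 5, 6)
  st$var_hat <- rep(0, 6L)
  expect_equal(thompson_values(st, seed = 1L), st$mu_hat)
  st$var_hat <- rep(0.25, 6L)
  set.seed(2)
  draws <- colMeans(t(replicate(1e4, thompson_values(st))))
  se <- sqrt(0.25 / 1e4)
  expect_true(all(abs(draws - st$mu_hat) < 5 * se))
  expect_identical(thompson_values(st, seed = 7L),
                   thompson_values(st, seed = 7L))
})

test_that("episodes account the weighted-probability error correctly", {
  # perfect knowledge: constant rewards equal to Q0, agent temperature equal
  # to the evaluation temperature -> zero error forever
  rewards <- matrix(3, 60L, 6L)
  cfg <- bandit_config("boltzmann", Q0 = 3, alpha = 0.5, tau = 2, seed = 1L)
  ep <- run_episode(cfg, rewards, tau_star = 2)
  expect_equal(ep$ae, rep(0, 60L), tolerance = 1e-12)

  # constant rewards, Kalman, sigma2_xi = 0: pulled-arm error shrinks
  # monotonically toward the constant
  cfg2 <- bandit_config("kalman", sigma2_xi = 0, sigma2_eps = 0.5, tau = 2,
                        seed = 2L)
  rewards2 <- matrix(rep(c(1, 2, 3, 1.5, 2.5, 0.5), each = 60L), 60L, 6L)
  ep2 <- run_episode(cfg2, rewards2)
  mu <- as.matrix(ep2$log[, paste0("mu_", 1:6)])
  for (k in 1:6) {
    errs <- abs(mu[, k] - rewards2[1L, k])
    expect_true(all(diff(errs) <= 1e-9))
  }

  # ae is non-decreasing and probabilities are simplex vectors on any run
  seqs <- simulate_reward_sequences(2L, seed = 6L)
  for (kind in bandit_kinds()) {
    ep3 <- run_episode(bandit_config(kind, seed = 3L), seqs[[1L]])
    expect_true(all(diff(ep3$ae) >= -1e-12))
    P <- as.matrix(ep3$log[, paste0("P_", 1:6)])
    for (t in seq_len(nrow(P))) expect_prob_vector(P[t, ])
    # replay oracle reproduces the logged cumulative error exactly
    expect_equal(replay_error(ep3, seqs[[1L]]), ep3$ae, tolerance = 1e-12)
  }

  expect_error(run_episode(bandit_config("boltzmann"), rewards[1:10, ]),
               "iterations")
})

test_that("grid search returns the exhaustive minimiser", {
  seqs <- simulate_reward_sequences(2L, seed = 8L)
  single <- list(boltzmann = list(Q0 = 5, alpha = 0.3, tau = 2))
  gs1 <- grid_search(seqs, kinds = "boltzmann", grids = single, n_seeds = 2L)
  expect_equal(gs1$best$boltzmann$alpha, 0.3)
  expect_equal(nrow(gs1$table), 1L)

  grid22 <- list(boltzmann = list(Q0 = 5, alpha = c(0.1, 1), tau = c(1, 3)))
  gs2 <- grid_search(seqs, kinds = "boltzmann", grids = grid22, n_seeds = 2L,
                     seed = 5L)
  expect_equal(nrow(gs2$table), 4L)
  win <- gs2$best$boltzmann
  expect_equal(min(gs2$table$mean_ae),
               gs2$table$mean_ae[gs2$table$alpha == win$alpha &
                                   gs2$table$tau == win$tau])
  expect_error(grid_search(seqs, kinds = "boltzmann",
                           grids = list(boltzmann = list())), "empty")
})
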