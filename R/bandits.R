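## Non-stationary multi-armed bandits over latent-distance rewards.
##
## Six arms, one per movement; the reward of an arm at iteration t is the
## latent distance of that movement to its target centroid.  Arms are chosen
## probabilistically through a softmax over the agent's value vector; five
## agents differ in how values are formed and updated:
##   boltzmann      constant-rate exponential update, softmax of estimates
##   boltzmann_ucb  same update, softmax of estimates + UCB bonus
##   kalman         per-arm Kalman tracking (adaptive gain), softmax
##   kalman_iucb    Kalman + bonus from posterior sd and observation noise
##   kalman_ts      Kalman + Thompson sampling from each arm's posterior
## Agents are scored by the cumulative weighted-probability error comparing
## probability-weighted estimated rewards with their true counterparts.

#' The five bandit agent kinds
#' @return character vector of the agent identifiers.
#' @export
bandit_kinds <- function() {
  c("boltzmann", "boltzmann_ucb", "kalman", "kalman_iucb", "kalman_ts")
}

#' Configuration of one bandit agent
#'
#' Defaults for the free parameters are the minimisers of the cumulative
#' weighted-probability error found by [grid_search()] over the published
#' parameter grids on reward sequences from a code-X artificial database;
#' any value can be overridden.
#'
#' @param kind one of [bandit_kinds()].
#' @param Q0 optimistic initial value for all arm estimates (default 5).
#' @param alpha learning rate in (0, 1] (Boltzmann kinds).
#' @param tau softmax temperature > 0.
#' @param c confidence level > 0 (UCB/IUCB kinds).
#' @param sigma2_xi innovation variance >= 0 (Kalman kinds).
#' @param sigma2_eps observation variance > 0 (Kalman kinds).
#' @param n_arms number of arms (default 6).
#' @param horizon episode length (default 60).
#' @param seed seed for action draws (and Thompson sampling).
#' @return a `bandit_config` object.
#' @export
bandit_config <- function(kind = bandit_kinds(), Q0 = 5, alpha = NULL,
                          tau = NULL, c = NULL, sigma2_xi = NULL,
                          sigma2_eps = NULL, n_arms = 6L, horizon = 60L,
                          seed = 1L) {
  kind <- match.arg(kind)
  def <- bandit_selected_params()[[kind]]
  alpha <- alpha %||% def$alpha %||% 0.5
  tau <- tau %||% def$tau %||% 2
  c <- c %||% def$c %||% 1
  sigma2_xi <- sigma2_xi %||% def$sigma2_xi %||% 0.5
  sigma2_eps <- sigma2_eps %||% def$sigma2_eps %||% 0.1
  stopifnot(alpha > 0, alpha <= 1, tau > 0, c > 0, sigma2_xi >= 0,
            sigma2_eps > 0, n_arms >= 2L, horizon >= 1L)
  structure(list(kind = kind, Q0 = Q0, alpha = alpha, tau = tau, c = c,
                 sigma2_xi = sigma2_xi, sigma2_eps = sigma2_eps,
                 n_arms = as.integer(n_arms), horizon = as.integer(horizon),
                 seed = as.integer(seed)),
            class = "bandit_config")
}

#' Initial agent state
#'
#' Estimates start at the optimistic value `Q0`; Kalman posterior variances
#' start at `sigma2_xi + sigma2_eps` (a weakly-informative prior on the
#' model's own noise scale); pull counts at zero.
#'
#' @param config a [bandit_config()].
#' @return a `bandit_state` list.
#' @export
bandit_state <- function(config) {
  structure(list(mu_hat = rep(config$Q0, config$n_arms),
                 var_hat = rep(config$sigma2_xi + config$sigma2_eps,
                               config$n_arms),
                 counts = integer(config$n_arms), t = 0L),
            class = "bandit_state")
}

#' Softmax selection probabilities
#'
#' Computed with max-subtraction for overflow safety.
#'
#' @param values finite numeric value vector.
#' @param tau temperature > 0.
#' @return probability vector summing to 1.
#' @export
softmax_probs <- function(values, tau) {
  if (tau <= 0) stop_bad("tau must be > 0")
  if (any(!is.finite(values))) stop_bad("softmax values must be finite")
  e <- exp((values - max(values)) / tau)
  e / sum(e)
}

#' Constant-rate value update (Boltzmann kinds)
#'
#' Moves only the pulled arm's estimate by `alpha` times the prediction
#' error and increments its pull count.
#'
#' @param state a `bandit_state`.
#' @param arm pulled arm index.
#' @param reward observed reward.
#' @param alpha learning rate in (0, 1].
#' @return updated state.
#' @export
boltzmann_update <- function(state, arm, reward, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  state$mu_hat[arm] <- state$mu_hat[arm] +
    alpha * (reward - state$mu_hat[arm])
  state$counts[arm] <- state$counts[arm] + 1L
  state
}

#' Estimates augmented by the UCB exploration bonus
#'
#' `mu_hat_k + c * sqrt(ln t / (2 N_k))`; arms never pulled receive an
#' infinite bonus so each arm is tried at least once.
#'
#' @param state a `bandit_state` with `t >= 1`.
#' @param c confidence level.
#' @return value vector (may contain `Inf` for unpulled arms).
#' @export
ucb_values <- function(state, c) {
  t <- max(state$t, 1L)
  bonus <- ifelse(state$counts > 0L,
                  c * sqrt(log(t) / (2 * state$counts)), Inf)
  state$mu_hat + bonus
}

#' Sibling Kalman filter update
#'
#' The pulled arm's estimate moves by the Kalman gain
#' `G = (var + sigma2_xi) / (var + sigma2_xi + sigma2_eps)` times the
#' prediction error and its variance contracts to `(1 - G)(var + sigma2_xi)`;
#' every untested arm's variance inflates by `sigma2_xi`.
#'
#' @param state a `bandit_state`.
#' @param arm pulled arm index.
#' @param reward observed reward.
#' @param sigma2_xi innovation variance >= 0.
#' @param sigma2_eps observation variance > 0.
#' @return updated state.
#' @export
kalman_update <- function(state, arm, reward, sigma2_xi, sigma2_eps) {
  stopifnot(sigma2_eps > 0, sigma2_xi >= 0)
  prior_var <- state$var_hat[arm] + sigma2_xi
  G <- prior_var / (prior_var + sigma2_eps)
  new_var <- state$var_hat + sigma2_xi
  new_var[arm] <- (1 - G) * prior_var
  state$mu_hat[arm] <- state$mu_hat[arm] + G * (reward - state$mu_hat[arm])
  state$var_hat <- new_var
  state$counts[arm] <- state$counts[arm] + 1L
  state
}

#' Kalman gain for a given prior variance
#' @param var_hat current posterior variance of the arm.
#' @param sigma2_xi innovation variance.
#' @param sigma2_eps observation variance.
#' @return gain in (0, 1).
#' @export
kalman_gain <- function(var_hat, sigma2_xi, sigma2_eps) {
  (var_hat + sigma2_xi) / (var_hat + sigma2_xi + sigma2_eps)
}

#' Estimates augmented by the innovation UCB bonus
#'
#' `mu_hat_k + c * sqrt(var_hat_k + sigma2_eps)`: exploration driven by the
#' posterior uncertainty plus the observation noise, so arms left untested
#' keep growing more attractive.
#'
#' @param state a Kalman-kind `bandit_state`.
#' @param c confidence level.
#' @param sigma2_eps observation variance.
#' @return value vector.
#' @export
iucb_values <- function(state, c, sigma2_eps) {
  state$mu_hat + c * sqrt(state$var_hat + sigma2_eps)
}

#' Thompson samples from each arm's posterior
#'
#' One Gaussian draw per arm, `theta_k ~ N(mu_hat_k, var_hat_k)`.
#'
#' @param state a Kalman-kind `bandit_state`.
#' @param seed optional seed.
#' @return sampled value vector.
#' @export
thompson_values <- function(state, seed = NULL) {
  with_seed(seed,
            stats::rnorm(length(state$mu_hat), state$mu_hat,
                         sqrt(pmax(state$var_hat, 0))))
}

## selection probabilities for one iteration; handles the infinite UCB
## bonus by forcing uniform choice among unexplored arms
selection_probs <- function(values, tau) {
  if (any(is.infinite(values))) {
    p <- as.numeric(is.infinite(values))
    return(p / sum(p))
  }
  softmax_probs(values, tau)
}

#' Run one bandit episode against a reward sequence
#'
#' At each iteration the agent forms its value vector (per its kind),
#' converts it to selection probabilities with its own temperature, draws an
#' arm, observes that arm's true reward at the current iteration and updates
#' its estimates.  Concurrently the evaluator forms the true probability
#' vector `P*(t)` (softmax of the full true reward vector at temperature
#' `tau_star`) and accumulates the weighted-probability error
#' `ae(T) = sum_{t<=T} sum_k |P*_k(t) mu*_k(t) - P_k(t) mu_hat_k(t)|`,
#' with `mu_hat` taken as the estimates the agent acted on at iteration t.
#'
#' @param config a [bandit_config()].
#' @param rewards T x K matrix of true rewards (iterations x arms), e.g. a
#'   [latent_distances()] result.
#' @param tau_star temperature of the true probability softmax (default 2).
#' @param seed optional seed overriding `config$seed`.
#' @return an `error_curve`: list with `ae` (cumulative error per
#'   iteration), `log` (data frame `t, arm, reward` plus `P_k`, `mu_k`
#'   columns and `ae`), and the config.
#' @export
run_episode <- function(config, rewards, tau_star = 2, seed = NULL) {
  stopifnot(inherits(config, "bandit_config"))
  rewards <- as.matrix(rewards)
  K <- config$n_arms
  if (ncol(rewards) != K) {
    stop_bad("reward matrix has %d arms, config expects %d",
             ncol(rewards), K)
  }
  if (nrow(rewards) != config$horizon) {
    stop_bad("reward matrix has %d iterations, config expects %d",
             nrow(rewards), config$horizon)
  }
  state <- bandit_state(config)
  ae <- numeric(config$horizon)
  log_arm <- integer(config$horizon)
  log_reward <- numeric(config$horizon)
  log_P <- matrix(0, config$horizon, K)
  log_mu <- matrix(0, config$horizon, K)
  acc <- 0
  with_seed(seed %||% config$seed, {
    for (t in seq_len(config$horizon)) {
      state$t <- t
      values <- switch(config$kind,
        boltzmann = state$mu_hat,
        boltzmann_ucb = ucb_values(state, config$c),
        kalman = state$mu_hat,
        kalman_iucb = iucb_values(state, config$c, config$sigma2_eps),
        kalman_ts = thompson_values(state))
      P <- selection_probs(values, config$tau)
      arm <- sample.int(K, 1L, prob = P)
      reward <- rewards[t, arm]
      mu_true <- rewards[t, ]
      P_star <- softmax_probs(mu_true, tau_star)
      acc <- acc + sum(abs(P_star * mu_true - P * state$mu_hat))
      ae[t] <- acc
      log_arm[t] <- arm
      log_reward[t] <- reward
      log_P[t, ] <- P
      log_mu[t, ] <- state$mu_hat
      state <- switch(config$kind,
        boltzmann = ,
        boltzmann_ucb = boltzmann_update(state, arm, reward, config$alpha),
        kalman_update(state, arm, reward, config$sigma2_xi,
                      config$sigma2_eps))
    }
  })
  colnames(log_P) <- paste0("P_", seq_len(K))
  colnames(log_mu) <- paste0("mu_", seq_len(K))
  log <- data.frame(t = seq_len(config$horizon), arm = log_arm,
                    reward = log_reward)
  log <- cbind(log, log_P, log_mu, ae = ae)
  structure(list(ae = ae, log = log, config = config, tau_star = tau_star,
                 final_state = state),
            class = "error_curve")
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf("<error_curve> %s: ae(%d) = %.3f\n", x$config$kind,
              length(x$ae), x$ae[length(x$ae)]))
  invisible(x)
}

#' Replay a logged episode and recompute its error curve
#'
#' Independent accounting check: reconstructs `ae(T)` from the logged
#' per-iteration probabilities, estimates and true rewards alone.
#'
#' @param curve an `error_curve`.
#' @param rewards the reward matrix the episode was run against.
#' @return numeric vector of recomputed cumulative errors.
#' @export
replay_error <- function(curve, rewards) {
  K <- curve$config$n_arms
  P <- as.matrix(curve$log[, paste0("P_", seq_len(K))])
  mu <- as.matrix(curve$log[, paste0("mu_", seq_len(K))])
  inc <- vapply(seq_len(nrow(P)), function(t) {
    mu_true <- rewards[t, ]
    P_star <- softmax_probs(mu_true, curve$tau_star)
    sum(abs(P_star * mu_true - P[t, ] * mu[t, ]))
  }, 0)
  cumsum(inc)
}

#' Default agent parameters selected by grid search
#'
#' Per-kind parameter values minimising the mean cumulative
#' weighted-probability error at the horizon over code-X artificial-database
#' reward sequences (the procedure implemented by [grid_search()]); used as
#' the defaults of [bandit_config()].
#'
#' @return named list of per-kind parameter lists.
#' @export
bandit_selected_params <- function() {
  list(
    boltzmann = list(Q0 = 5, alpha = 1.0, tau = 2),
    boltzmann_ucb = list(Q0 = 5, alpha = 1.0, c = 1, tau = 2),
    kalman = list(Q0 = 5, sigma2_xi = 2, sigma2_eps = 0.01, tau = 2),
    kalman_iucb = list(Q0 = 5, sigma2_xi = 0.05, sigma2_eps = 0.01,
                       tau = 2, c = 1),
    kalman_ts = list(Q0 = 5, sigma2_xi = 0.05, sigma2_eps = 0.05, tau = 3)
  )
}

#' The published hyperparameter grids per agent kind
#'
#' @return named list of parameter grids (one list of candidate vectors per
#'   agent kind).
#' @export
bandit_param_grids <- function() {
  list(
    boltzmann = list(Q0 = 5, alpha = c(0.05, 0.1, 0.2, 0.5, 1.0),
                     tau = c(1, 2, 3)),
    boltzmann_ucb = list(Q0 = 5, alpha = c(0.05, 0.1, 0.2, 0.5, 1.0),
                         c = c(1, 2, 3), tau = c(1, 2, 3)),
    kalman = list(Q0 = 5, sigma2_xi = c(0.01, 0.05, 0.1, 0.2, 0.5, 1, 2),
                  sigma2_eps = c(0.01, 0.05, 0.1, 0.5, 1), tau = c(1, 2, 3)),
    kalman_iucb = list(Q0 = 5, sigma2_xi = c(0.01, 0.05, 0.1, 0.2, 0.5, 1, 2),
                       sigma2_eps = c(0.01, 0.05, 0.1, 0.5, 1),
                       tau = c(1, 2, 3, 4), c = c(1, 2, 3, 4)),
    kalman_ts = list(Q0 = 5, sigma2_xi = c(0.01, 0.05, 0.1, 0.2, 0.5, 1, 2),
                     sigma2_eps = c(0.01, 0.05, 0.1, 0.5, 1),
                     tau = c(1, 2, 3, 4))
  )
}

#' Grid search for bandit hyperparameters
#'
#' Evaluates every combination of each agent kind's grid by its mean
#' cumulative weighted-probability error at the horizon over the supplied
#' reward sequences (each replicated over `n_seeds` episode seeds) and
#' returns the minimiser per kind plus the full result table.
#'
#' @param reward_sequences list of T x K reward matrices.
#' @param kinds agent kinds to search (default all five).
#' @param grids parameter grids, as [bandit_param_grids()].
#' @param n_seeds episode seeds per combination (default 3).
#' @param tau_star evaluation temperature (default 2).
#' @param seed master seed.
#' @return list with `best` (named list of `bandit_config` per kind) and
#'   `table` (data frame of every combination's mean/sd final error).
#' @export
grid_search <- function(reward_sequences, kinds = bandit_kinds(),
                        grids = bandit_param_grids(), n_seeds = 3L,
                        tau_star = 2, seed = 1L) {
  if (length(reward_sequences) == 0L) stop_bad("no reward sequences supplied")
  horizon <- nrow(reward_sequences[[1L]])
  n_arms <- ncol(reward_sequences[[1L]])
  best <- list()
  rows <- list()
  for (kind in kinds) {
    grid <- grids[[kind]]
    if (is.null(grid) || length(grid) == 0L) {
      stop_bad("empty parameter grid for kind '%s'", kind)
    }
    combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
    scores <- numeric(nrow(combos))
    sds <- numeric(nrow(combos))
    for (i in seq_len(nrow(combos))) {
      cfg_args <- as.list(combos[i, , drop = FALSE])
      cfg <- do.call(bandit_config,
                     c(list(kind = kind, horizon = horizon,
                            n_arms = n_arms), cfg_args))
      finals <- unlist(lapply(seq_along(reward_sequences), function(r) {
        vapply(seq_len(n_seeds), function(s) {
          ep_seed <- derive_seed(seed, sprintf("%s-%d-%d-%d", kind, i, r, s))
          ep <- run_episode(cfg, reward_sequences[[r]], tau_star,
                            seed = ep_seed)
          ep$ae[horizon]
        }, 0)
      }))
      scores[i] <- mean(finals)
      sds[i] <- stats::sd(finals)
    }
    combos$mean_ae <- scores
    combos$sd_ae <- sds
    combos$kind <- kind
    rows[[kind]] <- combos
    win <- which.min(scores)
    best[[kind]] <- do.call(bandit_config,
                            c(list(kind = kind, horizon = horizon,
                                   n_arms = n_arms),
                              as.list(combos[win, names(grid),
                                             drop = FALSE])))
  }
  all_params <- unique(unlist(lapply(rows, function(d) {
    setdiff(names(d), c("kind", "mean_ae", "sd_ae"))
  })))
  table <- do.call(rbind, lapply(rows, function(d) {
    for (p in setdiff(all_params, names(d))) d[[p]] <- NA
    d[, c("kind", all_params, "mean_ae", "sd_ae")]
  }))
  rownames(table) <- NULL
  list(best = best, table = table)
}

#' Simulate synthetic latent-distance reward sequences
#'
#' Emulates the qualitative shape of latent rewards from an artificial
#' subject: per arm, a piecewise-linear distance decaying from a random
#' start toward zero over the horizon, with one randomly chosen arm
#' receiving a mid-episode jump (an abrupt skill regression) that then
#' decays again, plus small observation noise.
#'
#' @param n number of sequences.
#' @param horizon iterations per sequence (default 60).
#' @param n_arms arms per sequence (default 6).
#' @param noise_sd additive noise standard deviation (default 0.05).
#' @param seed master seed.
#' @return list of `horizon x n_arms` reward matrices.
#' @export
simulate_reward_sequences <- function(n, horizon = 60L, n_arms = 6L,
                                      noise_sd = 0.05, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      m <- vapply(seq_len(n_arms), function(k) {
        start <- stats::runif(1, 2, 6)
        seq(start, start * 0.05, length.out = horizon)
      }, numeric(horizon))
      jump_arm <- sample.int(n_arms, 1L)
      t_jump <- sample(25:40, 1L)
      jump_to <- stats::runif(1, 1, 4)
      m[t_jump:horizon, jump_arm] <-
        seq(jump_to, jump_to * 0.1, length.out = horizon - t_jump + 1L)
      m <- m + matrix(stats::rnorm(length(m), 0, noise_sd),
                      horizon, n_arms)
      m <- pmax(m, 0)
      colnames(m) <- if (n_arms == 6L) motion_shapes() else
        paste0("arm_", seq_len(n_arms))
      m
    })
  })
}

#' Write an episode log to CSV
#' @param curve an `error_curve`.
#' @param path output path.
#' @export
write_episode_csv <- function(curve, path) {
  utils::write.csv(curve$log, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
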