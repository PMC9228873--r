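## Polar-rose Gaussian mixture: the latent prior.
##
## Six two-dimensional Gaussian components whose means sit uniformly on a
## circle, each with an anisotropic covariance whose long axis points
## radially, so the density resembles a six-petal polar rose.  Component i
## is the latent target for motion label i (in motion_shapes() order).

#' Construct the six-component polar-rose latent prior
#'
#' @param n_components number of components (default 6, one per label).
#' @param radius distance of each component mean from the origin (default 4).
#' @param sigma_radial standard deviation along the radial axis (default 1).
#' @param sigma_tangential standard deviation along the tangential axis
#'   (default 0.5).
#' @return a `prior_mixture`: list with `means` (k x 2), `covs` (list of
#'   2 x 2 matrices) and `n_components`.
#' @export
prior_mixture <- function(n_components = 6L, radius = 4,
                          sigma_radial = 1, sigma_tangential = 0.5) {
  stopifnot(n_components >= 1L, radius >= 0,
            sigma_radial >= 0, sigma_tangential >= 0)
  angles <- 2 * pi * (seq_len(n_components) - 1L) / n_components
  means <- cbind(radius * cos(angles), radius * sin(angles))
  covs <- lapply(angles, function(a) {
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
    rot %*% diag(c(sigma_radial^2, sigma_tangential^2)) %*% t(rot)
  })
  structure(list(n_components = as.integer(n_components),
                 means = means, covs = covs),
            class = "prior_mixture")
}

#' Draw latent samples from the prior mixture
#'
#' Unsupervised draws pick a component uniformly at random per sample;
#' supervised draws (when `labels` is given) take each sample from the
#' component matching its label index.
#'
#' @param mixture a [prior_mixture()].
#' @param n number of samples.
#' @param labels optional integer component indices (1-based, length `n`).
#' @param seed optional seed.
#' @return list with `z` (n x 2 matrix) and `component` (integer vector).
#' @export
sample_prior <- function(mixture, n, labels = NULL, seed = NULL) {
  stopifnot(inherits(mixture, "prior_mixture"), n >= 1L)
  k <- mixture$n_components
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop_bad("labels must have length n")
    if (any(labels < 1L | labels > k)) {
      stop_bad("label index out of range 1..%d", k)
    }
  }
  with_seed(seed, {
    comp <- if (is.null(labels)) sample.int(k, n, replace = TRUE) else labels
    # per-component square-root factor via eigendecomposition (tolerates
    # degenerate zero-covariance components)
    chols <- lapply(mixture$covs, function(S) {
      e <- eigen(S, symmetric = TRUE)
      sqrt(pmax(e$values, 0)) * t(e$vectors)
    })
    z <- matrix(0, n, 2L)
    eps <- matrix(stats::rnorm(2L * n), n, 2L)
    for (ci in unique(comp)) {
      rows <- which(comp == ci)
      z[rows, ] <- eps[rows, , drop = FALSE] %*% chols[[ci]] +
        matrix(mixture$means[ci, ], length(rows), 2L, byrow = TRUE)
    }
    list(z = z, component = comp)
  })
}
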