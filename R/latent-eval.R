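## Latent-space evaluation and reward extraction.
##
## The quality of an embedding is measured two ways: how closely each
## label's embedded cloud matches its prior component (closed-form Gaussian
## KL divergence, averaged over the six clusters) and how separable the
## labels are (k-nearest-neighbour accuracy).  For the bandit stage, each
## embedded test point is reduced to the Euclidean distance to its label's
## target centroid, ordered along the augmentation schedule into a
## 60-iteration reward sequence per label.

#' Closed-form KL divergence between two multivariate Gaussians
#'
#' `D_KL(p || q) = 1/2 [ tr(S_q^-1 S_p) + (m_q - m_p)' S_q^-1 (m_q - m_p)
#'   - d + ln(det S_q / det S_p) ]`.
#'
#' @param mean_p,mean_q mean vectors.
#' @param cov_p,cov_q symmetric positive-definite covariance matrices.
#'   Near-singular covariances are regularised by `+ 1e-8 I` with a warning.
#' @return non-negative scalar; 0 iff the distributions coincide.
#' @export
gaussian_kl <- function(mean_p, cov_p, mean_q, cov_q) {
  mean_p <- as.numeric(mean_p); mean_q <- as.numeric(mean_q)
  d <- length(mean_p)
  stopifnot(length(mean_q) == d,
            all(dim(cov_p) == d), all(dim(cov_q) == d))
  fix <- function(S, tag) {
    S <- (S + t(S)) / 2
    if (!all(is.finite(S))) stop_bad("non-finite covariance (%s)", tag)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(abs(ev), 1)) {
      warning(sprintf("near-singular covariance (%s) regularised by 1e-8 I",
                      tag))
      S <- S + diag(1e-8, d)
    }
    S
  }
  Sp <- fix(as.matrix(cov_p), "p")
  Sq <- fix(as.matrix(cov_q), "q")
  Sq_inv <- solve(Sq)
  dm <- mean_q - mean_p
  val <- 0.5 * (sum(diag(Sq_inv %*% Sp)) + drop(t(dm) %*% Sq_inv %*% dm) -
                  d + log(det(Sq) / det(Sp)))
  max(val, 0)
}

#' Mean per-cluster KL divergence of an embedding against the prior
#'
#' Fits a Gaussian (sample mean, sample covariance) to each label's embedded
#' points and computes `D_KL(prior component || fitted)` per cluster,
#' returning the mean over clusters.  Labels are matched to prior components
#' in [motion_shapes()] order.
#'
#' @param points n x 2 matrix of latent coordinates.
#' @param labels label per point; every present label needs >= 3 points.
#' @param mixture a [prior_mixture()].
#' @return non-negative scalar.
#' @export
mean_cluster_kl <- function(points, labels, mixture = prior_mixture()) {
  points <- as.matrix(points)
  idx <- label_index(labels)
  kls <- vapply(sort(unique(idx)), function(ci) {
    rows <- which(idx == ci)
    if (length(rows) < 3L) {
      stop_bad("label '%s' has fewer than 3 embedded points",
               motion_shapes()[ci])
    }
    zc <- points[rows, , drop = FALSE]
    S <- stats::cov(zc)
    gaussian_kl(mixture$means[ci, ], mixture$covs[[ci]], colMeans(zc), S)
  }, 0)
  mean(kls)
}

#' k-nearest-neighbour classification accuracy in the latent space
#'
#' Each test point is classified by majority vote among its `k` nearest
#' training points (Euclidean distance).  Vote ties are broken by the
#' smallest summed distance among the tied classes, then by label order.
#'
#' @param train_points,test_points n x 2 coordinate matrices.
#' @param train_labels,test_labels labels per point.
#' @param k number of neighbours (default 10).
#' @return fraction of test points whose prediction matches the true label.
#' @export
knn_accuracy <- function(train_points, train_labels, test_points,
                         test_labels, k = 10L) {
  train_points <- as.matrix(train_points)
  test_points <- as.matrix(test_points)
  if (nrow(test_points) == 0L) stop_bad("empty test set")
  if (k > nrow(train_points)) stop_bad("k exceeds number of training points")
  train_labels <- as.character(train_labels)
  pred <- knn_predict(train_points, train_labels, test_points, k)
  mean(pred == as.character(test_labels))
}

knn_predict <- function(train_points, train_labels, test_points, k) {
  # squared distances, all pairs: |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(test_points^2), rowSums(train_points^2), `+`) -
    2 * tcrossprod(test_points, train_points)
  vapply(seq_len(nrow(test_points)), function(i) {
    nn <- order(d2[i, ])[seq_len(k)]
    votes <- table(train_labels[nn])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl) {
        sum(d2[i, nn[train_labels[nn] == cl]])
      }, 0)
      top <- top[order(sums, top)]
    }
    top[1L]
  }, "")
}

#' Target centroids per label
#'
#' The per-label arithmetic mean of reference embedding coordinates; these
#' are the latent "targets" distances are measured against.
#'
#' @param points n x 2 matrix of latent coordinates of reference motions.
#' @param labels label per point; all six labels must be present.
#' @return a `centroid_set`: 6 x 2 matrix with labels as row names.
#' @export
compute_centroids <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  missing <- setdiff(motion_shapes(), unique(labels))
  if (length(missing) > 0L) {
    stop_bad("missing label(s) in reference embedding: %s",
             paste(missing, collapse = ", "))
  }
  ctr <- t(vapply(motion_shapes(), function(lab) {
    colMeans(points[labels == lab, , drop = FALSE])
  }, numeric(2L)))
  structure(ctr, class = c("centroid_set", class(ctr)))
}

#' Distances to target centroids, ordered as a reward sequence
#'
#' Computes each embedded test point's Euclidean distance to its own label's
#' centroid and orders the points into iterations t = 1..(schedule length x
#' noise copies) by ascending schedule index, noise replicates occupying
#' consecutive iterations.  One artificial dataset thus becomes a 60 x 6
#' reward matrix (iterations x labels) for one artificial subject.
#'
#' @param embedding list with `points` (n x 2), `labels`,
#'   `schedule_index`, `noise_index` (see [collect_fold()] /
#'   [embed_dataset()]).
#' @param centroids a [compute_centroids()] result.
#' @return a `reward_sequence`: T x 6 matrix, columns named by label.
#' @export
latent_distances <- function(embedding, centroids) {
  pts <- as.matrix(embedding$points)
  labels <- as.character(embedding$labels)
  sched <- embedding$schedule_index
  noise <- embedding$noise_index
  if (any(is.na(sched)) || any(is.na(noise))) {
    stop_bad("embedding lacks schedule/noise annotations")
  }
  dists <- unname(sqrt(rowSums((pts - centroids[labels, , drop = FALSE])^2)))
  labs <- motion_shapes()
  horizon <- length(unique(sched)) * length(unique(noise))
  out <- matrix(NA_real_, horizon, length(labs),
                dimnames = list(NULL, labs))
  for (lab in labs) {
    rows <- which(labels == lab)
    if (length(rows) == 0L) next
    ord <- rows[order(sched[rows], noise[rows])]
    if (length(ord) != horizon) {
      stop_bad("label %s has %d annotated points, expected %d", lab,
               length(ord), horizon)
    }
    out[, lab] <- dists[ord]
  }
  structure(out, class = c("reward_sequence", class(out)))
}

#' Embed one artificial dataset with its annotations
#'
#' Convenience wrapper: encodes a dataset's motions and carries the
#' schedule/noise annotations needed by [latent_distances()].
#'
#' @param trained a `trained_aae`.
#' @param items list of annotated motions (one artificial dataset).
#' @return list with `points`, `labels`, `schedule_index`, `noise_index`.
#' @export
embed_dataset <- function(trained, items) {
  fl <- flatten_motions(items)
  list(points = encode(trained, fl$X), labels = fl$labels,
       schedule_index = fl$schedule_index, noise_index = fl$noise_index)
}

#' Evaluate a trained embedding on one fold
#'
#' @param trained a `trained_aae`.
#' @param data a [collect_fold()] result.
#' @return list with `knn_accuracy` (test set against training embedding),
#'   `mean_kl` (test embedding against the prior), and `centroids` computed
#'   from the training embedding.
#' @export
evaluate_latent <- function(trained, data) {
  ztr <- encode(trained, data$train$X)
  zte <- encode(trained, data$test$X)
  acc <- knn_accuracy(ztr, data$train$labels, zte, data$test$labels, k = 10L)
  kl <- mean_cluster_kl(zte, data$test$labels, trained$mixture)
  cent <- compute_centroids(ztr, data$train$labels)
  list(knn_accuracy = acc, mean_kl = kl, centroids = cent)
}

#' Write reward sequences to CSV
#'
#' Long format `subject,label,t,distance`.
#'
#' @param rewards named list of `reward_sequence` matrices (names are
#'   subject identifiers), or a single matrix.
#' @param path output path.
#' @export
write_reward_csv <- function(rewards, path) {
  if (is.matrix(rewards)) rewards <- list(`1` = rewards)
  df <- do.call(rbind, lapply(names(rewards), function(s) {
    m <- rewards[[s]]
    data.frame(subject = s,
               label = rep(colnames(m), each = nrow(m)),
               t = rep(seq_len(nrow(m)), times = ncol(m)),
               distance = as.vector(m))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
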