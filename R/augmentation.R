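## Artificial-database construction.
##
## Starting from one source motion per label, variations are produced by
## scheduling three augmentation parameters -- horizontal stretch p_h,
## vertical stretch p_v and rotation theta -- from a randomly drawn starting
## value toward neutral (stretch ratio 1, rotation 0) over 20 steps, each
## step replicated 3 times with additive coordinate noise.  Seven database
## codes define which parameters depart from neutral and over which ranges.

## Table of augmentation ranges per database code.  Stretch entries are
## percentages of the original extent; rotation is in degrees.
.table1 <- list(
  X   = list(ph = c(10, 50),  pv = c(90, 100), theta = c(-5, 5)),
  Y   = list(ph = c(90, 100), pv = c(10, 50),  theta = c(-5, 5)),
  R   = list(ph = c(90, 100), pv = c(90, 100), theta = c(-45, 45)),
  XY  = list(ph = c(10, 50),  pv = c(10, 50),  theta = c(-5, 5)),
  XR  = list(ph = c(10, 50),  pv = c(90, 100), theta = c(-45, 45)),
  YR  = list(ph = c(90, 100), pv = c(10, 50),  theta = c(-45, 45)),
  XYR = list(ph = c(10, 50),  pv = c(10, 50),  theta = c(-45, 45))
)

#' The seven artificial-database codes
#' @return character vector `c("X","Y","R","XY","XR","YR","XYR")`.
#' @export
database_codes <- function() names(.table1)

#' Configuration of one artificial database
#'
#' Each database code fixes the sampling ranges for the starting values of
#' the three augmentation parameters; codes containing X vary the horizontal
#' stretch (start drawn in 10--50%), Y the vertical stretch, and R the
#' rotation (start in -45..45 degrees); parameters absent from the code stay
#' near neutral (90--100%, -5..5 degrees).
#'
#' @param code one of [database_codes()].
#' @param n_schedule schedule length per label set (default 20).
#' @param n_noise_copies noise replicates per schedule point (default 3).
#' @param noise_sigma coordinate-noise standard deviation as a fraction of
#'   the motion's bounding-box diagonal (default 0.02).
#' @param n_datasets datasets per database (default 20).
#' @param seed integer seed driving all random draws.
#' @return an `augmentation_config` object.
#' @export
augmentation_config <- function(code, n_schedule = 20L, n_noise_copies = 3L,
                                noise_sigma = 0.02, n_datasets = 20L,
                                seed = 1L) {
  code <- toupper(code)
  if (!code %in% database_codes()) {
    stop_bad("unknown database code '%s'; expected one of %s", code,
             paste(database_codes(), collapse = ", "))
  }
  stopifnot(n_schedule >= 2L, n_noise_copies >= 1L, noise_sigma >= 0,
            n_datasets >= 1L)
  structure(c(list(code = code), .table1[[code]],
              list(n_schedule = as.integer(n_schedule),
                   n_noise_copies = as.integer(n_noise_copies),
                   noise_sigma = noise_sigma,
                   n_datasets = as.integer(n_datasets),
                   seed = as.integer(seed))),
            class = "augmentation_config")
}

#' Sample a monotone parameter schedule
#'
#' Produces `n` ordered values from `start_value` to `end_value`.  The
#' `linear` behavior is an arithmetic progression; `random_staircase` is a
#' monotone piecewise-constant sequence whose plateau values are taken from
#' the linear progression at randomly drawn change points, ending exactly at
#' `end_value`.
#'
#' @param start_value,end_value schedule endpoints.
#' @param n schedule length (>= 2).
#' @param behavior `"linear"` or `"random_staircase"`.
#' @param seed optional seed for the staircase draw.
#' @return numeric vector of length `n`.
#' @export
sample_schedule <- function(start_value, end_value, n = 20L,
                            behavior = c("linear", "random_staircase"),
                            seed = NULL) {
  behavior <- match.arg(behavior)
  if (n < 2L) stop_bad("schedule length must be >= 2")
  lin <- seq(start_value, end_value, length.out = n)
  if (behavior == "linear") return(lin)
  with_seed(seed, {
    k <- sample(2:min(10L, n), 1L)                 # number of plateaus
    cuts <- sort(sample(seq_len(n - 1L), k - 1L))  # plateau boundaries
    starts <- c(1L, cuts + 1L)
    lens <- diff(c(starts, n + 1L))
    vals <- lin[starts]
    vals[1L] <- start_value
    vals[k] <- end_value
    rep(vals, times = lens)
  })
}

#' Stretch and rotate a trajectory about its centroid
#'
#' Scales x-coordinates by `ratio_h` and y-coordinates by `ratio_v`, then
#' rotates by `theta_deg` degrees (counter-clockwise), all relative to the
#' trajectory centroid, which is left unchanged.
#'
#' @param points n x 2 numeric matrix.
#' @param ratio_h,ratio_v positive stretch ratios.
#' @param theta_deg rotation angle in degrees.
#' @return transformed n x 2 matrix.
#' @export
apply_transform <- function(points, ratio_h, ratio_v, theta_deg) {
  check_finite_matrix(points)
  if (ratio_h <= 0 || ratio_v <= 0) stop_bad("stretch ratios must be > 0")
  ctr <- colMeans(points)
  p <- sweep(points, 2L, ctr)
  p[, 1L] <- p[, 1L] * ratio_h
  p[, 2L] <- p[, 2L] * ratio_v
  th <- theta_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(p %*% t(rot), 2L, ctr, `+`)
}

#' Build the 60-item artificial set for one label
#'
#' Draws starting values p_h, p_v, theta uniformly from the config ranges
#' and a schedule behavior (linear or random staircase) independently per
#' parameter, builds `n_schedule` transformed copies of the source motion
#' along the joint schedule (index 0 farthest from neutral, last index
#' neutral), then emits `n_noise_copies` replicates of each with additive
#' Gaussian coordinate noise.
#'
#' @param source_motion a motion list with `points` and `label`.
#' @param config an [augmentation_config()].
#' @param seed seed for this label set's draws.
#' @return list of annotated motions; each carries `schedule_index` (0-based),
#'   `noise_index` (0-based), and the applied `ph`, `pv`, `theta`.
#' @export
build_label_set <- function(source_motion, config, seed = NULL) {
  stopifnot(inherits(config, "augmentation_config"))
  pts <- source_motion$points
  check_finite_matrix(pts, "source motion points")
  with_seed(seed, {
    start_ph <- stats::runif(1, config$ph[1L], config$ph[2L]) / 100
    start_pv <- stats::runif(1, config$pv[1L], config$pv[2L]) / 100
    start_th <- stats::runif(1, config$theta[1L], config$theta[2L])
    behaviors <- sample(c("linear", "random_staircase"), 3L, replace = TRUE)
    n <- config$n_schedule
    sch_ph <- sample_schedule(start_ph, 1, n, behaviors[1L])
    sch_pv <- sample_schedule(start_pv, 1, n, behaviors[2L])
    sch_th <- sample_schedule(start_th, 0, n, behaviors[3L])
    out <- vector("list", n * config$n_noise_copies)
    pos <- 0L
    for (i in seq_len(n)) {
      base <- apply_transform(pts, sch_ph[i], sch_pv[i], sch_th[i])
      sd <- config$noise_sigma * bbox_diagonal(base)
      for (j in seq_len(config$n_noise_copies)) {
        noisy <- base
        if (sd > 0) {
          noisy <- noisy + matrix(stats::rnorm(length(base), 0, sd), ncol = 2L)
        }
        pos <- pos + 1L
        out[[pos]] <- list(points = noisy, label = source_motion$label,
                           schedule_index = i - 1L, noise_index = j - 1L,
                           ph = sch_ph[i], pv = sch_pv[i], theta = sch_th[i])
      }
    }
    out
  })
}

#' Build an artificial database of 20 datasets
#'
#' For each of `config$n_datasets` repetitions, selects one source motion
#' per label at random from the supplied pool (fresh draw per dataset) and
#' builds its 60-item label set, yielding datasets of `60 x n_labels` items.
#'
#' @param motions a `motion_set` containing at least one motion per label.
#' @param config an [augmentation_config()].
#' @return an `artificial_database`: list with `datasets` (each a list of
#'   annotated motions), `config`, and (after [split_database()]) `split`.
#' @export
build_database <- function(motions, config) {
  stopifnot(inherits(config, "augmentation_config"))
  labels <- motion_shapes()
  pool <- split(seq_along(motions), vapply(motions, `[[`, "", "label"))
  missing <- setdiff(labels, names(pool))
  if (length(missing) > 0L) {
    stop_bad("no source motion available for label(s): %s",
             paste(missing, collapse = ", "))
  }
  datasets <- with_seed(config$seed, {
    lapply(seq_len(config$n_datasets), function(i) {
      items <- list()
      for (lab in labels) {
        src <- motions[[sample(pool[[lab]], 1L)]]
        set_seed_i <- sample.int(2^31 - 2L, 1L)
        items <- c(items, build_label_set(src, config, seed = set_seed_i))
      }
      items
    })
  })
  structure(list(datasets = datasets, config = config, split = NULL),
            class = "artificial_database")
}

#' @export
print.artificial_database <- function(x, ...) {
  cat(sprintf("<artificial_database> code %s: %d datasets x %d items\n",
              x$config$code, length(x$datasets),
              length(x$datasets[[1L]])))
  if (!is.null(x$split)) cat("  split: assigned\n")
  invisible(x)
}

#' Assign train/validation/test structure to a database
#'
#' Randomly reserves 3 datasets for testing; from the remaining 17, forms a
#' 15-dataset cross-validation pool partitioned into 5 folds of 3 validation
#' datasets each (so every fold trains on 12 and validates on 3), leaving 2
#' datasets unused.
#'
#' @param database an `artificial_database` with 20 datasets.
#' @param seed seed for the random assignment.
#' @return the database with a `split` element: `test` (3 indices),
#'   `folds` (list of 5, each with `train` and `validation` indices),
#'   `unused` (2 indices).
#' @export
split_database <- function(database, seed = 1L) {
  stopifnot(inherits(database, "artificial_database"))
  n <- length(database$datasets)
  if (n != 20L) stop_bad("split expects a 20-dataset database, got %d", n)
  split <- with_seed(seed, {
    idx <- sample.int(n)
    test <- sort(idx[1:3])
    pool <- idx[4:18]
    unused <- sort(idx[19:20])
    folds <- lapply(1:5, function(k) {
      val <- sort(pool[(3 * k - 2):(3 * k)])
      list(train = sort(setdiff(pool, val)), validation = val)
    })
    list(test = test, folds = folds, unused = unused,
         cv_pool = sort(pool), seed = as.integer(seed))
  })
  database$split <- split
  database
}

## ---- archive ---------------------------------------------------------------

dataset_to_df <- function(items) {
  do.call(rbind, lapply(items, function(m) {
    data.frame(label = m$label, point_index = seq_len(nrow(m$points)),
               x = m$points[, 1L], y = m$points[, 2L],
               schedule_index = m$schedule_index, noise_index = m$noise_index,
               ph = m$ph, pv = m$pv, theta = m$theta)
  }))
}

df_to_dataset <- function(df) {
  key <- interaction(df$label, df$schedule_index, df$noise_index, drop = TRUE)
  items <- lapply(split(df, key), function(d) {
    d <- d[order(d$point_index), ]
    list(points = cbind(d$x, d$y), label = as.character(d$label[1L]),
         schedule_index = d$schedule_index[1L], noise_index = d$noise_index[1L],
         ph = d$ph[1L], pv = d$pv[1L], theta = d$theta[1L])
  })
  names(items) <- NULL
  items
}

#' Write a database to a directory of CSV files plus a manifest
#'
#' Creates `dataset_00.csv` ... under `dir`, one per artificial dataset,
#' and a `manifest.json` echoing the configuration and split.
#'
#' @param database an `artificial_database`.
#' @param dir output directory (created if absent).
#' @export
write_database <- function(database, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(database$datasets)) {
    f <- file.path(dir, sprintf("dataset_%02d.csv", i - 1L))
    utils::write.csv(dataset_to_df(database$datasets[[i]]), f,
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }
  manifest <- list(config = unclass(database$config), split = database$split)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a database written by [write_database()]
#' @param dir directory path.
#' @return an `artificial_database`.
#' @export
read_database <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(augmentation_config,
                 manifest$config[c("code", "n_schedule", "n_noise_copies",
                                   "noise_sigma", "n_datasets", "seed")])
  files <- sort(list.files(dir, pattern = "^dataset_\\d+\\.csv$",
                           full.names = TRUE))
  datasets <- lapply(files, function(f) {
    df_to_dataset(utils::read.csv(f, fileEncoding = "UTF-8"))
  })
  split <- manifest$split
  if (!is.null(split) && !is.null(split$folds)) {
    if (is.data.frame(split$folds)) {
      split$folds <- lapply(seq_len(nrow(split$folds)), function(i) {
        list(train = split$folds$train[[i]],
             validation = split$folds$validation[[i]])
      })
    }
  }
  structure(list(datasets = datasets, config = cfg, split = split),
            class = "artificial_database")
}
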