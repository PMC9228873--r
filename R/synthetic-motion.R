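## Synthetic hand-motion trajectories.
##
## Six reference shapes drawn in the frontal plane with a hand-held
## controller; each recorded movement is resampled to a fixed 32-point
## polyline.  The templates here are parametric silhouettes (square,
## rectangle, heart curve, lemniscate, circle, equilateral triangle)
## standing in for recorded volunteer motions: the downstream embedding and
## bandit machinery only needs six distinguishable planar classes.

#' The six permitted motion class labels
#'
#' @return character vector of the six shape labels, in canonical order.
#' @export
motion_shapes <- function() {
  c("Cube", "Cylinder", "Heart", "Infinity", "Sphere", "Triangle")
}

#' Number of points every motion matrix carries
#' @export
motion_n_points <- function() 32L

## ideal (jitter-free) parametric silhouette, n points, closed curves
## traced once.  Centered at the centroid and scaled so the longest
## bounding-box side is 1.
shape_curve <- function(label, n) {
  # open parametrisation: the duplicate closing point is omitted so sampled
  # closed curves have uniform gaps throughout
  t <- (seq_len(n) - 1L) / n
  pts <- switch(label,
    Cube = walk_polygon(rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1)), n),
    Cylinder = walk_polygon(rbind(c(-0.5, -1), c(0.5, -1),
                                  c(0.5, 1), c(-0.5, 1)), n),
    Heart = {
      th <- 2 * pi * t
      cbind(16 * sin(th)^3,
            13 * cos(th) - 5 * cos(2 * th) - 2 * cos(3 * th) - cos(4 * th))
    },
    Infinity = {
      th <- 2 * pi * t
      cbind(cos(th), sin(th) * cos(th))  # lemniscate of Gerono
    },
    Sphere = {
      th <- 2 * pi * t
      cbind(cos(th), sin(th))
    },
    Triangle = {
      a <- 2 * pi * (0:2) / 3 + pi / 2
      walk_polygon(cbind(cos(a), sin(a)), n)
    },
    stop_bad("unknown motion label '%s'; expected one of %s",
             label, paste(motion_shapes(), collapse = ", "))
  )
  normalize_points(pts)
}

## n points around a closed polygon, vertices included exactly, remaining
## points spread along the edges proportionally to edge length
walk_polygon <- function(vertices, n) {
  V <- nrow(vertices)
  closed <- rbind(vertices, vertices[1L, , drop = FALSE])
  lens <- sqrt(rowSums(diff(closed)^2))
  # points per edge (each edge owns its starting vertex)
  counts <- pmax(1L, round(n * lens / sum(lens)))
  while (sum(counts) > n) counts[which.max(counts)] <-
      counts[which.max(counts)] - 1L
  while (sum(counts) < n) counts[which.min(counts)] <-
      counts[which.min(counts)] + 1L
  do.call(rbind, lapply(seq_len(V), function(e) {
    a <- closed[e, ]
    b <- closed[e + 1L, ]
    t <- seq(0, 1, length.out = counts[e] + 1L)[seq_len(counts[e])]
    cbind(a[1L] + t * (b[1L] - a[1L]), a[2L] + t * (b[2L] - a[2L]))
  }))
}

## center at centroid, scale longest bounding-box side to 1
normalize_points <- function(pts) {
  pts <- sweep(pts, 2L, colMeans(pts))
  side <- max(diff(range(pts[, 1L])), diff(range(pts[, 2L])))
  if (side > 0) pts <- pts / side
  pts
}

#' Generate a raw template polyline for one motion class
#'
#' Produces a planar silhouette of the named shape, centred at its centroid
#' and scaled so the longest bounding-box side is 1, with optional Gaussian
#' jitter emulating inter-trial human variability.
#'
#' @param label one of [motion_shapes()].
#' @param n_points number of raw polyline points (>= 32).
#' @param jitter standard deviation of per-point Gaussian jitter, as a
#'   fraction of the bounding-box diagonal.  Default 0.02.
#' @param seed optional integer seed for the jitter draw.
#' @return an `n_points` x 2 numeric matrix.
#' @export
generate_template <- function(label, n_points = 128L, jitter = 0.02,
                              seed = NULL) {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% motion_shapes())) {
    stop_bad("unknown motion label '%s'; expected one of %s",
             paste(label, collapse = "/"),
             paste(motion_shapes(), collapse = ", "))
  }
  if (n_points < 32L) stop_bad("n_points must be >= 32")
  pts <- shape_curve(label, n_points)
  if (jitter > 0) {
    sd <- jitter * bbox_diagonal(pts)
    pts <- pts + with_seed(seed, matrix(stats::rnorm(length(pts), 0, sd),
                                        ncol = 2L))
  }
  pts
}

#' Resample a polyline to m points uniform in arc length
#'
#' The first and last input points are preserved; intermediate points are
#' placed at equal increments of cumulative arc length along the input,
#' mirroring the resampling step of point-cloud gesture recognizers.  On an
#' input whose points are already uniformly spaced (equal consecutive
#' gaps) the operation reproduces the input exactly.
#'
#' @param polyline an n x 2 numeric matrix, n >= 2, finite coordinates.
#' @param m number of output points (>= 2); defaults to 32.
#' @return an m x 2 matrix.
#' @export
resample_trajectory <- function(polyline, m = motion_n_points()) {
  check_finite_matrix(polyline, "polyline")
  if (nrow(polyline) < 2L) stop_bad("polyline needs at least 2 points")
  if (m < 2L) stop_bad("m must be >= 2")
  seg <- sqrt(rowSums(diff(polyline)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop_bad("polyline has zero total path length")
  target <- seq(0, total, length.out = m)
  out <- matrix(0, m, 2L)
  # findInterval on the cumulative lengths; duplicate vertices collapse into
  # zero-length segments which the interpolation skips naturally
  idx <- findInterval(target, s, rightmost.closed = TRUE)
  idx[idx >= length(s)] <- length(s) - 1L
  for (j in 1:2) {
    frac <- (target - s[idx]) / pmax(s[idx + 1L] - s[idx], .Machine$double.xmin)
    out[, j] <- polyline[idx, j] + frac * (polyline[idx + 1L, j] -
                                             polyline[idx, j])
  }
  out[1L, ] <- polyline[1L, ]
  out[m, ] <- polyline[nrow(polyline), ]
  out
}

#' Protocol specification for emulated motion collection
#'
#' Describes the collection protocol: each participant draws each of the six
#' shapes three times per session over three sessions, giving
#' 10 x 6 x 3 x 3 = 540 motions by default.
#'
#' @param n_participants number of participants (default 10).
#' @param n_labels number of motion classes used, between 1 and 6 (default 6).
#' @param reps_per_session repetitions of each motion per session (default 3).
#' @param n_sessions number of sessions (default 3).
#' @param jitter per-trial jitter fraction passed to [generate_template()].
#' @param participant_sd standard deviation of the per-participant style
#'   perturbation (consistent within a participant).
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(n_participants = 10L, n_labels = 6L,
                          reps_per_session = 3L, n_sessions = 3L,
                          jitter = 0.02, participant_sd = 0.03) {
  for (v in c(n_participants, n_labels, reps_per_session, n_sessions)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      stop_bad("protocol counts must be positive integers")
    }
  }
  if (n_labels > 6L) stop_bad("at most 6 motion labels are defined")
  structure(list(n_participants = as.integer(n_participants),
                 n_labels = as.integer(n_labels),
                 reps_per_session = as.integer(reps_per_session),
                 n_sessions = as.integer(n_sessions),
                 jitter = jitter, participant_sd = participant_sd),
            class = "protocol_spec")
}

#' Emulate the motion-collection protocol
#'
#' Generates `n_participants x n_labels x reps_per_session x n_sessions`
#' motion matrices.  Each participant carries a consistent random "style"
#' (small affine perturbation of the templates) on top of per-trial jitter,
#' so that within-participant trials resemble each other more than
#' across-participant trials.
#'
#' @param spec a [protocol_spec()].
#' @param seed integer seed driving all randomness.
#' @return a `motion_set`: list of motions, each a list with `points`
#'   (32 x 2 matrix), `label`, `participant`, `session`, `repetition`.
#' @export
emulate_protocol <- function(spec = protocol_spec(), seed = 1L) {
  stopifnot(inherits(spec, "protocol_spec"))
  labels <- motion_shapes()[seq_len(spec$n_labels)]
  motions <- list()
  with_seed(seed, {
    for (p in seq_len(spec$n_participants)) {
      # participant style: slight anisotropic scale + rotation, fixed per
      # participant across sessions
      style_sx <- 1 + stats::rnorm(1, 0, spec$participant_sd)
      style_sy <- 1 + stats::rnorm(1, 0, spec$participant_sd)
      style_th <- stats::rnorm(1, 0, 3)  # degrees
      for (s in seq_len(spec$n_sessions)) {
        for (lab in labels) {
          for (r in seq_len(spec$reps_per_session)) {
            raw <- generate_template(lab, 128L, jitter = spec$jitter)
            raw <- apply_transform(raw, style_sx, style_sy, style_th)
            motions[[length(motions) + 1L]] <- list(
              points = resample_trajectory(raw, motion_n_points()),
              label = lab, participant = p, session = s, repetition = r)
          }
        }
      }
    }
  })
  structure(motions, class = "motion_set")
}

#' @export
print.motion_set <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<motion_set> %d motions, %d labels (%s)\n",
              length(x), length(unique(labs)),
              paste(unique(labs), collapse = ", ")))
  invisible(x)
}

## ---- serialization ---------------------------------------------------------

#' Write a motion set to CSV
#'
#' Long format, one row per point:
#' `participant,session,repetition,label,point_index,x,y`.
#'
#' @param motions a `motion_set`.
#' @param path output file path.
#' @export
write_motion_csv <- function(motions, path) {
  df <- motion_set_to_df(motions)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

motion_set_to_df <- function(motions) {
  do.call(rbind, lapply(motions, function(m) {
    data.frame(participant = m$participant %||% NA_integer_,
               session = m$session %||% NA_integer_,
               repetition = m$repetition %||% NA_integer_,
               label = m$label,
               point_index = seq_len(nrow(m$points)),
               x = m$points[, 1L], y = m$points[, 2L])
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a motion set from CSV written by [write_motion_csv()]
#' @param path CSV path.
#' @return a `motion_set`.
#' @export
read_motion_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("label", "point_index", "x", "y")
  if (!all(need %in% names(df))) {
    stop_bad("motion CSV must have columns %s", paste(need, collapse = ","))
  }
  key <- interaction(df$participant %||% 0, df$session %||% 0,
                     df$repetition %||% 0, df$label, drop = TRUE)
  motions <- lapply(split(df, key), function(d) {
    d <- d[order(d$point_index), ]
    list(points = cbind(d$x, d$y), label = as.character(d$label[1L]),
         participant = d$participant[1L], session = d$session[1L],
         repetition = d$repetition[1L])
  })
  names(motions) <- NULL
  structure(motions, class = "motion_set")
}

#' Write a motion set to JSON
#' @param motions a `motion_set`.
#' @param path output path.
#' @export
write_motion_json <- function(motions, path) {
  recs <- lapply(motions, function(m) {
    list(label = m$label,
         points = unname(apply(m$points, 1L, function(r) r, simplify = FALSE)),
         meta = list(participant = m$participant, session = m$session,
                     repetition = m$repetition))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a motion set from JSON written by [write_motion_json()]
#' @param path JSON path.
#' @return a `motion_set`.
#' @export
read_motion_json <- function(path) {
  recs <- jsonlite::read_json(path)
  motions <- lapply(recs, function(r) {
    pts <- do.call(rbind, lapply(r$points, function(p) unlist(p)))
    list(points = pts, label = r$label,
         participant = r$meta$participant %||% NA_integer_,
         session = r$meta$session %||% NA_integer_,
         repetition = r$meta$repetition %||% NA_integer_)
  })
  structure(motions, class = "motion_set")
}

#' Reader stub for the publicly deposited motion dataset
#'
#' The deposited capture data (Mendeley accession 10.17632/kbbprxr4nw.1) has
#' no documented on-disk layout; this adapter only validates that a local
#' copy exists and directs the user to convert it to the motion CSV schema.
#'
#' @param path path to a local copy of the deposit.
#' @export
read_mendeley_motions <- function(path) {
  if (!file.exists(path)) stop_bad("no file at '%s'", path)
  stop_bad(paste0("the deposit's on-disk layout is not standardized; ",
                  "convert it to the motion CSV schema and use ",
                  "read_motion_csv()"))
}
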