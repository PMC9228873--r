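# Schedules, stretch/rotation transforms and artificial-database assembly.

test_that("linear schedules are arithmetic progressions", {
  s <- sample_schedule(0.1, 1.0, 20L, "linear")
  expect_equal(s, 0.1 + (0:19) * 0.9 / 19, tolerance = 1e-12)
  expect_equal(sample_schedule(1, 1, 20L, "linear"), rep(1, 20L))
})

test_that("random staircases are monotone with matching endpoints", {
  s <- sample_schedule(-45, 0, 20L, "random_staircase", seed = 7L)
  expect_length(s, 20L)
  expect_identical(s[1L], -45)
  expect_identical(s[20L], 0)
  expect_true(all(diff(s) >= 0))
  expect_lte(length(unique(s)), 19L)
  # decreasing direction too
  s2 <- sample_schedule(1.6, 1.0, 20L, "random_staircase", seed = 3L)
  expect_true(all(diff(s2) <= 0))
  expect_identical(range(s2), c(1.0, 1.6))
})

test_that("transforms stretch and rotate about the centroid", {
  pts <- generate_template("Heart", 64L, jitter = 0)
  expect_equal(apply_transform(pts, 1, 1, 0), pts)

  sq <- rbind(c(-0.5, -0.5), c(0.5, -0.5), c(0.5, 0.5), c(-0.5, 0.5))
  half <- apply_transform(sq, 0.5, 1, 0)
  expect_equal(diff(range(half[, 1L])), 0.5)
  expect_equal(diff(range(half[, 2L])), 1)

  rot <- apply_transform(rbind(c(1, 0), c(-1, 0)), 1, 1, 90)
  expect_equal(rot, rbind(c(0, 1), c(0, -1)), tolerance = 1e-12)

  expect_error(apply_transform(sq, 0, 1, 0), "> 0")
})

test_that("a transform composed with its inverse recovers the input", {
  set.seed(11)
  for (i in 1:10) {
    pts <- matrix(stats::rnorm(40), ncol = 2L)
    rh <- stats::runif(1, 0.2, 2)
    rv <- stats::runif(1, 0.2, 2)
    th <- stats::runif(1, -180, 180)
    fwd <- apply_transform(pts, rh, rv, th)
    # undo the rotation first, then the stretch
    und <- apply_transform(apply_transform(fwd, 1, 1, -th), 1 / rh, 1 / rv, 0)
    expect_equal(und, pts, tolerance = 1e-9)
  }
})

test_that("label sets hold 60 annotated matrices ending at the source", {
  pool <- fixture_pool()
  src <- pool[[which(vapply(pool, `[[`, "", "label") == "Cube")[1L]]]
  for (code in c("X", "R", "XYR")) {
    cfg <- augmentation_config(code, noise_sigma = 0)
    ls <- build_label_set(src, cfg, seed = 21L)
    expect_length(ls, 60L)
    # zero noise: the three replicates of a schedule point are identical
    expect_equal(ls[[1L]]$points, ls[[2L]]$points)
    expect_equal(ls[[2L]]$points, ls[[3L]]$points)
    # last schedule entry is at neutral parameters: the source itself
    last <- ls[[60L]]
    expect_equal(last$schedule_index, 19L)
    expect_equal(c(last$ph, last$pv, last$theta), c(1, 1, 0))
    expect_equal(last$points, src$points, tolerance = 1e-9)
    # schedule annotations run monotonically toward neutral
    ph <- vapply(ls, `[[`, 0, "ph")
    th <- vapply(ls, `[[`, 0, "theta")
    expect_true(all(diff(abs(ph - 1)) <= 1e-12))
    expect_true(all(diff(abs(th)) <= 1e-12))
  }
})

test_that("databases hold 20 datasets of 360 items for every code", {
  db <- fixture_xyr_db()
  expect_length(db$datasets, 20L)
  for (d in db$datasets[c(1L, 20L)]) {
    expect_length(d, 360L)
    labs <- vapply(d, `[[`, "", "label")
    expect_equal(unname(table(labs)), rep(60L, 6L), ignore_attr = TRUE)
  }
  # every Table-1 code builds, and drawn starting values honour its ranges
  pool <- fixture_pool()
  for (code in database_codes()) {
    cfg <- augmentation_config(code, n_datasets = 2L, seed = 31L)
    db2 <- build_database(pool, cfg)
    expect_length(db2$datasets, 2L)
    starts <- lapply(db2$datasets, function(d) {
      first <- d[vapply(d, function(m) m$schedule_index == 0L, TRUE)]
      list(ph = vapply(first, `[[`, 0, "ph"),
           pv = vapply(first, `[[`, 0, "pv"),
           th = vapply(first, `[[`, 0, "theta"))
    })
    for (st in starts) {
      expect_true(all(st$ph >= cfg$ph[1L] / 100 - 1e-12 &
                        st$ph <= cfg$ph[2L] / 100 + 1e-12))
      expect_true(all(st$pv >= cfg$pv[1L] / 100 - 1e-12 &
                        st$pv <= cfg$pv[2L] / 100 + 1e-12))
      expect_true(all(st$th >= cfg$theta[1L] - 1e-9 &
                        st$th <= cfg$theta[2L] + 1e-9))
    }
  }
  expect_error(augmentation_config("Q"), "unknown database code")
})

test_that("database construction is deterministic under a fixed seed", {
  pool <- fixture_pool()
  cfg <- augmentation_config("X", n_datasets = 3L, seed = 77L)
  a <- build_database(pool, cfg)
  b <- build_database(pool, cfg)
  expect_identical(a$datasets, b$datasets)
})

test_that("a missing label is rejected by name", {
  pool <- fixture_pool()
  no_heart <- structure(Filter(function(m) m$label != "Heart", pool),
                        class = "motion_set")
  expect_error(build_database(no_heart, augmentation_config("X")), "Heart")
})

test_that("the split yields 3 test datasets and 5 folds of 12/3", {
  for (seed in c(1L, 99L, 2024L)) {
    db <- split_database(fixture_xyr_db(), seed = seed)
    sp <- db$split
    expect_length(sp$test, 3L)
    expect_length(sp$folds, 5L)
    expect_length(sp$unused, 2L)
    vals <- integer()
    for (f in sp$folds) {
      expect_length(f$train, 12L)
      expect_length(f$validation, 3L)
      expect_length(intersect(f$train, f$validation), 0L)
      expect_setequal(c(f$train, f$validation), sp$cv_pool)
      vals <- c(vals, f$validation)
    }
    # fold validation sets partition the CV pool
    expect_setequal(vals, sp$cv_pool)
    expect_length(vals, 15L)
    # test/pool/unused are disjoint and cover all 20
    expect_setequal(c(sp$test, sp$cv_pool, sp$unused), 1:20)
  }
})

test_that("database archives round-trip through CSV", {
  pool <- fixture_pool()
  cfg <- augmentation_config("Y", n_datasets = 2L, seed = 13L)
  db <- build_database(pool, cfg)
  dir <- withr::local_tempdir()
  write_database(db, dir)
  expect_true(file.exists(file.path(dir, "dataset_00.csv")))
  back <- read_database(dir)
  expect_length(back$datasets, 2L)
  key <- function(d) {
    ord <- order(vapply(d, `[[`, "", "label"),
                 vapply(d, `[[`, 0L, "schedule_index"),
                 vapply(d, `[[`, 0L, "noise_index"))
    lapply(d[ord], function(m) round(unname(m$points), 8))
  }
  expect_equal(key(back$datasets[[1L]]), key(db$datasets[[1L]]))
})
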