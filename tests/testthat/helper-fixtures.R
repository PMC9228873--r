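# Shared fixtures, built once per test run and memoised.  All randomness is
# seeded so the suite is reproducible.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# single participant's emulated collection (54 motions): the augmentation
# source pool
fixture_pool <- function() {
  memo("pool", function() {
    emulate_protocol(protocol_spec(n_participants = 1L), seed = 401L)
  })
}

# full emulated cohort (540 motions), for centroid references
fixture_cohort <- function() {
  memo("cohort", function() emulate_protocol(seed = 402L))
}

# split code-XYR database shared by augmentation/aae/latent tests
fixture_xyr_db <- function() {
  memo("xyr_db", function() {
    db <- build_database(fixture_pool(), augmentation_config("XYR", seed = 403L))
    split_database(db, seed = 404L)
  })
}

fixture_fold <- function() {
  memo("xyr_fold", function() collect_fold(fixture_xyr_db(), 1L))
}

# a small trained semi-supervised model for latent/pipeline tests (short
# budget: enough for a usable embedding, not a converged one)
fixture_ssaae <- function() {
  memo("ssaae", function() {
    train_aae(fixture_fold(),
              aae_config(mode = "semi_supervised", max_epochs = 12L,
                         patience = 12L, seed = 405L),
              prior_mixture())
  })
}

# independent oracle: cumulative arc-length position of each point of `pts`
# along the polyline `poly` (the points are assumed to lie on the path);
# scans segments in order, keeping progression monotone
arc_positions <- function(poly, pts) {
  seg <- sqrt(rowSums(diff(poly)^2))
  s0 <- c(0, cumsum(seg))
  last <- -1e-12
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    best <- NA_real_
    for (j in seq_len(nrow(poly) - 1L)) {
      a <- poly[j, ]
      d <- poly[j + 1L, ] - a
      dd <- sum(d^2)
      if (dd == 0) next
      t <- max(0, min(1, sum((p - a) * d) / dd))
      gap <- sqrt(sum((a + t * d - p)^2))
      pos <- s0[j] + t * sqrt(dd)
      if (gap < 1e-8 && pos >= last - 1e-9 && (is.na(best) || pos < best)) {
        best <- pos
      }
    }
    last <<- best
    best
  }, 0)
}

# brute-force k-NN with the package's tie-break rule (smallest summed
# squared distance among tied classes, then label order)
knn_oracle <- function(trp, trl, tep, tel, k) {
  correct <- 0L
  for (i in seq_len(nrow(tep))) {
    d <- sqrt(colSums((t(trp) - tep[i, ])^2))
    nn <- order(d)[1:k]
    tab <- table(trl[nn])
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1L) {
      sums <- sapply(cand, function(cl) sum(d[nn[trl[nn] == cl]]^2))
      cand <- cand[order(sums, cand)]
    }
    if (cand[1L] == tel[i]) correct <- correct + 1L
  }
  correct / nrow(tep)
}

expect_prob_vector <- function(p) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-9)
}
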