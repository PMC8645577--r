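# GFP, peak detection, modified K-means, GEV, canonical ordering.

avg_ref_epochs <- function(cols_list, srate = 500) {
  es <- ms_epochs(cols_list, srate = srate,
                  epoch_seconds = ncol(cols_list[[1]]) / srate)
  average_reference(es)
}

test_that("GFP matches its closed form and the brute-force formula", {
  es <- avg_ref_epochs(list(matrix(c(1, -1), 2, 1000)))
  g <- compute_gfp(es)
  expect_equal(g$values[[1]][1], 1)

  es0 <- avg_ref_epochs(list(matrix(0, 2, 1000)))
  expect_equal(compute_gfp(es0)$values[[1]][5], 0)

  set.seed(21)
  m <- matrix(rnorm(64 * 1000), 64, 1000)
  es2 <- avg_ref_epochs(list(m))
  g2 <- compute_gfp(es2)
  for (t in c(1, 17, 500)) {
    expect_equal(g2$values[[1]][t], oracle_gfp(m[, t]), tolerance = 1e-12)
  }
  # invariant to adding a constant to all channels at a time point
  m2 <- m + 7.3
  g3 <- compute_gfp(avg_ref_epochs(list(m2)))
  expect_equal(g3$values, g2$values, tolerance = 1e-10)
})

test_that("non-average-referenced input triggers a contract warning", {
  es <- ms_epochs(list(matrix(rnorm(2000), 2, 1000)), srate = 500,
                  epoch_seconds = 2)
  expect_warning(compute_gfp(es), "average-referenced")
})

test_that("GFP peaks are strict interior local maxima", {
  g <- structure(list(values = list(c(0, 1, 0, 2, 0)), peaks = list(NULL),
                      srate = 5), class = "ms_gfp")
  expect_equal(find_gfp_peaks(g)$peaks[[1]], c(2L, 4L))

  ramp <- structure(list(values = list(1:50 / 10), peaks = list(NULL),
                         srate = 50), class = "ms_gfp")
  expect_length(find_gfp_peaks(ramp)$peaks[[1]], 0L)

  # 10 Hz GFP oscillation at 500 Hz over 2 s: 20 +/- 1 maxima
  t <- (0:999) / 500
  osc <- structure(list(values = list(1 + 0.5 * sin(2 * pi * 10 * t + 0.3)),
                        peaks = list(NULL), srate = 500), class = "ms_gfp")
  np <- length(find_gfp_peaks(osc)$peaks[[1]])
  expect_true(abs(np - 20) <= 1)

  short <- structure(list(values = list(c(1, 2)), peaks = list(NULL),
                          srate = 500), class = "ms_gfp")
  expect_error(find_gfp_peaks(short), "too short")

  # min_separation keeps the larger of two close peaks
  g2 <- structure(list(values = list(c(0, 3, 2.9, 4, 0, 0, 1, 0)),
                       peaks = list(NULL), srate = 500), class = "ms_gfp")
  expect_equal(find_gfp_peaks(g2, min_separation = 3)$peaks[[1]], c(4L, 7L))
})

test_that("noise-free template copies are recovered exactly, polarity ignored", {
  tm <- make_templates()
  x <- tm$maps[rep(1:4, each = 25), ]
  signs <- rep(c(1, -1), 50)
  xs <- x * signs
  fit <- modified_kmeans(xs, k = 4, n_restarts = 5, seed = 3)
  m <- order_maps_canonical(fit, tm)
  expect_equal(unname(diag(abs(m$maps %*% t(tm$maps)))), rep(1, 4),
               tolerance = 1e-9)
  expect_equal(fit$gev, 1, tolerance = 1e-9)

  # flipping polarity of any subset leaves the fit identical
  fit2 <- modified_kmeans(x, k = 4, n_restarts = 5, seed = 3)
  expect_equal(fit$maps, fit2$maps, tolerance = 1e-12)
})

test_that("templates are recovered from noisy peak maps at generator SNR", {
  tm <- make_templates()
  sm <- sample_noisy_maps(tm, 200, snr = 4, seed = 11)
  fit <- modified_kmeans(sm$maps, k = 4, seed = 5)
  m <- order_maps_canonical(fit, tm)
  expect_true(all(diag(abs(m$maps %*% t(tm$maps))) >= 0.95))
})

test_that("the clustering objective is non-decreasing over iterations", {
  tm <- make_templates()
  for (seed in 1:3) {
    sm <- sample_noisy_maps(tm, 150, snr = 2, seed = seed)
    fit <- modified_kmeans(sm$maps, k = 4, n_restarts = 1, seed = seed)
    trace <- fit$provenance$gev_trace
    expect_true(all(diff(trace) >= -1e-12))
  }
})

test_that("templates and GEV are invariant to positive rescaling of the data", {
  tm <- make_templates()
  sm <- sample_noisy_maps(tm, 120, snr = 4, seed = 2)
  f1 <- modified_kmeans(sm$maps, k = 4, n_restarts = 3, seed = 9)
  f2 <- modified_kmeans(sm$maps * 37.5, k = 4, n_restarts = 3, seed = 9)
  expect_equal(f1$maps, f2$maps, tolerance = 1e-9)
  expect_equal(f1$gev, f2$gev, tolerance = 1e-12)
})

test_that("k exceeding the number of maps is a parameter error", {
  tm <- make_templates()
  expect_error(modified_kmeans(tm$maps[1:3, ], k = 4), "at least k")
})

test_that("GEV has its closed-form extremes and matches the brute-force oracle", {
  tm <- make_templates()
  expect_equal(compute_gev(tm, tm$maps), 1, tolerance = 1e-12)

  # peak maps orthogonal to every template: rotate into the orthocomplement
  q <- qr.Q(qr(t(rbind(tm$maps, rep(1, 64)))), complete = TRUE)
  ortho <- t(q[, 6:15])
  expect_equal(compute_gev(tm, ortho), 0, tolerance = 1e-12)

  sm <- sample_noisy_maps(tm, 40, snr = 3, seed = 8)
  gfp <- sqrt(rowMeans(microstatr:::center_rows(sm$maps)^2))
  expect_equal(compute_gev(tm, sm$maps, gfp),
               unname(oracle_gev(tm$maps, sm$maps, gfp)), tolerance = 1e-12)
})

test_that("group aggregation recovers shared subject maps", {
  tm <- make_templates()
  same <- lapply(1:4, function(i) tm)
  gm <- aggregate_group_maps(same, k = 4, seed = 2, n_restarts = 5)
  gm <- order_maps_canonical(gm, tm)
  expect_equal(unname(diag(abs(gm$maps %*% t(tm$maps)))), rep(1, 4),
               tolerance = 1e-9)

  noisy <- lapply(1:6, function(i) {
    sm <- sample_noisy_maps(tm, 60, snr = 6, seed = 100 + i)
    modified_kmeans(sm$maps, k = 4, n_restarts = 5, seed = i)
  })
  gm2 <- order_maps_canonical(
    aggregate_group_maps(noisy, k = 4, seed = 2, n_restarts = 5), tm)
  expect_true(all(diag(abs(gm2$maps %*% t(tm$maps))) >= 0.98))

  expect_error(aggregate_group_maps(list(tm), k = 4), "2 subjects")
})

test_that("canonical ordering recovers known permutations", {
  ref <- canonical_maps()
  expect_equal(order_maps_canonical(ref, ref)$provenance$permutation, 1:4)

  rev_maps <- ms_maps(ref$maps[4:1, ], labels = c("A", "B", "C", "D"))
  out <- order_maps_canonical(rev_maps, ref)
  expect_equal(out$provenance$permutation, 4:1)
  expect_equal(out$maps, ref$maps, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("canonical ordering survives noise in nearly all seeded shuffles", {
  ref <- canonical_maps()
  ok <- 0L
  n_trials <- 1000L
  set.seed(77)
  for (i in seq_len(n_trials)) {
    perm <- sample(4)
    noisy <- ref$maps[perm, ] + matrix(rnorm(4 * 64, sd = 0.04), 4, 64)
    m <- ms_maps(noisy)
    out <- order_maps_canonical(m, ref)
    if (all(out$provenance$permutation == order(perm))) ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.99)
})

test_that("exhaustive permutation matching equals greedy on separated maps", {
  ref <- canonical_maps()
  set.seed(31)
  noisy <- ms_maps(ref$maps[c(3, 1, 4, 2), ] +
                     matrix(rnorm(4 * 64, sd = 0.05), 4, 64))
  out <- order_maps_canonical(noisy, ref)
  r <- abs(noisy$maps %*% t(ref$maps))
  greedy <- apply(r, 2, which.max)
  expect_equal(out$provenance$permutation, unname(greedy))
})
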