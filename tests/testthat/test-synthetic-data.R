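# Templates, semi-Markov label dynamics, subject synthesis, cohorts.

test_that("canonical templates are orthogonal enough and properly oriented", {
  tm <- make_templates()
  r <- tm$maps %*% t(tm$maps)
  expect_true(all(abs(r[upper.tri(r)]) <= 0.5))
  expect_equal(unname(rowSums(tm$maps)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(rowSums(tm$maps^2)), rep(1, 4), tolerance = 1e-12)

  # class A: signs anti-symmetric across the midline at lateral electrodes
  mont <- standard_montage_64()
  lat <- which(mont$x >= 0.5)
  mirror <- vapply(lat, function(i)
    which.min((mont$x + mont$x[i])^2 + (mont$y - mont$y[i])^2), 0L)
  a <- tm$maps["A", ]
  expect_true(all(sign(a[lat]) == -sign(a[mirror])))
  # class C: anterior-posterior axis on the midline
  cc <- tm$maps["C", ]
  expect_gt(cc[mont$name == "Oz"], 0)
  expect_lt(cc[mont$name == "Fpz"], 0)
  # class D: fronto-central maximum
  dd <- tm$maps["D", ]
  expect_equal(mont$name[which.max(abs(dd))],
               mont$name[which.max(dd)])
  expect_gt(mont$y[which.max(dd)], 0)

  expect_error(make_templates(k = 5), "built in")
})

test_that("templates are reproducible bit-exact for a fixed seed", {
  t1 <- make_templates(jitter = 0.05, seed = 99)
  t2 <- make_templates(jitter = 0.05, seed = 99)
  t3 <- make_templates(jitter = 0.05, seed = 100)
  expect_identical(t1$maps, t2$maps)
  expect_false(identical(t1$maps, t3$maps))
})

test_that("dwell times obey the configured mean over many epochs", {
  set.seed(11)
  tot <- 0; nn <- 0
  for (e in 1:10000) {
    lab <- sample_label_sequence(2000, 1000, c(80, 80, 80, 80))
    r <- microstatr:::rle_runs(lab)
    n <- length(r$length)
    if (n > 1) {  # completed (non-truncated) runs only
      tot <- tot + sum(r$length[-n])
      nn <- nn + n - 1
    }
  }
  expect_lt(abs(tot / nn - 80) / 80, 0.02)
})

test_that("class coverage follows the duration-weighted stationary law", {
  set.seed(12)
  cnt <- numeric(4)
  for (e in 1:4000) {
    lab <- sample_label_sequence(2000, 1000, c(60, 80, 100, 120))
    cnt <- cnt + tabulate(lab, 4)
  }
  cov <- cnt / sum(cnt)
  expected <- c(60, 80, 100, 120) / 360
  expect_true(all(abs(cov - expected) / expected < 0.02))
})

test_that("a single-class semi-Markov configuration is rejected", {
  expect_error(generator_config(k = 1, mean_duration_ms = c(A = 80)),
               "k >= 2")
})

test_that("labels never self-transition across run boundaries", {
  set.seed(3)
  for (i in 1:20) {
    lab <- sample_label_sequence(1000, 500, c(60, 90, 120))
    r <- microstatr:::rle_runs(lab)
    expect_true(all(diff(r$value) != 0))
  }
})

test_that("subject synthesis is deterministic and within amplitude bounds", {
  cfg <- generator_config(n_epochs = 4)
  tm <- make_templates()
  s1 <- synthesize_subject(cfg, tm, "seizure", "x", seed = 5)
  s2 <- synthesize_subject(cfg, tm, "seizure", "x", seed = 5)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$ground_truth$labels, s2$ground_truth$labels)
  # stays clear of the 100 uV rejection threshold
  expect_lt(max(abs(s1$recording$data)), 100)
  expect_equal(length(unlist(s1$ground_truth$labels)),
               ncol(s1$recording$data))
})

test_that("noise-free recordings backfit to the planted labels exactly", {
  cfg <- generator_config(n_epochs = 3, snr = Inf)
  tm <- make_templates()
  s <- synthesize_subject(cfg, tm, "control", "nf", seed = 21)
  es <- average_reference(segment_epochs(s$recording, 2))
  ls <- backfit(es, tm)
  expect_identical(lapply(ls$labels, as.integer), s$ground_truth$labels)
  # smoothing may only touch planted runs already shorter than the minimum
  sm <- smooth_labels(ls, min_duration_ms = 20)
  for (e in seq_along(sm$labels)) {
    gt <- s$ground_truth$labels[[e]]
    runs <- microstatr:::rle_runs(gt)
    long_enough <- rep(runs$length >= 20, runs$length)
    expect_identical(as.integer(sm$labels[[e]][long_enough]),
                     gt[long_enough])
  }
})

test_that("cohorts have the configured structure and survive preprocessing", {
  cfg <- generator_config(n_epochs = 31,
                          group_sizes = c(seizure = 2, seizure_free = 2,
                                          control = 2))
  coh <- make_cohort(cfg)
  expect_length(coh$recordings, 6L)
  expect_equal(as.integer(table(coh$manifest$group)[c("seizure",
                                                      "seizure_free",
                                                      "control")]),
               c(2L, 2L, 2L))
  expect_equal(nrow(coh$ground_truth$parameters), 6L * 4L)
  # generated data pass the artifact screen with zero rejections
  es <- preprocess_subject(coh$recordings[[1]], min_epochs = 30)
  expect_equal(es$n_rejected, 0L)
  expect_gte(length(es$epochs), 30L)
  # determinism of the full cohort
  coh2 <- make_cohort(cfg)
  expect_identical(coh$recordings[[3]]$data, coh2$recordings[[3]]$data)
})

test_that("cohorts written to disk round-trip through the manifest reader", {
  cfg <- generator_config(n_epochs = 2, n_channels = 64,
                          group_sizes = c(seizure = 1, control = 1))
  dir <- file.path(tempfile(), "cohort")
  coh <- make_cohort(cfg, dir = dir, format = "delim")
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  back <- read_cohort(m)
  expect_equal(back$sub01$data, coh$recordings$sub01$data,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$sub02$group, "control")
  expect_error(make_cohort(cfg, dir = dir), "not empty")
})

test_that("planted group effects shift the realised parameters as designed", {
  tab <- simulate_label_cohort(generator_config(), seed = 404, srate = 500)
  mean_by <- function(cl, grp, col)
    mean(tab[[col]][tab$class == cl & tab$group == grp])
  # seizure group: higher class-A frequency/coverage ...
  expect_gt(mean_by("A", "seizure", "frequency_per_s"),
            mean_by("A", "control", "frequency_per_s"))
  expect_gt(mean_by("A", "seizure", "coverage"),
            mean_by("A", "control", "coverage"))
  # ... and lower class-C duration/coverage
  expect_lt(mean_by("C", "seizure", "duration_ms"),
            mean_by("C", "control", "duration_ms"))
  expect_lt(mean_by("C", "seizure", "coverage"),
            mean_by("C", "control", "coverage"))
})
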