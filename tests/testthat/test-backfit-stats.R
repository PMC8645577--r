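# Backfitting, duration smoothing, and the Duration/Frequency/Coverage table.

test_that("backfit labels template copies perfectly and respects min_corr", {
  tm <- make_templates()
  ep <- matrix(tm$maps["B", ], nrow = 64, ncol = 1000) * 30
  es <- average_reference(ms_epochs(list(ep), srate = 500, epoch_seconds = 2,
                                    channel_names = tm$channel_names))
  ls <- backfit(es, tm)
  expect_true(all(ls$labels[[1]] == 2L))
  expect_equal(max(abs(ls$corr[[1]][2, ] - 1)), 0, tolerance = 1e-9)

  # a topography orthogonal to every template stays unassigned
  q <- qr.Q(qr(t(rbind(tm$maps, rep(1, 64)))), complete = TRUE)
  ortho <- q[, 7]
  ep2 <- cbind(matrix(tm$maps["A", ] * 30, 64, 999), ortho * 30)
  es2 <- average_reference(ms_epochs(list(ep2), srate = 500,
                                     epoch_seconds = 2))
  ls2 <- backfit(es2, tm, min_corr = 0.5)
  expect_true(is.na(ls2$labels[[1]][1000]))
  expect_true(all(ls2$labels[[1]][1:999] == 1L))

  bad <- ms_epochs(list(matrix(0.0, 8, 1000) + rnorm(8000)), srate = 500,
                   epoch_seconds = 2)
  expect_error(backfit(bad, tm), "channels")
})

test_that("smoothing dissolves sub-minimum interior runs into their flanks", {
  # AAAA B AAAA with a 1-sample B run and 2-sample minimum -> all A
  lab <- c(rep(1L, 4), 2L, rep(1L, 4))
  r <- matrix(0.5, nrow = 2, ncol = 9)
  r[1, ] <- 0.9
  ls <- microstatr:::ms_labels(list(lab), list(r), list(rep(1, 9)),
                               srate = 500, class_labels = c("A", "B"))
  out <- smooth_labels(ls, min_duration_ms = 2 / 500 * 1000)
  expect_true(all(out$labels[[1]] == 1L))

  # already-long runs are untouched (idempotence)
  lab2 <- rep(c(1L, 2L), each = 50)
  r2 <- matrix(runif(200), 2, 100)
  ls2 <- microstatr:::ms_labels(list(lab2), list(r2), list(rep(1, 100)),
                                srate = 500, class_labels = c("A", "B"))
  out2 <- smooth_labels(ls2, min_duration_ms = 20)
  expect_identical(out2$labels[[1]], lab2)
})

test_that("smoothing matches the brute-force reference on random sequences", {
  set.seed(42)
  for (trial in 1:60) {
    n <- sample(5:50, 1)
    k <- sample(2:4, 1)
    lab <- as.integer(sample(k, n, replace = TRUE))
    r <- matrix(runif(k * n), k, n)
    min_samples <- sample(2:4, 1)
    ls <- microstatr:::ms_labels(list(lab), list(r), list(rep(1, n)),
                                 srate = 1000,
                                 class_labels = LETTERS[1:k])
    out <- smooth_labels(ls, min_duration_ms = min_samples)
    expect_identical(out$labels[[1]],
                     oracle_smooth(lab, r, min_samples))
  }
})

test_that("smoothing never leaves a short interior run", {
  set.seed(17)
  for (trial in 1:20) {
    n <- 200
    lab <- as.integer(sample(4, n, replace = TRUE))
    r <- matrix(runif(4 * n), 4, n)
    ls <- microstatr:::ms_labels(list(lab), list(r), list(rep(1, n)),
                                 srate = 500, class_labels = LETTERS[1:4])
    out <- smooth_labels(ls, min_duration_ms = 3 / 500 * 1000)
    runs <- microstatr:::rle_runs(out$labels[[1]])
    interior <- runs$start > 1 & runs$end < n
    expect_true(all(runs$length[interior] >= 3))
  }
})

test_that("the worked parameter example is computed exactly", {
  # 500 Hz, one epoch: A x10, B x10, A x20
  lab <- c(rep(1L, 10), rep(2L, 10), rep(1L, 20))
  p <- parameters_from_labels(list(lab), srate = 500, k = 2,
                              class_labels = c("A", "B"))
  expect_equal(p$duration_ms[p$class == "A"], 30)
  expect_equal(p$frequency_per_s[p$class == "A"], 25)
  expect_equal(p$coverage[p$class == "A"], 0.75)
  expect_equal(p$coverage[p$class == "A"],
               p$frequency_per_s[p$class == "A"] *
                 p$duration_ms[p$class == "A"] / 1000)

  # one class everywhere over several epochs
  labs <- replicate(3, rep(1L, 500), simplify = FALSE)
  p2 <- parameters_from_labels(labs, srate = 500, k = 2,
                               class_labels = c("A", "B"))
  expect_equal(p2$coverage[1], 1)
  expect_equal(p2$frequency_per_s[1], 3 / 3)  # 3 runs / 3 s
  expect_true(is.na(p2$duration_ms[2]))
  expect_equal(p2$frequency_per_s[2], 0)
  expect_equal(p2$coverage[2], 0)
})

test_that("parameters match the run-length oracle and satisfy the identity", {
  set.seed(9)
  for (trial in 1:25) {
    labs <- lapply(1:3, function(e)
      as.integer(sample(4, sample(50:200, 1), replace = TRUE)))
    if (trial %% 3 == 0) labs[[1]][sample(length(labs[[1]]), 10)] <- NA
    p <- parameters_from_labels(labs, srate = 500, k = 4)
    o <- oracle_parameters(labs, srate = 500, k = 4)
    expect_equal(p$duration_ms, o$duration_ms, tolerance = 1e-12)
    expect_equal(p$frequency_per_s, o$frequency_per_s, tolerance = 1e-12)
    expect_equal(p$coverage, o$coverage, tolerance = 1e-12)
    # coverage = frequency x duration, exactly, class by class
    occ <- !is.na(p$duration_ms)
    expect_equal(p$coverage[occ],
                 p$frequency_per_s[occ] * p$duration_ms[occ] / 1000,
                 tolerance = 1e-12)
    expect_equal(sum(p$coverage), 1, tolerance = 1e-12)
  }
})

test_that("cohort tables summarise group means and flag degenerate SDs", {
  rows <- function(id, grp, dur) {
    parameters_from_labels(list(rep(1:4, each = round(dur / 2))), 500, 4,
                           subject_id = id, group = grp)
  }
  # identical subjects within a group -> SD 0
  tabs <- list(rows("a", "seizure", 100), rows("b", "seizure", 100),
               rows("c", "control", 80), rows("d", "control", 80),
               rows("e", "seizure_free", 60))
  ct <- build_cohort_table(tabs)
  s <- ct$summary
  expect_equal(s$sd[s$group == "seizure" & s$parameter == "duration_ms"],
               rep(0, 4))
  # single-subject group -> SD missing, mean passes through
  expect_true(all(is.na(s$sd[s$group == "seizure_free"])))
  expect_equal(s$mean[s$group == "seizure_free" &
                        s$parameter == "coverage"], rep(0.25, 4))
  expect_error(build_cohort_table(list()), "empty|no applicable")
})

test_that("group means of a quiet synthetic cohort sit near the planted values", {
  cfg <- generator_config(subject_sdlog = 0,
                          group_effects = NULL)
  tab <- simulate_label_cohort(cfg, seed = 314, srate = 500)
  planted_dur <- cfg$mean_duration_ms
  planted_cov <- planted_dur / sum(planted_dur)
  for (grp in unique(tab$group)) {
    for (cl in 1:4) {
      sel <- tab$group == grp & tab$class == LETTERS[cl]
      expect_lt(abs(mean(tab$duration_ms[sel]) - planted_dur[cl]) /
                  planted_dur[cl], 0.05)
      expect_lt(abs(mean(tab$coverage[sel]) - planted_cov[cl]), 0.02)
    }
  }
})
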