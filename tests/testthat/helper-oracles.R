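# Independent brute-force oracles, deliberately written as plain loops over
# the defining formulas, sharing no code with the package internals.

# GFP of one column: spatial SD across channels.
oracle_gfp <- function(v) {
  m <- sum(v) / length(v)
  acc <- 0
  for (x in v) acc <- acc + (x - m)^2
  sqrt(acc / length(v))
}

# Polarity-invariant spatial correlation via stats::cor.
oracle_abs_cor <- function(a, b) abs(stats::cor(a, b))

# GEV by double loop: each peak map assigned to its best template.
oracle_gev <- function(templates, peak_maps, gfp) {
  num <- 0
  den <- 0
  for (i in seq_len(nrow(peak_maps))) {
    best <- 0
    for (j in seq_len(nrow(templates))) {
      r <- oracle_abs_cor(peak_maps[i, ], templates[j, ])
      if (r > best) best <- r
    }
    num <- num + gfp[i]^2 * best^2
    den <- den + gfp[i]^2
  }
  num / den
}

# Duration / Frequency / Coverage by naive per-sample run counting.
oracle_parameters <- function(labels, srate, k) {
  run_count <- numeric(k)
  sample_count <- numeric(k)
  total <- 0
  for (lab in labels) {
    prev <- NA_integer_
    for (t in seq_along(lab)) {
      v <- lab[t]
      if (is.na(v)) { prev <- NA_integer_; next }
      total <- total + 1
      sample_count[v] <- sample_count[v] + 1
      if (is.na(prev) || v != prev) run_count[v] <- run_count[v] + 1
      prev <- v
    }
  }
  list(duration_ms = ifelse(run_count > 0,
                            sample_count / run_count * 1000 / srate, NA),
       frequency_per_s = run_count / (total / srate),
       coverage = sample_count / total)
}

# Minimum-duration smoothing, re-derived sample by sample: find interior
# runs shorter than the minimum, hand each of their samples to the flank
# whose template correlates better there (ties to the left), repeat.
oracle_smooth <- function(lab, r, min_samples, max_passes = 10) {
  n <- length(lab)
  if (n < 2L) return(lab)
  for (pass in seq_len(max_passes)) {
    # boundaries of runs, scanning samples directly
    starts <- 1L
    for (t in 2:n) {
      if (!identical(lab[t], lab[t - 1L]) &&
          !(is.na(lab[t]) && is.na(lab[t - 1L]))) starts <- c(starts, t)
    }
    ends <- c(starts[-1L] - 1L, n)
    lens <- ends - starts + 1L
    short <- which(lens < min_samples & starts > 1L & ends < n &
                     !is.na(lab[starts]))
    if (!length(short)) break
    for (i in short) {
      lv <- lab[starts[i] - 1L]
      rv <- lab[ends[i] + 1L]
      for (t in starts[i]:ends[i]) {
        rl <- if (is.na(lv)) -Inf else r[lv, t]
        rr <- if (is.na(rv)) -Inf else r[rv, t]
        if (is.infinite(rl) && is.infinite(rr)) next
        lab[t] <- if (rl >= rr) lv else rv
      }
    }
  }
  lab
}

# Wilks' Lambda for two groups from Hotelling's T^2.
oracle_wilks_two_group <- function(y1, y2) {
  n1 <- nrow(y1); n2 <- nrow(y2); n <- n1 + n2
  d <- colMeans(y1) - colMeans(y2)
  s_pooled <- (crossprod(scale(y1, scale = FALSE)) +
                 crossprod(scale(y2, scale = FALSE))) / (n - 2)
  t2 <- (n1 * n2 / n) * drop(t(d) %*% solve(s_pooled) %*% d)
  1 / (1 + t2 / (n - 2))
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(v, grp) {
  grp <- as.factor(grp)
  grand <- mean(v)
  ssb <- 0; ssw <- 0
  for (lev in levels(grp)) {
    vg <- v[grp == lev]
    ssb <- ssb + length(vg) * (mean(vg) - grand)^2
    ssw <- ssw + sum((vg - mean(vg))^2)
  }
  g <- nlevels(grp); n <- length(v)
  (ssb / (g - 1)) / (ssw / (n - g))
}

# --- shared fixtures -------------------------------------------------------

# A tiny average-referenced epoch set built from given column topographies.
make_epochs_from_columns <- function(cols_list, srate = 500) {
  epochs <- lapply(cols_list, function(m) m)
  ms_epochs(epochs, srate = srate,
            epoch_seconds = ncol(cols_list[[1L]]) / srate,
            reference = "original")
}

# Noisy peak-map sample from templates: n maps, template RMS snr times
# the (spatially smoothed) noise RMS.
sample_noisy_maps <- function(templates, n, snr = 4, seed = 1) {
  tm <- templates$maps
  nc <- ncol(tm)
  mont <- standard_montage_64()[seq_len(nc), ]
  W <- microstatr:::montage_smoother(mont)
  with_seed <- microstatr:::with_seed
  with_seed(seed, {
    idx <- sample.int(nrow(tm), n, replace = TRUE)
    x <- tm[idx, , drop = FALSE]
    noise <- t(W %*% matrix(rnorm(nc * n), nrow = nc))
    noise <- noise - rowMeans(noise)
    noise <- noise * (sqrt(mean(x^2)) / snr / sqrt(mean(noise^2)))
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    list(maps = sgn * (x + noise), truth = idx)
  })
}
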