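# Synthetic cohort generator: semi-Markov microstate dynamics with planted
# ground truth, alpha-band GFP modulation and spatially correlated noise.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the pipeline targets: 64-channel
#' eyes-closed EEG sampled at 1,000 Hz, 30 two-second epochs per subject,
#' three groups of 10/12/17 subjects, microstate dwell times in the
#' 60--120 ms regime, and planted group effects in the reported directions
#' (the seizure group transitions into class A more often and dwells in
#' class C for a shorter time, raising A's frequency/coverage and lowering
#' C's duration/coverage).
#'
#' @param n_channels Electrode count (uses the first rows of the montage).
#' @param srate Sampling rate in Hz.
#' @param k Number of microstate classes.
#' @param group_sizes Named integer vector of subjects per group.
#' @param n_epochs Epochs generated per subject.
#' @param epoch_seconds Epoch length in seconds.
#' @param mean_duration_ms Named per-class mean dwell time (ms).
#' @param duration_shape Gamma shape of the dwell-time law (scale is
#'   \code{mean/shape}).
#' @param transition Base K x K transition weight matrix (diagonal ignored);
#'   \code{NULL} = uniform off-diagonal.
#' @param snr Ratio of template-signal RMS to noise RMS.
#' @param signal_amplitude Peak of the 10 Hz GFP envelope, in microvolts
#'   (kept well below the 100 uV rejection threshold).
#' @param envelope_hz Frequency of the rectified sinusoidal GFP envelope.
#' @param subject_sdlog Between-subject log-normal spread of the per-class
#'   dwell times (0.2 gives coverage dispersion of the order seen in
#'   resting-state cohorts).
#' @param group_effects Per-group list of \code{duration_scale} and
#'   \code{transition_scale} named per-class multipliers; see
#'   [default_group_effects()].
#' @param seed Master seed; every randomisation derives from it.
#' @return A list of class \code{ms_generator_config}.
#' @export
generator_config <- function(n_channels = 64, srate = 1000, k = 4,
                             group_sizes = c(seizure = 10, seizure_free = 12,
                                             control = 17),
                             n_epochs = 30, epoch_seconds = 2,
                             mean_duration_ms = c(A = 75, B = 85,
                                                  C = 95, D = 110),
                             duration_shape = 4, transition = NULL,
                             snr = 4, signal_amplitude = 60,
                             envelope_hz = 10, subject_sdlog = 0.2,
                             group_effects = default_group_effects(),
                             seed = 1) {
  if (k < 2L)
    stop_io("the semi-Markov label model needs k >= 2 classes (no self-%s",
            "transitions are possible for k = 1)")
  if (is.null(transition)) {
    transition <- matrix(1, k, k)
  }
  transition <- as.matrix(transition)
  stopifnot(nrow(transition) == k, ncol(transition) == k)
  diag(transition) <- 0
  if (any(transition < 0) || any(rowSums(transition) == 0))
    stop_io("transition weights must be non-negative with a possible exit %s",
            "from every class")
  if (length(mean_duration_ms) != k || any(mean_duration_ms <= 0))
    stop_io("mean_duration_ms must give a positive dwell time per class")
  stopifnot(all(names(group_sizes) %in% .ms_groups))
  structure(
    list(n_channels = n_channels, srate = srate, k = k,
         group_sizes = group_sizes, n_epochs = n_epochs,
         epoch_seconds = epoch_seconds,
         mean_duration_ms = mean_duration_ms,
         duration_shape = duration_shape, transition = transition,
         snr = snr, signal_amplitude = signal_amplitude,
         envelope_hz = envelope_hz, subject_sdlog = subject_sdlog,
         group_effects = group_effects, seed = seed),
    class = "ms_generator_config")
}

#' Default planted group effects
#'
#' The seizure group gets its transition weight into class A scaled by 1.8
#' (raising A's occurrence frequency and coverage) and its class-C dwell
#' time scaled by 0.6 (lowering C's duration and coverage); the other two
#' groups are neutral. Classes B and D carry no planted effect.
#'
#' @return A named list of per-group effect lists.
#' @export
default_group_effects <- function() {
  neutral <- list(duration_scale = c(A = 1, B = 1, C = 1, D = 1),
                  transition_scale = c(A = 1, B = 1, C = 1, D = 1))
  list(
    seizure = list(duration_scale = c(A = 1, B = 1, C = 0.6, D = 1),
                   transition_scale = c(A = 1.8, B = 1, C = 1, D = 1)),
    seizure_free = neutral,
    control = neutral)
}

#' Sample one epoch's microstate label sequence
#'
#' Explicit-duration (semi-Markov) dynamics: the class of each run is drawn
#' from the transition weights of the previous class (self-transitions
#' impossible), its length from a per-class gamma law rounded up to at least
#' one sample; the final run is truncated at the epoch end.
#'
#' @param n_samples Epoch length in samples.
#' @param srate Sampling rate in Hz.
#' @param mean_duration_ms Per-class mean dwell times (ms).
#' @param duration_shape Gamma shape parameter.
#' @param transition K x K transition weight matrix (diagonal ignored).
#' @return Integer vector of class indices in \code{1..K}. Draws from the
#'   current RNG stream; seed management is the caller's concern.
#' @export
sample_label_sequence <- function(n_samples, srate, mean_duration_ms,
                                  duration_shape = 4, transition = NULL) {
  k <- length(mean_duration_ms)
  if (is.null(transition)) transition <- matrix(1, k, k)
  diag(transition) <- 0
  scale_ms <- mean_duration_ms / duration_shape
  labels <- integer(n_samples)
  pos <- 1L
  cls <- sample.int(k, 1L)
  while (pos <= n_samples) {
    len_ms <- stats::rgamma(1L, shape = duration_shape,
                            scale = scale_ms[cls])
    len <- max(1L, round(len_ms / 1000 * srate))
    end <- min(pos + len - 1L, n_samples)
    labels[pos:end] <- cls
    pos <- end + 1L
    w <- transition[cls, ]
    cls <- sample.int(k, 1L, prob = w)
  }
  labels
}

# Per-subject realisation of the class dwell-time means and transition
# weights: group effects plus log-normal between-subject variation.
subject_dynamics <- function(cfg, group) {
  eff <- cfg$group_effects[[group]]
  dur <- cfg$mean_duration_ms
  trn <- cfg$transition
  if (!is.null(eff)) {
    dur <- dur * eff$duration_scale[seq_len(cfg$k)]
    trn <- sweep(trn, 2L, eff$transition_scale[seq_len(cfg$k)], "*")
  }
  if (cfg$subject_sdlog > 0)
    dur <- dur * stats::rlnorm(cfg$k, meanlog = -cfg$subject_sdlog^2 / 2,
                               sdlog = cfg$subject_sdlog)
  list(mean_duration_ms = dur, transition = trn)
}

#' Synthesise one subject's recording with ground truth
#'
#' The signal at time t is \code{a(t) * map[label(t)] + noise(t)}: the
#' subject's planted label sequence (one independent semi-Markov sequence per
#' epoch) multiplied by a signed 10 Hz alpha oscillation
#' \code{a(t) = A sin(2 pi f t + phi)} — the polarity of a microstate's
#' topography alternates every half-cycle while the map itself stays fixed,
#' so the GFP traces the rectified 10 Hz envelope \code{|a(t)|} and the
#' signal is zero-mean and band-limited well inside 1--40 Hz. Spatially
#' smoothed Gaussian noise is added, scaled so the template-signal RMS over
#' the recording is \code{snr} times the noise RMS. Epochs are concatenated
#' into one continuous recording so the preprocessing chain can re-cut them.
#'
#' @param cfg A [generator_config()].
#' @param templates An [ms_maps()] with \code{cfg$k} rows (e.g.
#'   [make_templates()]).
#' @param group Group this subject belongs to.
#' @param subject_id Subject identifier.
#' @param seed Seed for this subject's randomness.
#' @return A list with \code{recording} ([ms_recording()]) and
#'   \code{ground_truth}: per-epoch label vectors, the realised per-class
#'   parameters (computed by the same run-length definitions the analysis
#'   uses), and the subject's realised dynamics.
#' @export
synthesize_subject <- function(cfg, templates, group, subject_id,
                               seed = cfg$seed) {
  stopifnot(inherits(cfg, "ms_generator_config"),
            inherits(templates, "ms_maps"),
            nrow(templates$maps) == cfg$k)
  tm <- templates$maps
  nc <- ncol(tm)
  L <- round(cfg$epoch_seconds * cfg$srate)
  montage <- standard_montage_64()[seq_len(nc), ]
  smoother <- montage_smoother(montage)

  with_seed(seed, {
    dyn <- subject_dynamics(cfg, group)
    labels <- lapply(seq_len(cfg$n_epochs), function(e)
      sample_label_sequence(L, cfg$srate, dyn$mean_duration_ms,
                            cfg$duration_shape, dyn$transition))
    all_labels <- unlist(labels, use.names = FALSE)
    n <- length(all_labels)
    phase <- stats::runif(1L, 0, 2 * pi)
    a <- cfg$signal_amplitude *
      sin(2 * pi * cfg$envelope_hz * (seq_len(n) - 1L) / cfg$srate + phase)
    sig <- t(tm[all_labels, , drop = FALSE] * a)
    noise <- smoother %*% matrix(stats::rnorm(nc * n), nrow = nc)
    noise <- center_cols(noise)
    rms_sig <- sqrt(mean(sig^2))
    rms_noise <- sqrt(mean(noise^2))
    if (is.finite(cfg$snr) && cfg$snr > 0 && rms_noise > 0) {
      noise <- noise * (rms_sig / cfg$snr / rms_noise)
    } else {
      noise <- noise * 0
    }
    rec <- ms_recording(sig + noise, srate = cfg$srate,
                        channel_names = montage$name,
                        subject_id = subject_id, group = group)
    params <- parameters_from_labels(labels, cfg$srate, cfg$k,
                                     class_labels = class_tags(cfg$k),
                                     subject_id = subject_id, group = group)
    list(recording = rec,
         ground_truth = list(labels = labels, parameters = params,
                             dynamics = dyn))
  })
}

#' Generate a full synthetic cohort
#'
#' Draws one subject seed per subject under the master seed, synthesises all
#' recordings, and bundles the manifest-style metadata with the full ground
#' truth (true templates, planted label sequences, realised per-subject
#' parameters). Optionally writes recordings to disk as EDF or delimited
#' matrices plus a cohort manifest.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory; \code{NULL} (default) keeps everything in
#'   memory.
#' @param format \code{"edf"} or \code{"delim"} when writing to disk.
#' @return A list with \code{recordings} (named list), \code{manifest}
#'   (data frame), \code{templates}, and \code{ground_truth} (per-subject
#'   labels and the pooled realised parameter table).
#' @export
make_cohort <- function(cfg = generator_config(), dir = NULL,
                        format = c("edf", "delim")) {
  format <- match.arg(format)
  templates <- make_templates(
    standard_montage_64()[seq_len(cfg$n_channels), ], k = cfg$k)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  ids <- sprintf("sub%02d", seq_along(groups))
  seeds <- with_seed(cfg$seed,
                     sample.int(.Machine$integer.max - 1L,
                                length(groups)))
  subs <- lapply(seq_along(groups), function(i)
    synthesize_subject(cfg, templates, groups[i], ids[i], seed = seeds[i]))
  recordings <- lapply(subs, `[[`, "recording")
  names(recordings) <- ids
  params <- do.call(rbind, lapply(subs, function(s) s$ground_truth$parameters))
  manifest <- data.frame(subject_id = ids, group = groups,
                         path = NA_character_, srate = cfg$srate,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)))
      stop_io("output directory %s exists and is not empty", dir)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(recordings)) {
      fn <- if (format == "edf") paste0(ids[i], ".edf")
            else paste0(ids[i], ".tsv")
      fp <- file.path(dir, fn)
      if (format == "edf") {
        write_edf(recordings[[i]], fp)
      } else {
        utils::write.table(recordings[[i]]$data, fp, sep = "\t",
                           row.names = FALSE, col.names = FALSE)
        writeLines(recordings[[i]]$channel_names,
                   paste0(fp, ".channels"))
      }
      manifest$path[i] <- fn
    }
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(seed = cfg$seed, group_sizes = as.list(cfg$group_sizes),
           realised_parameters = params),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(recordings = recordings, manifest = manifest, templates = templates,
       ground_truth = list(
         labels = lapply(subs, function(s) s$ground_truth$labels),
         parameters = params,
         subject_seeds = seeds))
}

#' Simulate a cohort at the label-sequence level
#'
#' Generates each subject's planted label sequences and the resulting
#' Duration/Frequency/Coverage table without synthesising any EEG signal or
#' re-clustering — the fast path for statistical calibration and power
#' studies of the group comparison, using the exact same semi-Markov
#' mechanism and run-length code the full generator uses.
#'
#' @param cfg A [generator_config()].
#' @param seed Seed overriding \code{cfg$seed}.
#' @param srate Rate to sample label sequences at (default \code{cfg$srate}).
#' @return A parameter table (one row per subject x class).
#' @export
simulate_label_cohort <- function(cfg = generator_config(), seed = cfg$seed,
                                  srate = cfg$srate) {
  L <- round(cfg$epoch_seconds * srate)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  ids <- sprintf("sub%02d", seq_along(groups))
  with_seed(seed, {
    do.call(rbind, lapply(seq_along(groups), function(i) {
      dyn <- subject_dynamics(cfg, groups[i])
      labels <- lapply(seq_len(cfg$n_epochs), function(e)
        sample_label_sequence(L, srate, dyn$mean_duration_ms,
                              cfg$duration_shape, dyn$transition))
      parameters_from_labels(labels, srate, cfg$k,
                             class_labels = class_tags(cfg$k),
                             subject_id = ids[i], group = groups[i])
    }))
  })
}
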