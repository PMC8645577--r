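# Preprocessing chain: band-pass filter, decimation, epoching, amplitude
# artifact rejection, average reference.

#' Zero-phase band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass forward and backward
#' (\code{signal::filtfilt}) to every channel, so the net response is
#' 8th-order in magnitude with zero phase distortion — phase shifts would
#' distort the instantaneous topographies the microstate analysis depends on.
#'
#' @param rec An [ms_recording()].
#' @param low,high Band edges in Hz; \code{0 < low < high < srate/2}.
#' @return The filtered [ms_recording()] (same shape and rate).
#' @export
bandpass_filter <- function(rec, low = 1, high = 40) {
  stopifnot(inherits(rec, "ms_recording"))
  nyq <- rec$srate / 2
  if (!(low > 0 && low < high))
    stop_io("need 0 < low < high, got low=%g high=%g", low, high)
  if (high >= nyq)
    stop_io("upper band edge %g Hz must be below the Nyquist rate %g Hz",
            high, nyq)
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  rec$data <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(bf, ch)))
  rec
}

#' Downsample a recording
#'
#' Integer-factor decimation with a zero-phase anti-alias low-pass
#' (8th-order Butterworth at 0.8 times the new Nyquist rate, applied
#' forward-backward) before sample picking.
#'
#' @param rec An [ms_recording()].
#' @param target_srate New rate in Hz; must divide \code{rec$srate}.
#' @return The decimated [ms_recording()].
#' @export
downsample <- function(rec, target_srate = 500) {
  stopifnot(inherits(rec, "ms_recording"))
  if (target_srate >= rec$srate)
    stop_io("target rate %g Hz must be below the current rate %g Hz",
            target_srate, rec$srate)
  q <- rec$srate / target_srate
  if (abs(q - round(q)) > 1e-9)
    stop_io("target rate %g Hz must divide the current rate %g Hz",
            target_srate, rec$srate)
  q <- round(q)
  lp <- signal::butter(8, 0.8 / q, type = "low")
  keep <- seq(1L, ncol(rec$data), by = q)
  rec$data <- t(apply(rec$data, 1L,
                      function(ch) signal::filtfilt(lp, ch)[keep]))
  rec$srate <- target_srate
  rec
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping consecutive segments; the trailing remainder shorter than
#' one epoch is discarded. Epoch k covers samples \code{[kL, (k+1)L)}.
#'
#' @param rec An [ms_recording()].
#' @param epoch_seconds Epoch length in seconds (default 2).
#' @return An [ms_epochs()].
#' @export
segment_epochs <- function(rec, epoch_seconds = 2) {
  stopifnot(inherits(rec, "ms_recording"))
  L <- round(epoch_seconds * rec$srate)
  n <- ncol(rec$data)
  if (n < L)
    stop_io("recording of %d samples is shorter than one %g-s epoch (%d)",
            n, epoch_seconds, L)
  n_ep <- n %/% L
  epochs <- lapply(seq_len(n_ep), function(k)
    rec$data[, ((k - 1L) * L + 1L):(k * L), drop = FALSE])
  ms_epochs(epochs, srate = rec$srate, epoch_seconds = epoch_seconds,
            subject_id = rec$subject_id, group = rec$group,
            channel_names = rec$channel_names)
}

#' Reject epochs by absolute amplitude
#'
#' An epoch whose absolute amplitude reaches the threshold on any channel at
#' any sample is removed (comparison is \code{>=}: a peak exactly at the
#' threshold is rejected). Epoch order is preserved.
#'
#' @param es An [ms_epochs()].
#' @param threshold Rejection threshold in microvolts (default 100).
#' @return The screened [ms_epochs()] with \code{n_rejected} updated.
#' @export
reject_amplitude_artifacts <- function(es, threshold = 100) {
  stopifnot(inherits(es, "ms_epochs"), threshold > 0)
  peak <- vapply(es$epochs, function(e) max(abs(e)), 0)
  keep <- peak < threshold
  if (!any(keep))
    stop_io("all %d epochs of subject %s exceed %g uV",
            length(es$epochs), es$subject_id, threshold)
  es$n_rejected <- es$n_rejected + sum(!keep)
  es$epochs <- es$epochs[keep]
  es
}

#' Re-reference epochs to the common average
#'
#' Subtracts the across-channel mean at every time point, the convention
#' under which GFP and topographic correlation are defined. Idempotent;
#' between-channel differences are preserved exactly.
#'
#' @param es An [ms_epochs()].
#' @return The re-referenced [ms_epochs()] with \code{reference = "average"}.
#' @export
average_reference <- function(es) {
  stopifnot(inherits(es, "ms_epochs"))
  if (n_channels(es) < 2L) stop_io("average reference needs >= 2 channels")
  es$epochs <- lapply(es$epochs, center_cols)
  es$reference <- "average"
  es
}

#' Full preprocessing chain for one subject
#'
#' Band-pass filter the continuous recording, decimate, cut into epochs,
#' reject high-amplitude epochs, apply an optional external epoch filter
#' (e.g. a keep/drop list from manual review or ICA cleaning done outside
#' this package), and re-reference to the common average.
#'
#' @param rec An [ms_recording()].
#' @param band Band-pass edges in Hz.
#' @param target_srate Decimation target in Hz; \code{NULL} skips.
#' @param epoch_seconds Epoch length in seconds.
#' @param reject_uv Amplitude rejection threshold in microvolts.
#' @param min_epochs Warn (not error) if fewer epochs survive screening.
#' @param epoch_filter Optional hook: either a logical keep-vector or a
#'   function \code{ms_epochs -> logical} applied after amplitude rejection.
#' @return An average-referenced [ms_epochs()].
#' @export
preprocess_subject <- function(rec, band = c(1, 40), target_srate = 500,
                               epoch_seconds = 2, reject_uv = 100,
                               min_epochs = 30, epoch_filter = NULL) {
  rec <- bandpass_filter(rec, band[1L], band[2L])
  if (!is.null(target_srate) && target_srate < rec$srate)
    rec <- downsample(rec, target_srate)
  es <- segment_epochs(rec, epoch_seconds)
  es <- reject_amplitude_artifacts(es, reject_uv)
  if (!is.null(epoch_filter)) {
    keep <- if (is.function(epoch_filter)) epoch_filter(es) else epoch_filter
    keep <- as.logical(keep)
    if (length(keep) != length(es$epochs))
      stop_io("epoch filter returned %d flags for %d epochs",
              length(keep), length(es$epochs))
    if (!any(keep)) stop_io("epoch filter removed every epoch of subject %s",
                            es$subject_id)
    es$n_rejected <- es$n_rejected + sum(!keep)
    es$epochs <- es$epochs[keep]
  }
  if (length(es$epochs) < min_epochs)
    warning(sprintf("subject %s retains %d epochs (< %d)",
                    es$subject_id, length(es$epochs), min_epochs),
            call. = FALSE)
  average_reference(es)
}
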