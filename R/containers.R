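# S3 containers: recordings, epoch sets, microstate maps, label sequences.

#' Construct a continuous multichannel EEG recording
#'
#' Bundles a channels-by-samples matrix of potentials (microvolts) with its
#' sampling rate, channel names and cohort metadata. This is the unit handed
#' to the preprocessing chain.
#'
#' @param data Numeric matrix, \code{n_channels x n_samples}, in microvolts.
#' @param srate Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of \code{data}.
#' @param subject_id Subject identifier.
#' @param group One of \code{"seizure"}, \code{"seizure_free"},
#'   \code{"control"}.
#' @return An object of class \code{ms_recording}.
#' @export
ms_recording <- function(data, srate, channel_names = NULL, subject_id = "s1",
                         group = c("seizure", "seizure_free", "control")) {
  group <- match.arg(group)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_io("recording data must be numeric")
  if (nrow(data) < 2L) stop_io("a recording needs at least 2 channels")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop_io("srate must be a single positive number")
  if (any(!is.finite(data))) {
    bad <- which(apply(data, 1L, function(r) any(!is.finite(r))))
    stop_io("non-finite values in channel row(s): %s",
            paste(bad, collapse = ", "))
  }
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop_io("channel name count (%d) does not match channel rows (%d)",
            length(channel_names), nrow(data))
  structure(
    list(data = data, srate = srate,
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id), group = group),
    class = "ms_recording")
}

#' @export
print.ms_recording <- function(x, ...) {
  cat(sprintf("<ms_recording> %s [%s]: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$srate,
              ncol(x$data) / x$srate))
  invisible(x)
}

#' Construct an epoch set
#'
#' Fixed-length artifact-screened segments of one subject's recording; the
#' unit of all downstream microstate analysis.
#'
#' @param epochs List of numeric matrices, all \code{n_channels x L}.
#' @param srate Sampling rate in Hz.
#' @param epoch_seconds Epoch length in seconds.
#' @param subject_id,group Cohort metadata (see [ms_recording()]).
#' @param channel_names Channel names carried from the recording.
#' @param n_rejected Number of epochs removed by artifact screening.
#' @param reference \code{"original"} or \code{"average"}.
#' @return An object of class \code{ms_epochs}.
#' @export
ms_epochs <- function(epochs, srate, epoch_seconds, subject_id = "s1",
                      group = c("seizure", "seizure_free", "control"),
                      channel_names = NULL, n_rejected = 0L,
                      reference = c("original", "average")) {
  group <- match.arg(group)
  reference <- match.arg(reference)
  stopifnot(is.list(epochs), length(epochs) >= 1L)
  dims <- vapply(epochs, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop_io("all epochs must share an identical shape")
  expected_len <- round(epoch_seconds * srate)
  if (dims[2L, 1L] != expected_len)
    stop_io("epoch length %d does not match epoch_seconds * srate = %d",
            dims[2L, 1L], expected_len)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dims[1L, 1L]))
  structure(
    list(epochs = epochs, srate = srate, epoch_seconds = epoch_seconds,
         subject_id = as.character(subject_id), group = group,
         channel_names = as.character(channel_names),
         n_rejected = as.integer(n_rejected), reference = reference),
    class = "ms_epochs")
}

#' @export
print.ms_epochs <- function(x, ...) {
  cat(sprintf(
    "<ms_epochs> %s [%s]: %d epochs of %g s @ %g Hz (%d rejected, ref=%s)\n",
    x$subject_id, x$group, length(x$epochs), x$epoch_seconds, x$srate,
    x$n_rejected, x$reference))
  invisible(x)
}

n_channels <- function(es) nrow(es$epochs[[1L]])
epoch_len <- function(es) ncol(es$epochs[[1L]])

#' Construct a set of microstate template maps
#'
#' @param maps Numeric matrix \code{K x n_channels}; each row a zero-mean,
#'   unit-norm topography.
#' @param labels Class tags, one per row (defaults A, B, C, D).
#' @param level \code{"subject"} or \code{"group"}.
#' @param gev Global explained variance achieved by these maps (fraction).
#' @param channel_names Channel names for provenance.
#' @param srate Sampling rate for provenance.
#' @param provenance Optional list (seed, restarts, ...).
#' @return An object of class \code{ms_maps}.
#' @export
ms_maps <- function(maps, labels = class_tags(nrow(maps)),
                    level = c("subject", "group"), gev = NA_real_,
                    channel_names = NULL, srate = NA_real_,
                    provenance = list()) {
  level <- match.arg(level)
  maps <- as.matrix(maps)
  maps <- center_rows(maps)
  nrm <- sqrt(rowSums(maps^2))
  if (any(nrm == 0)) stop_io("flat (zero) template map supplied")
  maps <- maps / nrm
  if (length(labels) != nrow(maps))
    stop_io("need one label per map")
  rownames(maps) <- labels
  if (!is.null(channel_names)) colnames(maps) <- channel_names
  structure(
    list(maps = maps, labels = as.character(labels), level = level,
         gev = gev, channel_names = channel_names, srate = srate,
         provenance = provenance),
    class = "ms_maps")
}

#' @export
print.ms_maps <- function(x, ...) {
  cat(sprintf("<ms_maps> %d maps [%s] over %d channels, level=%s, GEV=%s\n",
              nrow(x$maps), paste(x$labels, collapse = ""), ncol(x$maps),
              x$level,
              if (is.na(x$gev)) "NA" else sprintf("%.3f", x$gev)))
  invisible(x)
}

# Label sequence container: per-epoch integer class indices (NA = unassigned),
# with the per-sample |r| matrix to every template kept for smoothing, and the
# per-sample GFP for whole-recording GEV.
ms_labels <- function(labels, corr, gfp, srate, class_labels,
                      subject_id = "s1",
                      group = c("seizure", "seizure_free", "control")) {
  group <- match.arg(group)
  stopifnot(is.list(labels), length(labels) == length(corr),
            length(labels) == length(gfp))
  structure(
    list(labels = labels, corr = corr, gfp = gfp, srate = srate,
         class_labels = class_labels, subject_id = as.character(subject_id),
         group = group),
    class = "ms_labels")
}

#' @export
print.ms_labels <- function(x, ...) {
  n <- sum(lengths(x$labels))
  cat(sprintf("<ms_labels> %s [%s]: %d epochs, %d samples @ %g Hz\n",
              x$subject_id, x$group, length(x$labels), n, x$srate))
  invisible(x)
}
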