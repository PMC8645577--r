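# Reading recordings and cohort manifests.

#' Read one subject's EEG recording
#'
#' Dispatches on file extension: \code{.edf} files go through [read_edf()];
#' anything else is read as a delimited numeric matrix (rows = channels,
#' columns = samples, microvolts) with an optional one-channel-name-per-line
#' sidecar file.
#'
#' @param path Path to the EEG file.
#' @param subject_id,group Cohort metadata for this recording.
#' @param srate Sampling rate in Hz; required for delimited matrices (EDF
#'   carries its own).
#' @param sidecar Path to a channel-name sidecar (one name per line). If
#'   \code{NULL}, \code{<path>.channels} is used when present.
#' @return An [ms_recording()].
#' @export
read_recording <- function(path, subject_id, group, srate = NULL,
                           sidecar = NULL) {
  if (!file.exists(path)) stop_io("cannot read recording file: %s", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    return(read_edf(path, subject_id = subject_id, group = group))
  if (is.null(srate))
    stop_io("srate is required for delimited matrix input: %s", path)
  dat <- tryCatch(
    as.matrix(utils::read.table(path, header = FALSE)),
    error = function(e) stop_io("cannot parse matrix file %s: %s", path,
                                conditionMessage(e)))
  storage.mode(dat) <- "double"
  channel_names <- NULL
  if (is.null(sidecar)) {
    cand <- paste0(path, ".channels")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar)) {
    channel_names <- readLines(sidecar)
    channel_names <- channel_names[nzchar(trimws(channel_names))]
    if (length(channel_names) != nrow(dat))
      stop_io("sidecar %s lists %d channels but %s has %d rows",
              sidecar, length(channel_names), path, nrow(dat))
  }
  ms_recording(dat, srate = srate, channel_names = channel_names,
               subject_id = subject_id, group = group)
}

#' Read a cohort manifest
#'
#' A delimited table with columns \code{subject_id}, \code{group},
#' \code{path}, and optionally \code{srate} and \code{sidecar}. Paths are
#' resolved relative to the manifest's directory.
#'
#' @param path Manifest file path.
#' @return A data frame, one row per recording.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io("cannot read manifest: %s", path)
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop_io("manifest %s lacks column(s): %s", path,
            paste(miss, collapse = ", "))
  bad <- setdiff(unique(m$group), .ms_groups)
  if (length(bad))
    stop_io("manifest has unknown group(s): %s", paste(bad, collapse = ", "))
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(base, m$path[rel])
  m
}

#' Read every recording listed in a manifest
#'
#' @param manifest A data frame from [read_manifest()] (or of that shape).
#' @return A list of [ms_recording()] objects, named by subject id.
#' @export
read_cohort <- function(manifest) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    read_recording(row$path, subject_id = row$subject_id, group = row$group,
                   srate = if ("srate" %in% names(row)) row$srate else NULL,
                   sidecar = if ("sidecar" %in% names(row) &&
                               nzchar(row$sidecar)) row$sidecar else NULL)
  })
  names(out) <- manifest$subject_id
  out
}
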