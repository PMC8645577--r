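# End-to-end pipeline: preprocess -> GFP peaks -> subject clustering ->
# group maps -> canonical ordering -> backfit -> parameter table.

#' Run the full microstate pipeline on a cohort of recordings
#'
#' For each subject: preprocess (band-pass, decimate, epoch, amplitude
#' screen, average reference), extract GFP-peak topographies, and fit
#' subject-level templates with the polarity-invariant modified K-means.
#' Subject templates are then pooled within each group into group-level
#' maps, ordered into the canonical A--D classes, and backfitted to every
#' sample of that group's subjects; labels are duration-smoothed and
#' summarised into the Duration/Frequency/Coverage table with per-subject
#' GEV.
#'
#' @param recordings List of [ms_recording()] objects (e.g.
#'   \code{make_cohort(cfg)$recordings} or [read_cohort()]).
#' @param band,target_srate,epoch_seconds,reject_uv,min_epochs Passed to
#'   [preprocess_subject()].
#' @param k,n_restarts,tol Passed to [modified_kmeans()].
#' @param smooth_ms,min_corr Passed to [smooth_labels()] / [backfit()].
#' @param reference_maps Canonical reference for class ordering; defaults to
#'   the built-in idealised maps when the channel space matches.
#' @param seed Master seed for all clustering restarts.
#' @param keep_labels Keep each subject's smoothed label sequence in the
#'   result (needed for label-level comparisons; off by default to save
#'   memory).
#' @param preprocessed Set \code{TRUE} when \code{recordings} is already a
#'   list of [ms_epochs()].
#' @return A list of class \code{ms_pipeline}: \code{table} and
#'   \code{summary} (see [build_cohort_table()]), \code{subject_maps},
#'   \code{group_maps} (named by group, canonically ordered),
#'   \code{gev_by_group} (mean subject GEV per group), and optionally
#'   \code{labels}.
#' @export
microstate_pipeline <- function(recordings, band = c(1, 40),
                                target_srate = 500, epoch_seconds = 2,
                                reject_uv = 100, min_epochs = 30,
                                k = 4, n_restarts = 20, tol = 1e-6,
                                smooth_ms = 20, min_corr = 0,
                                reference_maps = NULL, seed = 1,
                                keep_labels = FALSE, preprocessed = FALSE) {
  stopifnot(length(recordings) >= 1L)
  epochsets <- if (preprocessed) recordings else
    lapply(recordings, preprocess_subject, band = band,
           target_srate = target_srate, epoch_seconds = epoch_seconds,
           reject_uv = reject_uv, min_epochs = min_epochs)

  peaks <- lapply(epochsets, function(es) {
    g <- find_gfp_peaks(compute_gfp(es))
    peak_topographies(es, g)
  })
  subject_maps <- lapply(seq_along(epochsets), function(i) {
    modified_kmeans(peaks[[i]]$maps, k = k, n_restarts = n_restarts,
                    tol = tol, seed = seed + i,
                    channel_names = epochsets[[i]]$channel_names,
                    srate = epochsets[[i]]$srate, level = "subject")
  })
  names(subject_maps) <- vapply(epochsets, `[[`, "", "subject_id")

  groups <- vapply(epochsets, `[[`, "", "group")
  group_maps <- list()
  tables <- vector("list", length(epochsets))
  labels_out <- if (keep_labels) vector("list", length(epochsets)) else NULL
  for (grp in unique(groups)) {
    idx <- which(groups == grp)
    gm <- if (length(idx) >= 2L) {
      aggregate_group_maps(subject_maps[idx], k = k, seed = seed,
                           n_restarts = n_restarts, tol = tol)
    } else {
      subject_maps[[idx]]
    }
    ref <- reference_maps
    if (is.null(ref) && ncol(gm$maps) <= 64L) {
      mont <- standard_montage_64()[seq_len(ncol(gm$maps)), ]
      ref <- canonical_maps(mont)
    }
    if (!is.null(ref)) gm <- order_maps_canonical(gm, ref)
    group_maps[[grp]] <- gm
    for (i in idx) {
      ls <- backfit(epochsets[[i]], gm, min_corr = min_corr)
      ls <- smooth_labels(ls, min_duration_ms = smooth_ms)
      tables[[i]] <- compute_parameters(ls)
      if (keep_labels) labels_out[[i]] <- ls$labels
    }
  }
  cohort <- build_cohort_table(tables)
  gev_tab <- cohort$table[cohort$table$class == cohort$table$class[1L], ]
  gev_by_group <- tapply(gev_tab$gev, gev_tab$group, mean)
  if (keep_labels) names(labels_out) <- names(subject_maps)
  structure(
    list(table = cohort$table, summary = cohort$summary,
         subject_maps = subject_maps, group_maps = group_maps,
         gev_by_group = gev_by_group, labels = labels_out,
         settings = list(band = band, target_srate = target_srate,
                         epoch_seconds = epoch_seconds,
                         reject_uv = reject_uv, k = k,
                         n_restarts = n_restarts, smooth_ms = smooth_ms,
                         min_corr = min_corr, seed = seed)),
    class = "ms_pipeline")
}

#' @export
print.ms_pipeline <- function(x, ...) {
  cat(sprintf("<ms_pipeline> %d subjects, %d groups, K = %d\n",
              length(x$subject_maps), length(x$group_maps), x$settings$k))
  cat("mean subject GEV by group:\n")
  print(round(x$gev_by_group, 4))
  invisible(x)
}

#' Write template maps to disk
#'
#' Templates go to a delimited matrix (K rows x channels) with a JSON
#' sidecar holding labels, GEV and clustering provenance.
#'
#' @param maps An [ms_maps()].
#' @param path Output path for the matrix; the sidecar is
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_maps <- function(maps, path) {
  stopifnot(inherits(maps, "ms_maps"))
  utils::write.table(maps$maps, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(labels = maps$labels, level = maps$level, gev = maps$gev,
         channel_names = maps$channel_names,
         provenance = maps$provenance[setdiff(names(maps$provenance),
                                              c("assignment", "gev_trace"))]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read template maps written by [write_maps()]
#'
#' @param path Path to the delimited matrix.
#' @return An [ms_maps()].
#' @export
read_maps <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ms_maps(m, labels = meta$labels, level = meta$level, gev = meta$gev,
          channel_names = meta$channel_names,
          provenance = as.list(meta$provenance))
}
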