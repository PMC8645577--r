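# Backfitting templates to every sample, duration smoothing, and the
# Duration / Frequency / Coverage parameters.

#' Backfit microstate templates to every sample
#'
#' Labels each sample of each epoch with the template of largest absolute
#' spatial correlation. Samples whose best \code{|r|} falls below
#' \code{min_corr} are left unassigned (\code{NA}); the default 0 assigns
#' every sample. Ties go to the lower class index.
#'
#' @param es An average-referenced [ms_epochs()].
#' @param maps An [ms_maps()] in the same channel space.
#' @param min_corr Assignment threshold in \code{[0, 1]}.
#' @return An \code{ms_labels} object carrying per-epoch label vectors, the
#'   full per-sample \code{|r|} matrix to every template (used by
#'   [smooth_labels()]), and the per-sample GFP.
#' @export
backfit <- function(es, maps, min_corr = 0) {
  stopifnot(inherits(es, "ms_epochs"), inherits(maps, "ms_maps"),
            min_corr >= 0, min_corr <= 1)
  if (ncol(maps$maps) != n_channels(es))
    stop_io("maps have %d channels but epochs have %d",
            ncol(maps$maps), n_channels(es))
  if (!identical(es$reference, "average")) es <- average_reference(es)
  tm <- maps$maps
  out_labels <- vector("list", length(es$epochs))
  out_corr <- vector("list", length(es$epochs))
  out_gfp <- vector("list", length(es$epochs))
  for (e in seq_along(es$epochs)) {
    v <- center_cols(es$epochs[[e]])
    nrm <- sqrt(colSums(v^2))
    gfp <- nrm / sqrt(nrow(v))
    a <- tm %*% v                                  # K x T projections
    r <- abs(sweep(a, 2L, pmax(nrm, .Machine$double.eps), "/"))
    lab <- max.col(t(r), ties.method = "first")
    best <- r[cbind(lab, seq_along(lab))]
    lab[best < min_corr | nrm == 0] <- NA_integer_
    out_labels[[e]] <- lab
    out_corr[[e]] <- r
    out_gfp[[e]] <- gfp
  }
  ms_labels(out_labels, out_corr, out_gfp, srate = es$srate,
            class_labels = maps$labels, subject_id = es$subject_id,
            group = es$group)
}

#' Temporal smoothing of a label sequence by minimum duration
#'
#' Runs shorter than \code{min_duration_ms} are dissolved samplewise: each
#' sample of a short run is reassigned to whichever flanking run's template
#' correlates better (\code{|r|}) with that sample's topography, ties going
#' to the left flank. Runs touching an epoch edge are exempt — they may be
#' truncated continuations of a genuine state, so their observed length is
#' not evidence against them. Repeated until no interior run is short, or
#' ten passes.
#'
#' @param ls An \code{ms_labels} from [backfit()].
#' @param min_duration_ms Minimum accepted run length in milliseconds
#'   (default 20).
#' @param max_passes Iteration cap.
#' @return The smoothed \code{ms_labels}.
#' @export
smooth_labels <- function(ls, min_duration_ms = 20, max_passes = 10) {
  stopifnot(inherits(ls, "ms_labels"), min_duration_ms >= 0)
  min_samples <- round(min_duration_ms / 1000 * ls$srate)
  if (min_samples <= 1L) return(ls)
  for (e in seq_along(ls$labels)) {
    lab <- ls$labels[[e]]
    r <- ls$corr[[e]]
    for (pass in seq_len(max_passes)) {
      runs <- rle_runs(lab)
      short <- which(runs$length < min_samples &
                       runs$start > 1L & runs$end < length(lab) &
                       !is.na(runs$value))
      if (!length(short)) break
      for (i in short) {
        left <- lab[runs$start[i] - 1L]
        right <- lab[runs$end[i] + 1L]
        for (t in runs$start[i]:runs$end[i]) {
          rl <- if (is.na(left)) -Inf else r[left, t]
          rr <- if (is.na(right)) -Inf else r[right, t]
          if (is.infinite(rl) && is.infinite(rr)) next
          lab[t] <- if (rl >= rr) left else right
        }
      }
    }
    ls$labels[[e]] <- lab
  }
  ls
}

# Run-length encoding of a label vector: start, end, length, value per run
# (NA runs kept as NA-valued runs).
rle_runs <- function(lab) {
  n <- length(lab)
  if (n == 1L) {
    return(list(start = 1L, end = 1L, length = 1L, value = lab))
  }
  eq <- lab[-1L] == lab[-n]
  eq[is.na(eq)] <- FALSE
  same <- c(FALSE, eq | (is.na(lab[-1L]) & is.na(lab[-n])))
  start <- which(!same)
  end <- c(start[-1L] - 1L, n)
  list(start = start, end = end, length = end - start + 1L,
       value = lab[start])
}

#' Duration, Frequency and Coverage from planted or backfitted labels
#'
#' The single run-length code path shared by the analysis and the synthetic
#' generator's ground truth. Runs are maximal same-label stretches counted
#' within epochs (a run never spans an epoch boundary; edge-truncated runs
#' count). Per class: Duration is the mean run length in ms; Frequency the
#' number of runs per second of analysed time; Coverage the fraction of
#' analysed samples carrying the label. Analysed time excludes unassigned
#' samples, so \code{coverage = frequency * duration / 1000} holds exactly
#' per class and coverages sum to one whenever every sample is assigned.
#'
#' @param labels List of per-epoch integer label vectors (\code{NA} =
#'   unassigned).
#' @param srate Sampling rate in Hz.
#' @param k Number of classes.
#' @param class_labels Class tags (default A, B, ...).
#' @param subject_id,group Metadata copied into the rows.
#' @param gev Optional subject-level global explained variance to attach.
#' @return A data frame with one row per class: \code{subject_id},
#'   \code{group}, \code{class}, \code{duration_ms}, \code{frequency_per_s},
#'   \code{coverage}, \code{gev}. A class that never occurs has
#'   \code{duration_ms = NA}, frequency and coverage 0.
#' @export
parameters_from_labels <- function(labels, srate, k,
                                   class_labels = class_tags(k),
                                   subject_id = "s1", group = "control",
                                   gev = NA_real_) {
  stopifnot(is.list(labels), length(labels) >= 1L)
  n_runs <- numeric(k)
  n_samples <- numeric(k)
  total <- 0
  for (lab in labels) {
    runs <- rle_runs(lab)
    ok <- !is.na(runs$value)
    total <- total + sum(runs$length[ok])
    for (i in which(ok)) {
      v <- runs$value[i]
      n_runs[v] <- n_runs[v] + 1
      n_samples[v] <- n_samples[v] + runs$length[i]
    }
  }
  if (total == 0) stop_io("no assigned samples for subject %s", subject_id)
  total_s <- total / srate
  duration_ms <- ifelse(n_runs > 0, n_samples / n_runs * 1000 / srate,
                        NA_real_)
  frequency <- n_runs / total_s
  coverage <- n_samples / total
  data.frame(subject_id = subject_id, group = group, class = class_labels,
             duration_ms = duration_ms, frequency_per_s = frequency,
             coverage = coverage, gev = gev, stringsAsFactors = FALSE)
}

#' Compute the microstate parameters of one backfitted subject
#'
#' Wraps [parameters_from_labels()] for an \code{ms_labels} object and
#' attaches the subject's whole-recording GEV (GFP-squared-weighted mean of
#' the squared correlation to the assigned template over all assigned
#' samples).
#'
#' @param ls An \code{ms_labels} from [backfit()] / [smooth_labels()].
#' @return A data frame, one row per class (see [parameters_from_labels()]).
#' @export
compute_parameters <- function(ls) {
  stopifnot(inherits(ls, "ms_labels"))
  num <- 0
  den <- 0
  for (e in seq_along(ls$labels)) {
    lab <- ls$labels[[e]]
    ok <- !is.na(lab)
    if (!any(ok)) next
    g2 <- ls$gfp[[e]][ok]^2
    r <- ls$corr[[e]][cbind(lab[ok], which(ok))]
    num <- num + sum(g2 * r^2)
    den <- den + sum(g2)
  }
  gev <- if (den > 0) num / den else NA_real_
  parameters_from_labels(ls$labels, ls$srate, length(ls$class_labels),
                         class_labels = ls$class_labels,
                         subject_id = ls$subject_id, group = ls$group,
                         gev = gev)
}

#' Assemble the cohort parameter table and its group summary
#'
#' Binds per-subject parameter rows into one long table and derives the
#' group-level mean and SD per class and parameter — the layout of the
#' classic three-group microstate characteristics table. The per-subject
#' identity \code{coverage = frequency x duration} does not survive
#' averaging across subjects (the mean of a product is not the product of
#' means), so the summary reports means only.
#'
#' @param subject_tables List (or already-bound data frame) of per-subject
#'   parameter tables.
#' @return A list with \code{table} (long format) and \code{summary}
#'   (group x class x parameter means and SDs; SD is \code{NA} for
#'   single-subject groups).
#' @export
build_cohort_table <- function(subject_tables) {
  tab <- if (is.data.frame(subject_tables)) subject_tables
         else do.call(rbind, subject_tables)
  if (is.null(tab) || !nrow(tab)) stop_io("empty parameter table")
  miss <- setdiff(unique(tab$group), .ms_groups)
  if (length(miss))
    stop_io("unknown group(s) in table: %s", paste(miss, collapse = ", "))
  params <- c("duration_ms", "frequency_per_s", "coverage")
  cells <- expand.grid(group = unique(tab$group),
                       class = unique(tab$class),
                       parameter = params, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- tab$group == cells$group[i] & tab$class == cells$class[i]
    v <- tab[[cells$parameter[i]]][sel]
    v <- v[!is.na(v)]
    data.frame(group = cells$group[i], class = cells$class[i],
               parameter = cells$parameter[i],
               mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summ)
}
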