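# Global field power and its peaks.

#' Compute the global field power of an epoch set
#'
#' GFP at time t is the spatial standard deviation of the scalp potential
#' across channels: \code{sqrt(mean((v - mean(v))^2))}. Its local maxima mark
#' the moments of highest topographic signal-to-noise, which is where the
#' clustering operates. Input is expected average-referenced; if not, it is
#' re-referenced implicitly with a warning (GFP is only reference-invariant
#' under the average-reference convention).
#'
#' @param es An [ms_epochs()].
#' @return An object of class \code{ms_gfp}: per-epoch GFP vectors plus
#'   (initially empty) per-epoch peak index lists.
#' @export
compute_gfp <- function(es) {
  stopifnot(inherits(es, "ms_epochs"))
  if (!identical(es$reference, "average")) {
    warning("epochs are not average-referenced; re-referencing for GFP",
            call. = FALSE)
    es <- average_reference(es)
  }
  values <- lapply(es$epochs, function(e) sqrt(colMeans(center_cols(e)^2)))
  structure(list(values = values,
                 peaks = vector("list", length(values)),
                 srate = es$srate),
            class = "ms_gfp")
}

#' Locate GFP local maxima
#'
#' Strict local maxima within each epoch (\code{g[t-1] < g[t] > g[t+1]});
#' epoch edge samples are never peaks. With \code{min_separation > 1}, peaks
#' are greedily thinned: among peaks closer than the separation, the larger
#' one is kept.
#'
#' @param g An \code{ms_gfp} from [compute_gfp()].
#' @param min_separation Minimum distance between retained peaks, in samples.
#' @return \code{g} with \code{peaks} filled (per-epoch sample indices).
#' @export
find_gfp_peaks <- function(g, min_separation = 1) {
  stopifnot(inherits(g, "ms_gfp"), min_separation >= 1)
  g$peaks <- lapply(g$values, function(v) {
    n <- length(v)
    if (n < 3L) stop_io("epoch with %d samples is too short for peaks", n)
    mid <- 2L:(n - 1L)
    p <- mid[v[mid - 1L] < v[mid] & v[mid] > v[mid + 1L]]
    if (min_separation > 1 && length(p) > 1L) {
      ord <- p[order(v[p], decreasing = TRUE)]
      kept <- integer(0)
      for (idx in ord)
        if (!length(kept) || all(abs(kept - idx) >= min_separation))
          kept <- c(kept, idx)
      p <- sort(kept)
    }
    p
  })
  g
}

# Stack the topographies at GFP peaks of every epoch into a matrix
# (rows = peak maps), with the matching GFP values.
peak_topographies <- function(es, g) {
  stopifnot(inherits(es, "ms_epochs"), inherits(g, "ms_gfp"))
  if (!length(g$peaks) || all(lengths(g$peaks) == 0L))
    stop_io("no GFP peaks found; run find_gfp_peaks() first")
  maps <- do.call(rbind, lapply(seq_along(es$epochs), function(k) {
    p <- g$peaks[[k]]
    if (!length(p)) return(NULL)
    t(es$epochs[[k]][, p, drop = FALSE])
  }))
  gfp <- unlist(lapply(seq_along(g$values), function(k)
    g$values[[k]][g$peaks[[k]]]), use.names = FALSE)
  list(maps = maps, gfp = gfp)
}
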