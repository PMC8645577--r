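# Polarity-invariant modified K-means over GFP-peak topographies.

# Deterministic sign convention: flip each map so its largest-magnitude
# channel is positive (ties resolved by first index).
fix_map_signs <- function(maps) {
  for (k in seq_len(nrow(maps))) {
    i <- which.max(abs(maps[k, ]))
    if (maps[k, i] < 0) maps[k, ] <- -maps[k, ]
  }
  maps
}

#' Modified K-means clustering of topographic maps
#'
#' The microstate variant of K-means: each map is assigned to the template
#' with the largest squared spatial correlation (so a map and its polarity
#' flip are equivalent), and each template is updated as the first
#' eigenvector of its members' cross-product matrix — the polarity-invariant
#' analogue of the cluster mean. The objective is the GFP-squared-weighted
#' explained variance (GEV) over the input maps; it is non-decreasing across
#' iterations and the best of several random restarts is kept.
#'
#' @param peak_maps Numeric matrix, rows = topographies (e.g. from GFP
#'   peaks), columns = channels. Rows are average-referenced internally.
#' @param k Number of templates (4 for the canonical A--D classes).
#' @param n_restarts Random restarts; best final GEV wins.
#' @param max_iter Iteration cap per restart.
#' @param tol Convergence threshold on the absolute GEV change.
#' @param seed RNG seed making the restarts reproducible.
#' @param polarity_invariant If \code{FALSE}, assignment uses signed
#'   correlation and templates are normalised means (plain K-means on the
#'   sphere).
#' @param normalize Normalise each input map to unit GFP before clustering,
#'   giving every peak equal weight in the template update and the
#'   objective. The default \code{FALSE} keeps the GFP-squared weighting of
#'   the GEV definition itself, so low-GFP peaks — the moments where the
#'   topography is mostly noise — barely influence the templates.
#'   Assignment is correlation-based either way.
#' @param channel_names,srate Provenance carried into the result.
#' @param level \code{"subject"} or \code{"group"}.
#' @return An [ms_maps()] with \code{gev} set, plus provenance (seed,
#'   restarts, iteration GEV trace of the winning restart, assignment).
#' @export
modified_kmeans <- function(peak_maps, k = 4, n_restarts = 20,
                            max_iter = 100, tol = 1e-6, seed = 1,
                            polarity_invariant = TRUE, normalize = FALSE,
                            channel_names = NULL, srate = NA_real_,
                            level = c("subject", "group")) {
  level <- match.arg(level)
  x <- center_rows(as.matrix(peak_maps))
  n <- nrow(x)
  if (n < k) stop_io("need at least k=%d maps, got %d", k, n)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop_io("flat (zero) map among the inputs")
  gfp <- nrm / sqrt(ncol(x))
  u <- x / nrm                       # unit-norm rows for correlations
  xw <- if (normalize) u else x      # rows entering the template update
  w <- if (normalize) rep(1, n) else gfp^2  # GEV weights of the objective

  assign_step <- function(tmpl) {
    a <- u %*% t(tmpl)                       # n x k correlations
    score <- if (polarity_invariant) a^2 else a
    assign_ <- max.col(score, ties.method = "first")
    r <- a[cbind(seq_len(n), assign_)]
    r2 <- if (polarity_invariant) r^2 else pmax(r, 0)^2
    # re-seed empty clusters from the worst-fit map
    for (j in seq_len(k)) {
      if (!any(assign_ == j)) {
        worst <- which.min(r2)
        tmpl[j, ] <- u[worst, ]
        assign_[worst] <- j
        r2[worst] <- 1
      }
    }
    list(tmpl = tmpl, assign = assign_,
         gev = sum(w * r2) / sum(w))
  }

  run_once <- function() {
    tmpl <- u[sample.int(n, k), , drop = FALSE]
    gev_prev <- -Inf
    trace <- numeric(0)
    st <- NULL
    for (it in seq_len(max_iter)) {
      st <- assign_step(tmpl)
      tmpl <- st$tmpl
      trace <- c(trace, st$gev)
      if (is.finite(gev_prev) && abs(st$gev - gev_prev) < tol) break
      gev_prev <- st$gev
      for (j in seq_len(k)) {
        member <- xw[st$assign == j, , drop = FALSE]
        if (polarity_invariant) {
          v <- eigen(crossprod(member), symmetric = TRUE)$vectors[, 1L]
        } else {
          v <- colMeans(member)
        }
        v <- v - mean(v)
        nv <- sqrt(sum(v^2))
        if (nv > 0) tmpl[j, ] <- v / nv
      }
    }
    list(templates = tmpl, gev = st$gev, trace = trace, assign = st$assign)
  }

  best <- with_seed(seed, {
    b <- NULL
    for (r in seq_len(n_restarts)) {
      res <- run_once()
      if (is.null(b) || res$gev > b$gev) b <- res
    }
    b
  })
  maps <- fix_map_signs(best$templates)
  ms_maps(maps, labels = class_tags(k), level = level, gev = best$gev,
          channel_names = channel_names, srate = srate,
          provenance = list(seed = seed, n_restarts = n_restarts,
                            tol = tol, gev_trace = best$trace,
                            assignment = best$assign,
                            polarity_invariant = polarity_invariant))
}

#' Global explained variance of templates over GFP-peak maps
#'
#' \deqn{GEV = \sum_t GFP_t^2 r_t^2 / \sum_t GFP_t^2} where \eqn{r_t} is the
#' polarity-invariant spatial correlation between the map at peak \eqn{t} and
#' its assigned (best-matching) template.
#'
#' @param maps An [ms_maps()].
#' @param peak_maps Matrix of topographies, rows = maps.
#' @param gfp GFP value of each row; defaults to each row's own spatial SD.
#' @return GEV as a fraction in \code{[0, 1]}.
#' @export
compute_gev <- function(maps, peak_maps, gfp = NULL) {
  stopifnot(inherits(maps, "ms_maps"))
  x <- center_rows(as.matrix(peak_maps))
  if (ncol(x) != ncol(maps$maps))
    stop_io("channel count mismatch: maps have %d, data has %d",
            ncol(maps$maps), ncol(x))
  nrm <- sqrt(rowSums(x^2))
  if (is.null(gfp)) gfp <- nrm / sqrt(ncol(x))
  tot <- sum(gfp^2)
  if (tot == 0) stop_io("total GFP is zero; cannot compute GEV")
  ok <- nrm > 0
  u <- x[ok, , drop = FALSE] / nrm[ok]
  r2 <- (u %*% t(maps$maps))^2
  best <- apply(r2, 1L, max)
  sum(gfp[ok]^2 * best) / tot
}

#' Aggregate subject-level maps into group-level maps
#'
#' Pools every subject's templates (each subject contributing K unit-norm
#' maps, so subjects are weighted equally regardless of how many epochs or
#' GFP peaks they had) and reruns the modified K-means on the pooled set.
#'
#' @param subject_maps List of [ms_maps()] (one per subject, same channels).
#' @param k Number of group templates.
#' @param seed RNG seed for the clustering restarts.
#' @param ... Passed to [modified_kmeans()].
#' @return An [ms_maps()] with \code{level = "group"}.
#' @export
aggregate_group_maps <- function(subject_maps, k = 4, seed = 1, ...) {
  if (!is.list(subject_maps) || length(subject_maps) < 2L)
    stop_io("group aggregation needs maps from at least 2 subjects")
  nc <- vapply(subject_maps, function(m) ncol(m$maps), 0L)
  if (length(unique(nc)) != 1L)
    stop_io("subjects have mismatched channel counts: %s",
            paste(unique(nc), collapse = ", "))
  pooled <- do.call(rbind, lapply(subject_maps, function(m) m$maps))
  modified_kmeans(pooled, k = k, seed = seed, level = "group",
                  channel_names = subject_maps[[1L]]$channel_names,
                  srate = subject_maps[[1L]]$srate, ...)
}

#' Order maps into the canonical A--D classes
#'
#' Finds the one-to-one assignment between the supplied maps and a reference
#' set that maximises the total absolute spatial correlation, searching all
#' K! permutations exactly (trivial for K = 4). Maps are reordered, relabelled
#' with the reference labels, and sign-aligned to the reference.
#'
#' @param maps An [ms_maps()] to relabel.
#' @param reference An [ms_maps()] of the same K and channel space; defaults
#'   to the built-in idealised A--D patterns on the standard 64-channel
#'   montage when the channel counts allow it.
#' @return The reordered [ms_maps()]; the achieved per-class \code{|r|} is
#'   stored in \code{provenance$match_r}.
#' @export
order_maps_canonical <- function(maps, reference = NULL) {
  stopifnot(inherits(maps, "ms_maps"))
  if (is.null(reference)) reference <- canonical_maps()
  stopifnot(inherits(reference, "ms_maps"))
  k <- nrow(maps$maps)
  if (nrow(reference$maps) != k)
    stop_io("reference has %d maps, expected %d", nrow(reference$maps), k)
  if (ncol(reference$maps) != ncol(maps$maps))
    stop_io("reference channel space (%d) does not match maps (%d)",
            ncol(reference$maps), ncol(maps$maps))
  r <- abs(maps$maps %*% t(reference$maps))   # unit-norm rows both sides
  perms <- permutations_of(k)
  score <- apply(perms, 1L, function(p) sum(r[cbind(p, seq_len(k))]))
  best <- perms[which.max(score), ]           # best[j] = map index for class j
  out <- maps
  out$maps <- maps$maps[best, , drop = FALSE]
  # sign-align to the reference for display consistency
  for (j in seq_len(k)) {
    if (sum(out$maps[j, ] * reference$maps[j, ]) < 0)
      out$maps[j, ] <- -out$maps[j, ]
  }
  out$labels <- reference$labels
  rownames(out$maps) <- out$labels
  out$provenance$match_r <- r[cbind(best, seq_len(k))]
  out$provenance$permutation <- best
  out
}

# All permutations of 1..n as rows (n small).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-i]
      out[row, ] <- c(i, rest[sub[s, ]])
      row <- row + 1L
    }
  }
  out
}
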