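# Idealised 64-channel extended 10/20 montage and canonical template maps.

#' Idealised 64-channel extended 10/20 montage
#'
#' Two-dimensional electrode layout on the unit disc: \code{x} runs left
#' (negative) to right, \code{y} posterior (negative) to anterior. Positions
#' are schematic (rows at fixed \code{y}, electrodes spread over the head
#' width at that row), adequate for synthesising and labelling smooth
#' topographies; no manufacturer coordinates are claimed.
#'
#' @return A data frame with columns \code{name}, \code{x}, \code{y}.
#' @export
standard_montage_64 <- function() {
  rows <- list(
    list(y = 0.92,  ch = c("Fp1", "Fpz", "Fp2")),
    list(y = 0.72,  ch = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.52,  ch = c("F7", "F5", "F3", "F1", "Fz",
                           "F2", "F4", "F6", "F8")),
    list(y = 0.28,  ch = c("FT7", "FC5", "FC3", "FC1", "FCz",
                           "FC2", "FC4", "FC6", "FT8")),
    list(y = 0.00,  ch = c("T7", "C5", "C3", "C1", "Cz",
                           "C2", "C4", "C6", "T8")),
    list(y = -0.28, ch = c("TP7", "CP5", "CP3", "CP1", "CPz",
                           "CP2", "CP4", "CP6", "TP8")),
    list(y = -0.52, ch = c("P7", "P5", "P3", "P1", "Pz",
                           "P2", "P4", "P6", "P8")),
    list(y = -0.72, ch = c("PO7", "PO5", "PO3", "POz", "PO4",
                           "PO6", "PO8")),
    list(y = -0.90, ch = c("O1", "Oz", "O2")),
    list(y = -1.00, ch = c("Iz")))
  out <- do.call(rbind, lapply(rows, function(r) {
    n <- length(r$ch)
    half <- sqrt(max(1 - r$y^2, 0.01))
    x <- if (n == 1L) 0 else seq(-half, half, length.out = n)
    data.frame(name = r$ch, x = x, y = r$y, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

gauss2d <- function(x, y, x0, y0, s) exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2))

#' Idealised canonical microstate template maps (classes A--D)
#'
#' Smooth dipolar scalp patterns on a 2-D montage matching the standard
#' orientations of the four canonical resting-state classes: A with a
#' left--right diagonal axis (left-posterior to right-frontal), B its mirror
#' (right--left), C an anterior--posterior axis, and D a fronto-central
#' maximum with a diffuse surround. Maps are average-referenced and
#' unit-norm; the pairwise absolute correlation between classes stays at or
#' below 0.5.
#'
#' @param montage Electrode layout as from [standard_montage_64()].
#' @param k Number of templates; only \code{k <= 4} patterns are defined.
#' @param jitter Standard deviation of optional Gaussian perturbation added
#'   to each map before renormalising (0 = deterministic ideal maps).
#' @param seed RNG seed used when \code{jitter > 0}.
#' @return An [ms_maps()] with \code{k} rows.
#' @export
make_templates <- function(montage = standard_montage_64(), k = 4,
                           jitter = 0, seed = 1) {
  if (k > 4)
    stop_io("only the 4 canonical map orientations are built in; k=%d", k)
  x <- montage$x
  y <- montage$y
  pat <- rbind(
    A = gauss2d(x, y, -0.80, -0.35, 0.55) - gauss2d(x, y, 0.70, 0.65, 0.55),
    B = gauss2d(x, y,  0.80, -0.35, 0.55) - gauss2d(x, y, -0.70, 0.65, 0.55),
    C = gauss2d(x, y,  0.00, -0.90, 0.45) - gauss2d(x, y, 0.00, 0.90, 0.60),
    D = gauss2d(x, y,  0.00,  0.20, 0.45) -
      0.5 * gauss2d(x, y, 0.00, 0.20, 0.90))
  pat <- pat[seq_len(k), , drop = FALSE]
  if (jitter > 0) {
    pat <- with_seed(seed, pat + matrix(stats::rnorm(length(pat), sd = jitter),
                                        nrow = nrow(pat)))
  }
  ms_maps(pat, labels = class_tags(k), level = "group",
          channel_names = montage$name)
}

#' Built-in canonical reference maps for class ordering
#'
#' The idealised A--D patterns of [make_templates()] on the standard
#' 64-channel montage, used as the default reference by
#' [order_maps_canonical()].
#'
#' @param montage Electrode layout; defaults to [standard_montage_64()].
#' @return An [ms_maps()] with 4 rows.
#' @export
canonical_maps <- function(montage = standard_montage_64()) {
  make_templates(montage, k = 4, jitter = 0)
}

# Row-normalised Gaussian spatial smoothing kernel over electrode distances,
# used to give synthetic noise a realistic spatial correlation structure.
montage_smoother <- function(montage, sigma = 0.35) {
  d2 <- outer(montage$x, montage$x, "-")^2 + outer(montage$y, montage$y, "-")^2
  w <- exp(-d2 / (2 * sigma^2))
  w / rowSums(w)
}
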