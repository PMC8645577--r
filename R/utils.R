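# Internal helpers shared across modules.

.ms_groups <- c("seizure", "seizure_free", "control")
.ms_class_labels <- c("A", "B", "C", "D")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Class tags for K clusters: A..D for K <= 4, then E, F, ...
class_tags <- function(k) {
  stopifnot(k >= 1, k <= 26)
  LETTERS[seq_len(k)]
}

#' Spatial correlation between two scalp topographies
#'
#' Pearson correlation across channels between two potential maps. Maps are
#' centred (average-referenced) before the product, so the result equals the
#' cosine similarity of the zero-mean vectors. With
#' \code{polarity_invariant = TRUE} (the microstate convention) the absolute
#' value is returned, treating a map and its polarity flip as identical.
#'
#' @param a,b Numeric vectors of equal length (one value per channel).
#' @param polarity_invariant Return \code{|r|} instead of signed \code{r}.
#' @return A correlation in \code{[-1, 1]} (or \code{[0, 1]} when polarity
#'   invariant); 0 if either map is flat.
#' @export
spatial_correlation <- function(a, b, polarity_invariant = TRUE) {
  stopifnot(length(a) == length(b))
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  r <- sum(a * b) / (na * nb)
  if (polarity_invariant) abs(r) else r
}

# Centre each row of a matrix (rows = maps/topographies).
center_rows <- function(x) {
  x - rowMeans(x)
}

# Centre each column (columns = time points, rows = channels).
center_cols <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

stop_io <- function(...) stop(sprintf(...), call. = FALSE)
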