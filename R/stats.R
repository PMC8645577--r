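# Three-group comparison: Wilks-Lambda MANOVA over the class profile,
# post-hoc one-way ANOVAs, pairwise pooled-t contrasts, Bonferroni alpha.

#' Wilks' Lambda one-way MANOVA on a response matrix
#'
#' Computes the within-group (E) and between-group (H) SSCP matrices,
#' \eqn{\Lambda = \det(E)/\det(E + H)}, Rao's F approximation with its
#' degrees of freedom, and the multivariate effect size
#' \eqn{\eta^2 = 1 - \Lambda^{1/s}} with
#' \eqn{s = \sqrt{(p^2 q^2 - 4)/(p^2 + q^2 - 5)}} (the SPSS "multivariate
#' eta squared" convention).
#'
#' @param y Numeric response matrix, one row per subject, \code{p} columns.
#' @param group Factor (or coercible) of group membership, one per row.
#' @return A list of class \code{ms_manova}: \code{wilks_lambda},
#'   \code{f_stat}, \code{df} (numerator, denominator), \code{p_value},
#'   \code{eta_squared}, plus \code{E}, \code{H} and the dimensions.
#' @export
wilks_manova <- function(y, group) {
  y <- as.matrix(y)
  group <- droplevels(as.factor(group))
  g <- nlevels(group)
  n <- nrow(y)
  p <- ncol(y)
  if (g < 2L) stop_io("need at least 2 groups")
  if (n < p + g) stop_io("need at least p + g = %d subjects, got %d",
                         p + g, n)
  grand <- colMeans(y)
  E <- matrix(0, p, p)
  H <- matrix(0, p, p)
  for (lev in levels(group)) {
    yg <- y[group == lev, , drop = FALSE]
    mg <- colMeans(yg)
    cg <- sweep(yg, 2L, mg, "-")
    E <- E + crossprod(cg)
    H <- H + nrow(yg) * tcrossprod(mg - grand)
  }
  detE <- det(E)
  detT <- det(E + H)
  if (!is.finite(detE) || detE <= 0 || detT <= 0)
    stop_io("singular within-group SSCP: consider dropping a response %s",
            "column or pooling classes")
  lambda <- detE / detT
  q <- g - 1
  ve <- n - g
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  w <- ve + q - (p + q + 1) / 2
  df2 <- w * s - p * q / 2 + 1
  lam_s <- lambda^(1 / s)
  f <- if (lam_s > 0) (1 - lam_s) / lam_s * df2 / df1 else Inf
  structure(
    list(wilks_lambda = lambda, f_stat = f, df = c(df1, df2),
         p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
         eta_squared = 1 - lam_s, s = s, E = E, H = H,
         n = n, p = p, groups = levels(group)),
    class = "ms_manova")
}

#' @export
print.ms_manova <- function(x, ...) {
  cat(sprintf(
    "Wilks' Lambda = %.3f, F(%g, %g) = %.3f, p = %.4g, eta^2 = %.3f\n",
    x$wilks_lambda, x$df[1L], x$df[2L], x$f_stat, x$p_value, x$eta_squared))
  invisible(x)
}

#' MANOVA over the four-class profile of one microstate parameter
#'
#' The mixed-design analysis of a three-group cohort via the multivariate
#' approach to repeated measures: each subject contributes a 4-vector (one
#' value per class) of the chosen parameter. With
#' \code{effect = "interaction"} (default) the MANOVA is run on the
#' within-subject class-difference contrasts (p = K - 1), testing whether
#' the class profile differs between groups — the group-by-class interaction,
#' and the test whose Lambda, F and eta-squared structure a three-group,
#' four-class design reports as its headline statistics.
#' \code{effect = "profile"} runs the MANOVA on the raw K-column profile.
#'
#' @param table Long parameter table (from [build_cohort_table()]).
#' @param parameter One of \code{"duration"}, \code{"frequency"},
#'   \code{"coverage"}.
#' @param effect Which multivariate test to run (see above).
#' @return An \code{ms_manova} (see [wilks_manova()]).
#' @export
manova_wilks <- function(table, parameter = c("duration", "frequency",
                                              "coverage"),
                         effect = c("interaction", "profile")) {
  parameter <- match.arg(parameter)
  effect <- match.arg(effect)
  wide <- table_to_wide(table, parameter)
  y <- wide$y
  if (effect == "interaction") {
    k <- ncol(y)
    contr <- diff(diag(k))        # successive class differences, (k-1) x k
    y <- y %*% t(contr)
  }
  wilks_manova(y, wide$group)
}

param_column <- function(parameter) {
  switch(parameter, duration = "duration_ms",
         frequency = "frequency_per_s", coverage = "coverage")
}

# Reshape the long table into subjects x classes for one parameter.
# Subjects with a missing value in any class are dropped listwise.
table_to_wide <- function(table, parameter) {
  col <- param_column(parameter)
  classes <- sort(unique(table$class))
  subjects <- unique(table$subject_id)
  y <- matrix(NA_real_, length(subjects), length(classes),
              dimnames = list(subjects, classes))
  grp <- character(length(subjects))
  names(grp) <- subjects
  for (i in seq_len(nrow(table))) {
    y[table$subject_id[i], table$class[i]] <- table[[col]][i]
    grp[table$subject_id[i]] <- table$group[i]
  }
  keep <- rowSums(is.na(y)) == 0L
  if (!all(keep))
    message(sprintf("dropping %d subject(s) with missing %s values",
                    sum(!keep), parameter))
  list(y = y[keep, , drop = FALSE], group = grp[keep])
}

#' Post-hoc one-way ANOVAs per microstate class
#'
#' For each class, a fixed-effects one-way ANOVA of the chosen parameter
#' across groups (df = (g - 1, N - g)), followed by all pairwise group
#' contrasts using the pooled-error t statistic on N - g degrees of freedom
#' with unadjusted p-values; each p is meant to be compared against the
#' Bonferroni-corrected alpha reported alongside.
#'
#' @param table Long parameter table.
#' @param parameter \code{"duration"}, \code{"frequency"} or
#'   \code{"coverage"}.
#' @param classes Classes to test (default: all present).
#' @param family_alpha Familywise alpha; the per-test threshold is
#'   \code{family_alpha / (n_groups * n_classes)}.
#' @return A list of class \code{ms_posthoc}: per-class data frame
#'   \code{anova} (f, df1, df2, p), data frame \code{pairwise} (class, pair,
#'   difference, t, p), and \code{alpha_bonferroni}.
#' @export
posthoc_anova <- function(table, parameter = c("duration", "frequency",
                                               "coverage"),
                          classes = NULL, family_alpha = 0.05) {
  parameter <- match.arg(parameter)
  col <- param_column(parameter)
  if (is.null(classes)) classes <- sort(unique(table$class))
  n_classes_family <- length(sort(unique(table$class)))
  groups <- sort(unique(table$group))
  if (length(groups) < 2L) stop_io("post-hoc ANOVA needs >= 2 groups")
  alpha_b <- bonferroni_alpha(family_alpha, length(groups), n_classes_family)

  res <- lapply(classes, function(cl) {
    sub <- table[table$class == cl & !is.na(table[[col]]), ]
    v <- sub[[col]]
    grp <- droplevels(factor(sub$group, levels = groups))
    sizes <- table(grp)
    if (any(sizes < 2L))
      stop_io("class %s: every group needs >= 2 subjects", cl)
    n <- length(v)
    g <- nlevels(grp)
    fit <- stats::aov(v ~ grp)
    an <- suppressWarnings(stats::anova(fit))  # degeneracy handled below
    mse <- an["Residuals", "Mean Sq"]
    # degeneracy detected relative to the overall scale of the data
    eps <- 1e-10 * (sum(v^2) / n + .Machine$double.xmin)
    if (an["grp", "Mean Sq"] < eps && mse < eps) {
      # fully degenerate: all observations identical
      f <- 0; p <- 1
    } else if (mse < eps) {
      message(sprintf("class %s: zero within-group variance", cl))
      f <- Inf; p <- 0
    } else {
      f <- an["grp", "F value"]
      p <- an["grp", "Pr(>F)"]
    }
    pairs <- utils::combn(levels(grp), 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
      m1 <- mean(v[grp == g1]); m2 <- mean(v[grp == g2])
      se <- sqrt(mse * (1 / sizes[[g1]] + 1 / sizes[[g2]]))
      tt <- if (se > 0) (m1 - m2) / se else if (m1 == m2) 0 else Inf
      data.frame(class = cl, pair = paste(g1, g2, sep = " vs "),
                 difference = m1 - m2, t = tt,
                 p = 2 * stats::pt(-abs(tt), n - g),
                 stringsAsFactors = FALSE)
    }))
    list(anova = data.frame(class = cl, f = f, df1 = g - 1, df2 = n - g,
                            p = p, stringsAsFactors = FALSE),
         pairwise = pw)
  })
  structure(
    list(parameter = parameter,
         anova = do.call(rbind, lapply(res, `[[`, "anova")),
         pairwise = do.call(rbind, lapply(res, `[[`, "pairwise")),
         alpha_bonferroni = alpha_b),
    class = "ms_posthoc")
}

#' @export
print.ms_posthoc <- function(x, ...) {
  cat(sprintf("Post-hoc one-way ANOVA of %s (Bonferroni alpha = %.6f)\n",
              x$parameter, x$alpha_bonferroni))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Bonferroni-corrected alpha for the microstate comparison family
#'
#' @param family_alpha Familywise error rate (default 0.05).
#' @param n_groups Number of groups compared.
#' @param n_classes Number of microstate classes tested.
#' @return \code{family_alpha / (n_groups * n_classes)}.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, n_groups = 3,
                             n_classes = 4) {
  stopifnot(family_alpha > 0, n_groups > 0, n_classes > 0)
  family_alpha / (n_groups * n_classes)
}
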