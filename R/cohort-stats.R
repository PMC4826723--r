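# Cohort statistics: subgroup assignment (EF/WM/LGE labels), two-group
# comparisons (Welch t or Wilcoxon rank sum after a normality check),
# Pearson correlation and Bland-Altman agreement analysis.

#' Assign EF/WM/LGE subgroup labels to subject records
#'
#' Labels follow the standard clinical rules: `EF+` for preserved ejection
#' fraction (>= 50%), `EF-` otherwise; `WM+` when at least one of the 16 AHA
#' wall-motion segments is graded worse than mildly hypokinetic (grade > 1);
#' LGE status is passed through. Records with missing EF are dropped with a
#' warning.
#'
#' @param records data frame with at least `subject_id` and `ef_pct`;
#'   an optional logical/`"LGE+"`-style `lge` column is normalized.
#' @param wm_grades matrix or data frame of 16 per-segment wall-motion grades
#'   (0-5) per subject, rows aligned with `records`; or `NULL` to skip WM
#'   labelling.
#' @param ef_cut preserved-EF threshold in percent (default 50).
#' @return `records` as a tibble with added `ef_label` and (when grades are
#'   given) `wm_label` columns, and a normalized `lge_label` if `lge` exists.
#' @export
assign_subgroups <- function(records, wm_grades = NULL, ef_cut = 50) {
  records <- tibble::as_tibble(records)
  if (is.null(records[["ef_pct"]])) stop("records must contain an `ef_pct` column")
  if (!is.null(wm_grades)) {
    wm_grades <- as.matrix(wm_grades)
    if (ncol(wm_grades) != 16) stop("wall-motion grades must have 16 segments")
    if (any(!wm_grades %in% 0:5)) stop("wall-motion grades must be integers 0-5")
    if (nrow(wm_grades) != nrow(records)) {
      stop("one row of grades per record required")
    }
    records$wm_label <- ifelse(apply(wm_grades, 1, function(g) any(g > 1)),
                               "WM+", "WM-")
  }
  missing_ef <- !is.finite(records$ef_pct)
  if (any(missing_ef)) {
    warning(sum(missing_ef), " record(s) excluded for missing EF")
    records <- records[!missing_ef, , drop = FALSE]
  }
  records$ef_label <- ifelse(records$ef_pct >= ef_cut, "EF+", "EF-")
  if (!is.null(records[["lge"]])) {
    records$lge_label <- ifelse(records[["lge"]] %in% c(TRUE, "LGE+", "+", 1),
                                "LGE+", "LGE-")
  }
  records
}

#' Compare a parameter between two groups
#'
#' Both samples are first checked for normality (Shapiro-Wilk at
#' `alpha_normality`); if both pass, a two-sample unequal-variance (Welch)
#' t-test is used, otherwise the Wilcoxon rank-sum test. Two-sided p-values.
#'
#' @param a,b numeric vectors (n >= 3 each).
#' @param name_a,name_b group names for the output.
#' @param alpha_normality significance level of the normality check
#'   (default 0.05).
#' @return one-row tibble: group names and sizes, means +/- SD, `test_used`
#'   (`"welch_t"` or `"wilcoxon"`), `p_value`.
#' @export
compare_groups <- function(a, b, name_a = "a", name_b = "b",
                           alpha_normality = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) stop("need at least 3 values per group")
  if (var(a) == 0 && var(b) == 0) stop("zero variance in both groups")
  normal <- function(x) {
    if (var(x) == 0) return(FALSE)
    shapiro.test(x)$p.value >= alpha_normality
  }
  if (normal(a) && normal(b)) {
    test_used <- "welch_t"
    p <- t.test(a, b, var.equal = FALSE)$p.value
  } else {
    test_used <- "wilcoxon"
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  }
  tibble::tibble(
    group_a = name_a, group_b = name_b,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), sd_a = sd(a),
    mean_b = mean(b), sd_b = sd(b),
    test_used = test_used, p_value = p
  )
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (var(x) == 0 || var(y) == 0) stop("constant input: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Bland-Altman agreement analysis
#'
#' Differences `x - y` per pair: mean difference, SD, limits of agreement
#' (mean +/- 1.96 SD) and the mean relative error, defined as the mean over
#' pairs of `|difference| / pair mean x 100` (pairs with zero mean are
#' excluded from the relative error with a warning). An alternative global
#' definition `|mean difference| / grand mean x 100` is available.
#'
#' @param x,y paired numeric vectors, length >= 2.
#' @param relative one of `"pairwise"` (default) or `"global"`.
#' @return An object of class `bland_altman`: one-row tibble with `n`,
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `relative_error_pct`;
#'   the per-pair means and differences are kept in attribute `pairs`.
#' @export
bland_altman <- function(x, y, relative = c("pairwise", "global")) {
  relative <- match.arg(relative)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  diffs <- x - y
  means <- (x + y) / 2
  md <- mean(diffs)
  sdd <- sd(diffs)
  rel <- if (relative == "pairwise") {
    nz <- means != 0
    if (any(!nz)) warning(sum(!nz), " pair(s) with zero mean excluded from relative error")
    if (!any(nz)) NA_real_ else mean(abs(diffs[nz]) / abs(means[nz])) * 100
  } else {
    gm <- mean(means)
    if (gm == 0) NA_real_ else abs(md) / abs(gm) * 100
  }
  out <- tibble::tibble(
    n = length(x), mean_diff = md, sd_diff = sdd,
    loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
    relative_error_pct = rel
  )
  structure(out, class = c("bland_altman", class(out)),
            pairs = tibble::tibble(mean = means, diff = diffs))
}

#' Bland-Altman plot
#'
#' @param object a [bland_altman()] result.
#' @param ... unused.
#' @return a ggplot object: per-pair differences against pair means with the
#'   mean difference (solid) and limits of agreement (dashed).
#' @export
autoplot.bland_altman <- function(object, ...) {
  pairs <- attr(object, "pairs")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_diff) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Pair mean", y = "Difference",
                  title = sprintf("Mean diff %.3f, LoA [%.3f, %.3f]",
                                  object$mean_diff, object$loa_low,
                                  object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Torsion-curve plot
#'
#' @param object a `torsion_curve` from [torsion_curve()].
#' @param ... unused.
#' @return a ggplot object of torsion versus time with the peak marked.
#' @export
autoplot.torsion_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t_ms, y = .data$torsion_deg_per_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = tibble::tibble(t_ms = attr(object, "t_peak_ms"),
                                              torsion_deg_per_mm = attr(object, "T_max")),
                        colour = "red") +
    ggplot2::labs(
      x = "Time (ms)", y = "Torsion (deg/mm)",
      title = sprintf("%s torsion, %s (T_max = %.3f deg/mm at %.0f ms)",
                      paste(attr(object, "slice_pair"), collapse = "-"),
                      attr(object, "layer"), attr(object, "T_max"),
                      attr(object, "t_peak_ms"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom dplyr .data
NULL
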