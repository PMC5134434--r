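# Method-agreement statistics: paired t-test, Bland-Altman limits of
# agreement, and R^2, as used to compare image-processing measurements with
# caliper / water-displacement references.

#' Paired t-test
#'
#' Classical paired t with `df = n - 1`, two-sided p-value and 95% CI of the
#' mean difference.
#'
#' @param x,y Paired measurements of equal length (n >= 2).
#' @return List with `t`, `df`, `p_value`, `ci95` (length 2), `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  if (sd(d) == 0)
    stop("differences have zero variance; paired t is degenerate", call. = FALSE)
  ht <- t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, ci95 = as.numeric(ht$conf.int),
       mean_diff = unname(ht$estimate))
}

#' Bland-Altman limits of agreement
#'
#' Differences `x - y`; limits `mean(d) +/- 1.96 sd(d)` with the normal
#' quantile 1.96 fixed by convention. The paired-t comparison is included
#' when the differences are non-degenerate.
#'
#' @param x,y Paired measurements of equal length (n >= 2).
#' @return An `agreement_summary`: list with `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `t_statistic`, `p_value`, `ci95`, `n`,
#'   `differences`, `averages` (scatter data for a Bland-Altman plot).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need n >= 2 pairs", call. = FALSE)
  d <- x - y
  m <- mean(d); s <- sd(d)
  tt <- if (s > 0) paired_t(x, y) else list(t = NA_real_, p_value = NA_real_,
                                            ci95 = c(m, m))
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 t_statistic = tt$t, p_value = tt$p_value, ci95 = tt$ci95,
                 n = length(d), differences = d, averages = (x + y) / 2),
            class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  mean difference: %.4g (sd %.4g)\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  95%% limits of agreement: [%.4g, %.4g]\n",
              x$loa_low, x$loa_high))
  if (is.finite(x$t_statistic))
    cat(sprintf("  paired t = %.3f, p = %.4g, 95%% CI [%.4g, %.4g]\n",
                x$t_statistic, x$p_value, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Coefficient of determination
#'
#' Squared Pearson correlation of `x` and `y`.
#'
#' @param x,y Numeric vectors (>= 3 points, non-constant).
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need >= 3 paired points", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant input; R^2 undefined", call. = FALSE)
  cor(x, y)^2
}
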