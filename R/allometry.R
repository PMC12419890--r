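#' Power-law (allometric) fit on log10-transformed data
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`. The slope is the
#' scaling exponent, `10^intercept` the prefactor (the value of `y` at
#' `x = 1`), and the exponent's confidence interval is the standard
#' t-interval on the slope.
#'
#' @param x,y positive numeric vectors of equal length `>= 3` (e.g. body
#'   mass in mg and edge radius in nm).
#' @param conf_level confidence level for the exponent interval;
#'   default 0.95.
#' @return An object of class `power_law_fit`: `exponent`, `exponent_ci`,
#'   `prefactor`, `r_squared`, `n`, and the underlying `lm` fit.
#' @examples
#' m <- 10^seq(0.3, 1.7, length.out = 8)
#' fit_power_law(m, 3 * m^-0.87)   # exponent -0.87, r^2 = 1
#' @export
fit_power_law <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  }
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("all values must be positive and finite; offending %s: %s",
                 if (length(bad) == 1L) "index" else "indices",
                 paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  lx <- log10(x)
  ly <- log10(y)
  fit <- stats::lm(ly ~ lx)
  # noiseless records are legitimate oracles; their zero residual makes
  # summary.lm (inside confint) warn about a perfect fit
  ci <- suppressWarnings(stats::confint(fit, "lx", level = conf_level))
  # computed directly: summary.lm warns on the noiseless fits used as
  # oracles elsewhere
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(
    list(exponent = unname(stats::coef(fit)[2L]),
         exponent_ci = c(ci[1L], ci[2L]),
         prefactor = 10^unname(stats::coef(fit)[1L]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n = length(x),
         conf_level = conf_level,
         fit = fit),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit (n = %d): y = %.4g * x^%.3g, r^2 = %.3f\n",
    x$n, x$prefactor, x$exponent, x$r_squared))
  cat(sprintf("  %d%% CI on exponent: [%.3g, %.3g]\n",
              round(100 * x$conf_level), x$exponent_ci[1L],
              x$exponent_ci[2L]))
  invisible(x)
}

#' Ratio of group mean forces with a bootstrap interval
#'
#' `mean(group_a) / mean(group_b)` with a seeded percentile bootstrap
#' interval (resampling each group independently with replacement). Uses
#' the caller's RNG state; set a seed beforehand for reproducibility.
#'
#' @param group_a,group_b numeric force vectors (nonempty).
#' @param n_boot bootstrap resamples; default 2000.
#' @param conf_level interval level; default 0.95.
#' @return List with `ratio`, `ci` (length 2) and `n_boot`.
#' @export
group_force_ratio <- function(group_a, group_b, n_boot = 2000,
                              conf_level = 0.95) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (mean(group_b) == 0) {
    stop("mean of the denominator group is zero", call. = FALSE)
  }
  ratio <- mean(group_a) / mean(group_b)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(group_a, replace = TRUE)) /
      mean(sample(group_b, replace = TRUE))
  }, 0)
  alpha <- (1 - conf_level) / 2
  list(ratio = ratio,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
       n_boot = n_boot)
}
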