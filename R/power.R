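## Analytic power. The between-ancestry Q statistic for two pooled
## estimates is (b_A - b_E)^2 / (V_A + V_E); under a true effect-size
## difference delta it is noncentral chi-square with 1 df and
## noncentrality delta^2 / V, V the total variance of the difference.

#' Power of the between-ancestry heterogeneity test
#'
#' Noncentrality `ncp = delta_beta^2 / total_variance`; the test rejects
#' when the statistic exceeds the upper-`alpha` quantile `c` of the
#' central chi-square with `df` degrees of freedom, so power is the
#' noncentral upper tail at `c`. For `df = 1` this is evaluated through
#' the exact two-sided normal form
#' `1 - (pnorm(sqrt(c) - sqrt(ncp)) - pnorm(-sqrt(c) - sqrt(ncp)))`;
#' higher df use the noncentral chi-square CDF.
#'
#' @param delta_beta between-group difference of log-odds effects.
#' @param total_variance variance of the difference of the pooled
#'   estimates (`V = V_A + V_E`), positive. The Immunochip discovery
#'   analysis motivating the defaults had median total variance 0.0030.
#' @param alpha significance level (default the Immunochip-wide 1.9e-6).
#' @param df degrees of freedom (default 1, the two-ancestry contrast).
#' @return Power in \[0, 1\].
#' @examples
#' power_het(0.31, 0.0030)  # ~0.81 at the chip-wide threshold
#' @export
power_het <- function(delta_beta, total_variance, alpha = 1.9e-6, df = 1) {
  if (any(total_variance <= 0)) stop_data("total_variance must be > 0")
  if (any(alpha <= 0 | alpha >= 1)) stop_data("alpha must be in (0, 1)")
  ncp <- delta_beta^2 / total_variance
  crit <- qchisq(alpha, df, lower.tail = FALSE)
  if (df == 1) {
    1 - (pnorm(sqrt(crit) - sqrt(ncp)) - pnorm(-sqrt(crit) - sqrt(ncp)))
  } else {
    pchisq(crit, df, ncp = ncp, lower.tail = FALSE)
  }
}

#' Minimum detectable between-ancestry effect difference
#'
#' Smallest `delta_beta` reaching `target_power` at the given variance and
#' level, found by monotone bisection to an absolute tolerance of 1e-6
#' (power is strictly increasing in the difference, so the root exists
#' and is unique).
#'
#' @inheritParams power_het
#' @param target_power desired power in (0, 1).
#' @return The minimal detectable difference (log-odds scale).
#' @examples
#' min_detectable_delta(0.0030, target_power = 0.80)  # just under 0.31
#' @export
min_detectable_delta <- function(total_variance, alpha = 1.9e-6,
                                 target_power = 0.80, df = 1) {
  if (total_variance <= 0) stop_data("total_variance must be > 0")
  if (target_power <= 0 || target_power >= 1)
    stop_data("target_power must be in (0, 1)")
  lo <- 0
  hi <- sqrt(total_variance)
  while (power_het(hi, total_variance, alpha, df) < target_power) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (power_het(mid, total_variance, alpha, df) >= target_power)
      hi <- mid else lo <- mid
  }
  hi
}

#' Power grid over effect differences and total variances
#'
#' Evaluates [power_het()] elementwise; rows index `deltas`, columns index
#' `variances`. Power is nondecreasing along rows and nonincreasing along
#' columns.
#'
#' @param deltas ascending vector of effect-size differences.
#' @param variances ascending vector of total variances.
#' @inheritParams power_het
#' @return An object of class `"power_grid"`: matrix of power values with
#'   `deltas`/`variances` attributes.
#' @export
power_grid <- function(deltas, variances, alpha = 1.9e-6, df = 1) {
  if (!length(deltas) || !length(variances))
    stop_data("deltas and variances must be nonempty")
  if (is.unsorted(deltas) || is.unsorted(variances))
    stop_data("deltas and variances must be ascending")
  g <- outer(deltas, variances,
             function(d, v) power_het(d, v, alpha = alpha, df = df))
  dimnames(g) <- list(delta = format(deltas), variance = format(variances))
  structure(g, deltas = deltas, variances = variances, alpha = alpha,
            df = df, class = c("power_grid", "matrix"))
}

#' @export
print.power_grid <- function(x, digits = 3, ...) {
  cat(sprintf("Heterogeneity-test power grid (alpha = %.3g, df = %d)\n",
              attr(x, "alpha"), attr(x, "df")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Plot power against effect-size difference, one curve per variance
#'
#' @param x a `"power_grid"`.
#' @param target optional horizontal reference power (default 0.8).
#' @param ... passed to [graphics::plot()].
#' @export
plot.power_grid <- function(x, target = 0.8, ...) {
  deltas <- attr(x, "deltas"); variances <- attr(x, "variances")
  plot(range(deltas), c(0, 1), type = "n", xlab = "beta difference",
       ylab = "power", ...)
  for (j in seq_along(variances))
    lines(deltas, x[, j], col = j)
  abline(h = target, lty = 2, col = "grey40")
  legend("bottomright", legend = paste("V =", format(variances)),
         col = seq_along(variances), lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Power of a single-population case-control association test
#'
#' Wald-test power under additive allele coding. The sampling variance of
#' the log-odds estimate is approximated by the null score variance,
#' `se^2 = 1 / (2 * n_total * maf * (1 - maf) * case_fraction *
#' (1 - case_fraction))`; power is the two-sided normal tail at
#' `z = log(or_alt) / se`. Used to show that an allele common in one
#' population but rare in another can be undetectable in the second at
#' realistic sample sizes.
#'
#' @param maf minor allele frequency in (0, 0.5\].
#' @param or_alt alternative odds ratio (> 0).
#' @param n_total total sample size (cases + controls).
#' @param case_fraction proportion of cases in (0, 1). No published value
#'   exists for a summary-level cohort; when the caller does not supply
#'   one, 0.25 is used and the assumption is logged via `message()`.
#' @param alpha two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
power_association <- function(maf, or_alt, n_total, case_fraction = NULL,
                              alpha = 1.9e-6) {
  if (maf <= 0 || maf > 0.5) stop_data("maf must be in (0, 0.5]")
  if (or_alt <= 0) stop_data("or_alt must be positive")
  if (n_total < 2) stop_data("n_total too small")
  if (is.null(case_fraction)) {
    case_fraction <- 0.25
    message("power_association: case_fraction not supplied; assuming 0.25")
  }
  if (case_fraction <= 0 || case_fraction >= 1)
    stop_data("case_fraction must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop_data("alpha must be in (0, 1)")
  se <- 1 / sqrt(2 * n_total * maf * (1 - maf) *
                   case_fraction * (1 - case_fraction))
  mu <- abs(log(or_alt)) / se
  zcrit <- qnorm(alpha / 2, lower.tail = FALSE)
  pnorm(mu - zcrit) + pnorm(-mu - zcrit)
}
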