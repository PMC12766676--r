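#' Chi-square test of expected proportions
#'
#' Pearson goodness-of-fit test of observed cell counts against a vector of
#' expected proportions: the statistic is `sum((O - E)^2 / E)` with
#' `E_i = total * p_i` and `df = cells - 1`; the p-value comes from the
#' asymptotic chi-square upper tail with no continuity correction. A warning
#' is emitted when any expected count falls below 5, where the asymptotic
#' approximation degrades.
#'
#' @param observed non-negative integer counts, one per cell (>= 2 cells).
#' @param expected expected proportions, summing to 1.
#' @return one-row tibble with `statistic`, `df`, `p_raw`.
#' @export
chi_square_expected <- function(observed, expected) {
  if (length(observed) < 2 || length(observed) != length(expected)) {
    abort(
      "`observed` and `expected` must have equal length >= 2.",
      class = "sunburstmeta_error_stats"
    )
  }
  if (any(observed < 0) || any(is.na(observed))) {
    abort("Counts must be non-negative.", class = "sunburstmeta_error_stats")
  }
  if (sum(observed) < 1) {
    abort("Total observed count must be >= 1.", class = "sunburstmeta_error_stats")
  }
  if (any(expected <= 0)) {
    abort("Expected proportions must be positive.", class = "sunburstmeta_error_stats")
  }
  if (abs(sum(expected) - 1) > 1e-8) {
    abort("Expected proportions must sum to 1.", class = "sunburstmeta_error_stats")
  }
  e <- sum(observed) * expected
  if (any(e < 5)) {
    warn(
      sprintf("Expected count below 5 in %d cell(s); chi-square p-value is approximate.",
              sum(e < 5)),
      class = "sunburstmeta_warning_small_expected"
    )
  }
  fit <- suppressWarnings(chisq.test(observed, p = expected, correct = FALSE))
  tibble(
    statistic = unname(fit$statistic),
    df = as.integer(unname(fit$parameter)),
    p_raw = unname(fit$p.value)
  )
}

#' Benjamini-Hochberg correction
#'
#' Step-up false-discovery-rate adjustment of a family of p-values. The
#' adjusted values are order-preserving, capped at 1, and satisfy the
#' step-up property (each adjusted value is the running minimum, from the
#' largest p down, of `p * m / rank`).
#'
#' @param p_values p-values in `[0, 1]`.
#' @return adjusted p-values, in the input order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].", class = "sunburstmeta_error_stats")
  }
  p.adjust(p_values, method = "BH")
}

#' z-difference test between two experiments
#'
#' Tests whether two chance-normalized preferences differ: the statistic is
#' the difference in z values minus the difference in shuffle means, divided
#' by the square root of the summed shuffle variances, with a two-sided
#' normal p-value. The shuffle mean and variance of each experiment are
#' obtained by pushing its own resampled chance draws through the
#' normalization, not assumed standard normal (by construction they come out
#' at ~0 and ~1, but they are computed from the stored draws).
#'
#' @param z_a,z_b normalized preference values to compare.
#' @param null_a,null_b the [chance_null()] objects the z values were
#'   normalized against.
#' @return one-row tibble with `statistic`, `p_raw` and the computed shuffle
#'   moments.
#' @export
z_difference_test <- function(z_a, z_b, null_a, null_b) {
  stopifnot(inherits(null_a, "chance_null"), inherits(null_b, "chance_null"))
  shuffle_z_a <- normalize_pct(null_a$draws, null_a)$z
  shuffle_z_b <- normalize_pct(null_b$draws, null_b)$z
  m_a <- mean(shuffle_z_a); m_b <- mean(shuffle_z_b)
  s2_a <- stats::var(shuffle_z_a); s2_b <- stats::var(shuffle_z_b)
  if (s2_a + s2_b <= 0) {
    abort("Summed shuffle variance is zero.", class = "sunburstmeta_error_stats")
  }
  stat <- ((z_a - z_b) - (m_a - m_b)) / sqrt(s2_a + s2_b)
  tibble(
    statistic = stat,
    p_raw = 2 * pnorm(-abs(stat)),
    shuffle_mean_a = m_a, shuffle_mean_b = m_b,
    shuffle_var_a = s2_a, shuffle_var_b = s2_b
  )
}

#' Gaussian density summary for mean +/- SD sources
#'
#' Some source studies report only the mean and standard deviation of the
#' chosen alley number. This evaluates the corresponding normal probability
#' density on a grid of alley positions so such studies can be visualised
#' alongside full choice distributions. The density is the continuous
#' normal pdf; it is not renormalized over the discrete grid.
#'
#' @param mean,sd reported moments, in alley-number units (`sd > 0`).
#' @param grid alley positions at which to evaluate.
#' @return tibble with `position` and `density`.
#' @export
gaussian_density_summary <- function(mean, sd, grid) {
  if (!is.numeric(sd) || length(sd) != 1 || sd <= 0) {
    abort("`sd` must be a single positive number.", class = "sunburstmeta_error_stats")
  }
  tibble(position = grid, density = dnorm(grid, mean = mean, sd = sd))
}
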