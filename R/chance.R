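#' Resampling-based chance distribution for path choices
#'
#' Builds the reference distribution for per-path choice percentages under
#' the null hypothesis that each of `n` subjects picks one of `k` available
#' (non-excluded) paths uniformly at random. Each of the `resamples` draws
#' reallocates all `n` choices across the `k` paths (a multinomial draw,
#' identical to tabulating `n` iid uniform path picks) and converts the
#' counts to percentages. Because paths are exchangeable under this null,
#' the per-path percentages from every resample are pooled into a single
#' reference: `mu_r` and `sigma_r` are the mean and standard deviation of
#' all `k * resamples` pooled values, giving one chance band per experiment.
#'
#' One-sided percentage thresholds are derived from the pooled moments:
#' `thr_05 = mu_r + 1.650 * sigma_r` (p = 0.05) and
#' `thr_01 = mu_r + 2.326 * sigma_r` (p = 0.01). These identities hold
#' exactly by construction.
#'
#' @param n number of scored choices (>= 1).
#' @param k number of non-excluded paths (>= 2).
#' @param resamples number of resamples (default 1000).
#' @param seed integer seed; identical `(n, k, resamples, seed)` give a
#'   bit-identical result and the caller's RNG state is left untouched.
#' @return an object of class `chance_null` with fields `n`, `k`,
#'   `resamples`, `seed`, `mu_r`, `sigma_r`, `thr_05`, `thr_01` and the
#'   pooled resampled percentages in `draws`.
#' @seealso [closed_form_null()] for the analytic binomial moments,
#'   [normalize_pct()] for chance normalization.
#' @export
chance_null <- function(n, k, resamples = 1000, seed = 1) {
  if (!is.numeric(n) || n < 1) {
    abort("`n` must be >= 1 scored choices.", class = "sunburstmeta_error_null")
  }
  if (!is.numeric(k) || k < 2) {
    abort("Chance is degenerate with fewer than 2 paths.", class = "sunburstmeta_error_null")
  }
  if (!is.numeric(resamples) || resamples < 1) {
    abort("`resamples` must be >= 1.", class = "sunburstmeta_error_null")
  }
  n <- as.integer(n); k <- as.integer(k); resamples <- as.integer(resamples)
  counts <- with_seed(seed, rmultinom(resamples, size = n, prob = rep(1 / k, k)))
  draws <- as.numeric(counts) * 100 / n
  mu_r <- mean(draws)
  sigma_r <- sd(draws)
  structure(
    list(
      n = n, k = k, resamples = resamples, seed = as.integer(seed),
      mu_r = mu_r, sigma_r = sigma_r,
      thr_05 = mu_r + 1.650 * sigma_r,
      thr_01 = mu_r + 2.326 * sigma_r,
      draws = draws
    ),
    class = "chance_null"
  )
}

#' @export
print.chance_null <- function(x, ...) {
  cat(
    sprintf(
      "<chance_null> n = %d choices over k = %d paths (%d resamples, seed %d)\n",
      x$n, x$k, x$resamples, x$seed
    ),
    sprintf("  mu_r = %.4f%%  sigma_r = %.4f%%\n", x$mu_r, x$sigma_r),
    sprintf("  thresholds: %.4f%% (p = 0.05), %.4f%% (p = 0.01)\n", x$thr_05, x$thr_01),
    sep = ""
  )
  invisible(x)
}

#' @rdname chance_null
#' @param x a `chance_null` object.
#' @param ... unused.
#' @method tidy chance_null
#' @export
tidy.chance_null <- function(x, ...) {
  tibble(
    n = x$n, k = x$k, resamples = x$resamples, seed = x$seed,
    mu_r = x$mu_r, sigma_r = x$sigma_r, thr_05 = x$thr_05, thr_01 = x$thr_01
  )
}

#' @rdname chance_null
#' @method glance chance_null
#' @export
glance.chance_null <- function(x, ...) tidy(x)

#' Closed-form chance moments
#'
#' Analytic counterpart of [chance_null()]: under uniform random choice each
#' path's count is Binomial(n, 1/k), so the per-path percentage has mean
#' `100 / k` and standard deviation `100 * sqrt((1/k) * (1 - 1/k) / n)`.
#' Used as the independent oracle for the resampler.
#'
#' @inheritParams chance_null
#' @return tibble with columns `mu` and `sigma` (percent units).
#' @export
closed_form_null <- function(n, k) {
  if (!is.numeric(n) || any(n < 1)) {
    abort("`n` must be >= 1 scored choices.", class = "sunburstmeta_error_null")
  }
  if (!is.numeric(k) || any(k < 2)) {
    abort("Chance is degenerate with fewer than 2 paths.", class = "sunburstmeta_error_null")
  }
  tibble(
    n = as.integer(n), k = as.integer(k),
    mu = 100 / k,
    sigma = 100 * sqrt((1 / k) * (1 - 1 / k) / n)
  )
}

#' Chance normalization (z)
#'
#' Normalizes observed per-path percentages against a chance reference:
#' `z = (observed - mu_r) / sigma_r`. The normalization is linear and
#' strictly increasing in the observed percentage and puts experiments with
#' different numbers of paths or subjects on a common scale.
#'
#' @param observed observed percentage(s).
#' @param null a [chance_null()] object.
#' @return tibble with columns `observed` and `z`.
#' @export
normalize_pct <- function(observed, null) {
  stopifnot(inherits(null, "chance_null"))
  if (!is.numeric(observed)) {
    abort("`observed` must be numeric percentages.", class = "sunburstmeta_error_null")
  }
  if (null$sigma_r <= 0) {
    abort(
      "Normalization undefined: chance distribution has zero spread.",
      class = "sunburstmeta_error_null"
    )
  }
  tibble(observed = observed, z = (observed - null$mu_r) / null$sigma_r)
}

#' Is an observed percentage above chance?
#'
#' Tests strict exceedance of a chance criterion: an observed value exactly
#' at a threshold is \emph{not} above chance. `level` may be `0.05` or
#' `0.01` (the percentage thresholds derived from the resampled null) or any
#' other single number, which is interpreted as a z cutoff applied to the
#' normalized value (e.g. `1.96`, the criterion used for experiment
#' categorization).
#'
#' @inheritParams normalize_pct
#' @param level `0.05`, `0.01`, or a z cutoff.
#' @return logical, same length as `observed`.
#' @export
above_chance <- function(observed, null, level = 0.05) {
  stopifnot(inherits(null, "chance_null"))
  if (!is.numeric(level) || length(level) != 1L || is.na(level)) {
    abort(
      "`level` must be 0.05, 0.01 or a numeric z cutoff.",
      class = "sunburstmeta_error_null"
    )
  }
  if (isTRUE(all.equal(level, 0.05))) {
    observed > null$thr_05
  } else if (isTRUE(all.equal(level, 0.01))) {
    observed > null$thr_01
  } else {
    normalize_pct(observed, null)$z > level
  }
}

#' @rdname chance_null
#' @param object a `chance_null` object.
#' @method autoplot chance_null
#' @export
autoplot.chance_null <- function(object, ...) {
  df <- tibble(pct = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$mu_r, linetype = "solid") +
    ggplot2::geom_vline(xintercept = object$thr_05, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$thr_01, linetype = "dotted") +
    ggplot2::labs(
      x = "per-path percentage under random choice",
      y = "pooled resamples",
      title = sprintf("Chance distribution (n = %d, k = %d)", object$n, object$k),
      subtitle = "dashed: p = 0.05 threshold; dotted: p = 0.01"
    )
}
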