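#' Sign-flip permutation test for paired differences
#'
#' Distribution-free two-sided test of whether paired per-experiment
#' differences are centred on zero. The statistic is the mean difference;
#' under the null each experiment's difference is symmetric about zero, so
#' the sign of each difference is flipped independently. For `length(delta)
#' <= exact_limit` the full set of `2^n` sign patterns is enumerated and the
#' p-value is the exact proportion of patterns whose |mean| is at least the
#' observed |mean| (the identity pattern included). Otherwise `n_perm`
#' random sign patterns are drawn and the add-one estimate
#' `(1 + hits) / (n_perm + 1)` is reported.
#'
#' @param delta numeric vector of paired differences.
#' @param n_perm number of sampled sign flips (default 10000).
#' @param seed integer seed for the sampled version.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   `NULL` enumerates automatically when `length(delta) <= exact_limit`.
#' @param exact_limit size up to which enumeration is automatic.
#' @return tibble with `statistic` (observed mean difference), `p_value`,
#'   `n`, `exact` and `n_perm` (NA when exact).
#' @export
sign_flip_test <- function(delta, n_perm = 10000, seed = 1, exact = NULL,
                           exact_limit = 20) {
  delta <- delta[!is.na(delta)]
  n <- length(delta)
  if (n == 0) {
    abort("No paired differences to test.", class = "sunburstmeta_error_contrast")
  }
  obs <- mean(delta)
  tol <- 1e-12 * max(1, abs(obs))
  if (is.null(exact)) exact <- n <= exact_limit
  if (exact && n > 30) {
    abort("Exhaustive enumeration requested for n > 30.", class = "sunburstmeta_error_contrast")
  }
  if (exact) {
    # all subset sums of delta: flipping subset S gives sum(delta) - 2 * sum(S)
    subset_sums <- 0
    for (d in delta) subset_sums <- c(subset_sums, subset_sums + d)
    perm_means <- (sum(delta) - 2 * subset_sums) / n
    p <- mean(abs(perm_means) >= abs(obs) - tol)
    n_perm_used <- NA_integer_
  } else {
    perm_means <- with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n_perm)
      as.numeric(signs %*% delta) / n
    })
    p <- (1 + sum(abs(perm_means) >= abs(obs) - tol)) / (n_perm + 1)
    n_perm_used <- as.integer(n_perm)
  }
  tibble(statistic = obs, p_value = p, n = n, exact = exact, n_perm = n_perm_used)
}

# Shared machinery for the paired role contrasts. `role_flag` selects the
# two candidate paths per experiment; `primary_flag` names which of the two
# is the focal side.
paired_role_contrast <- function(data, role_flag, primary_flag,
                                 primary_label, alternative_label,
                                 resamples, seed, z_cut, n_perm,
                                 require_above_chance = TRUE) {
  pcts <- path_percentages(data)
  sizes <- experiment_sizes(data) |>
    dplyr::arrange(.data$study_id, .data$experiment_id) |>
    dplyr::mutate(null_seed = as.integer(seed) + dplyr::row_number() - 1L)

  rows <- purrr::pmap(sizes, function(study_id, experiment_id, n, k, null_seed) {
    d <- pcts[pcts$study_id == study_id & pcts$experiment_id == experiment_id, ]
    cand <- d[d[[role_flag]], , drop = FALSE]
    if (nrow(cand) != 2 || sum(cand[[primary_flag]]) != 1) return(NULL)
    null <- chance_null(n, k, resamples = resamples, seed = null_seed)
    z <- normalize_pct(cand$pct, null)$z
    prim <- which(cand[[primary_flag]])
    alt <- which(!cand[[primary_flag]])
    tibble(
      study_id = study_id, experiment_id = experiment_id,
      path_primary = cand$path_index[prim],
      path_alternative = cand$path_index[alt],
      pct_primary = cand$pct[prim], pct_alternative = cand$pct[alt],
      z_primary = z[prim], z_alternative = z[alt],
      delta = z[prim] - z[alt],
      primary_above = z[prim] > z_cut,
      alternative_above = z[alt] > z_cut
    )
  })
  table <- dplyr::bind_rows(rows)
  if (require_above_chance && nrow(table) > 0) {
    table <- dplyr::filter(table, .data$primary_above | .data$alternative_above)
  }
  if (nrow(table) == 0) {
    summary <- tibble(
      n_experiments = 0L, pct_primary_above = NA_real_,
      pct_alternative_above = NA_real_, mean_delta = NA_real_,
      p_value = NA_real_, empty = TRUE
    )
  } else {
    test <- sign_flip_test(table$delta, n_perm = n_perm, seed = seed)
    summary <- tibble(
      n_experiments = nrow(table),
      pct_primary_above = 100 * mean(table$primary_above),
      pct_alternative_above = 100 * mean(table$alternative_above),
      mean_delta = test$statistic,
      p_value = test$p_value,
      empty = FALSE
    )
  }
  structure(
    list(
      table = table, summary = summary,
      primary_label = primary_label, alternative_label = alternative_label
    ),
    class = "sunburst_contrast"
  )
}

#' Paired contrast between the two adjacent paths
#'
#' Compares, across experiments, chance-normalized preference for one
#' adjacent path against the other. `mode = "intersect"` contrasts the
#' adjacent path more likely to intersect the training route beyond the
#' block ("intersect") with the other adjacent path ("alternative");
#' `mode = "first_turn"` contrasts the adjacent path heading in the same
#' direction as the first turn of the training route ("training") with the
#' other one. Only experiments with both adjacent paths flagged, an
#' unambiguous focal side, and at least one adjacent path chosen at an
#' above-chance level enter the contrast. The group-level test is a seeded
#' two-sided sign-flip permutation test on the per-experiment z differences.
#'
#' @param data validated experiment tibble.
#' @param mode `"intersect"` or `"first_turn"`.
#' @param resamples,seed,z_cut chance-model parameters as in
#'   [categorize_experiments()].
#' @param n_perm permutations for the group test (exhaustive enumeration is
#'   used automatically for 20 or fewer experiments).
#' @return a `sunburst_contrast` object: `tidy()` returns the
#'   per-experiment table (z for each side and their difference `delta`),
#'   `glance()` the group summary (percent of experiments above chance on
#'   each side and the permutation p-value). An empty result (no eligible
#'   experiments) is flagged in `glance()$empty`.
#' @export
adjacent_contrast <- function(data, mode = c("intersect", "first_turn"),
                              resamples = 1000, seed = 1, z_cut = 1.96,
                              n_perm = 10000) {
  mode <- match.arg(mode)
  data <- validate_experiments(data)
  paired_role_contrast(
    data,
    role_flag = "is_adjacent",
    primary_flag = if (mode == "intersect") "intersects_training" else "matches_first_turn",
    primary_label = if (mode == "intersect") "intersect" else "training",
    alternative_label = "alternative",
    resamples = resamples, seed = seed, z_cut = z_cut, n_perm = n_perm
  )
}

#' Paired contrast between the two outer paths
#'
#' As [adjacent_contrast()], for the two outermost paths of the array.
#' `mode = "reward_side"` contrasts the outer path on the rewarded side of
#' the maze ("reward") with the other outer path; `mode = "first_turn"`
#' contrasts the outer path heading in the direction of the first training
#' turn ("training") with the other one.
#'
#' @inheritParams adjacent_contrast
#' @param mode `"reward_side"` or `"first_turn"`.
#' @export
outer_contrast <- function(data, mode = c("reward_side", "first_turn"),
                           resamples = 1000, seed = 1, z_cut = 1.96,
                           n_perm = 10000) {
  mode <- match.arg(mode)
  data <- validate_experiments(data)
  paired_role_contrast(
    data,
    role_flag = "is_outer",
    primary_flag = if (mode == "reward_side") "reward_side" else "matches_first_turn",
    primary_label = if (mode == "reward_side") "reward" else "training",
    alternative_label = "alternative",
    resamples = resamples, seed = seed, z_cut = z_cut, n_perm = n_perm
  )
}

#' @export
print.sunburst_contrast <- function(x, ...) {
  cat(sprintf(
    "<sunburst_contrast> %s vs. %s, %d experiment(s)\n",
    x$primary_label, x$alternative_label, nrow(x$table)
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname adjacent_contrast
#' @param x,object a `sunburst_contrast` object.
#' @param ... unused.
#' @method tidy sunburst_contrast
#' @export
tidy.sunburst_contrast <- function(x, ...) x$table

#' @rdname adjacent_contrast
#' @method glance sunburst_contrast
#' @export
glance.sunburst_contrast <- function(x, ...) x$summary

#' @rdname adjacent_contrast
#' @method autoplot sunburst_contrast
#' @export
autoplot.sunburst_contrast <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$table,
    c("z_primary", "z_alternative"),
    names_to = "side", values_to = "z"
  ) |>
    dplyr::mutate(side = ifelse(
      .data$side == "z_primary", object$primary_label, object$alternative_label
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$side, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 1.96, linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(group = .data$experiment_id), colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = NULL, y = "preference relative to chance (z)",
      title = sprintf("%s vs. %s", object$primary_label, object$alternative_label),
      subtitle = "dashed line: z = 1.96 chance criterion"
    )
}

#' Empirical confidence intervals over the distribution of experiments
#'
#' Percentile intervals of a per-experiment statistic, computed from the
#' experiments themselves (no model). By default the statistic is the
#' difference between the shortcut and adjacent role z values of each
#' experiment, summarising shortcut-vs-adjacent preference across studies;
#' alternatively pass a numeric vector with one value per experiment.
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), so intervals at increasing levels are
#' nested.
#'
#' @param x validated experiment tibble, or a numeric vector of
#'   per-experiment statistic values.
#' @param levels interval coverage percentages.
#' @param ... chance-model parameters passed to [categorize_experiments()]
#'   when `x` is a dataset.
#' @return tibble with `level`, `lower`, `upper`.
#' @export
experiment_distribution_ci <- function(x, levels = c(90, 95, 99), ...) {
  values <- if (is.numeric(x)) {
    x
  } else {
    cats <- categorize_experiments(x, ...)
    if (!all(c("z_shortcut", "z_adjacent") %in% names(cats))) {
      abort(
        "Dataset must have shortcut and adjacent roles for the default statistic.",
        class = "sunburstmeta_error_contrast"
      )
    }
    cats$z_shortcut - cats$z_adjacent
  }
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort(
      "At least 2 experiments are required for a distribution interval.",
      class = "sunburstmeta_error_contrast"
    )
  }
  purrr::map_dfr(sort(levels), function(lv) {
    alpha <- (100 - lv) / 200
    qq <- quantile(values, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
    tibble(level = lv, lower = qq[1], upper = qq[2])
  })
}
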