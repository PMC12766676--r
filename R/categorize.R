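#' Per-role choice percentages
#'
#' Summarises each experiment's per-path percentages by path role. Roles
#' spanning a single path (shortcut, cued) report that path's percentage;
#' roles that can span two paths (adjacent, outer) report the arithmetic
#' mean of their member paths. A path carrying several role flags (e.g. a
#' shortcut that is also adjacent) contributes to each of its roles. Paths
#' with no role flag pool into `other`, reported as the \emph{maximum}
#' single-path percentage among them: the `other` category reflects an
#' unremarkable path winning outright, not the average unremarkable path.
#'
#' @param data validated experiment tibble.
#' @return long tibble with columns `study_id`, `experiment_id`, `role`,
#'   `pct` and `n_paths` (member paths of the role). Roles with no member
#'   path in an experiment are absent.
#' @export
role_percentages <- function(data) {
  pcts <- path_percentages(data)
  one_role <- function(d, role, member, summary_fun) {
    d <- d[member(d), , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    d |>
      dplyr::group_by(.data$study_id, .data$experiment_id) |>
      dplyr::summarise(
        role = role, pct = summary_fun(.data$pct), n_paths = dplyr::n(),
        .groups = "drop"
      )
  }
  dplyr::bind_rows(
    one_role(pcts, "shortcut", function(d) d$is_shortcut, mean),
    one_role(pcts, "adjacent", function(d) d$is_adjacent, mean),
    one_role(pcts, "outer", function(d) d$is_outer, mean),
    one_role(pcts, "cued", function(d) d$is_cued, mean),
    one_role(
      pcts, "other",
      function(d) {
        !d$is_shortcut & !d$is_adjacent & !d$is_outer & !d$is_cued & !d$is_training
      },
      max
    )
  ) |>
    dplyr::mutate(role = factor(.data$role, levels = ROLE_PRIORITY)) |>
    dplyr::arrange(.data$study_id, .data$experiment_id, .data$role)
}

#' Categorize experiments by preferred path role
#'
#' Assigns each experiment to the path role with the highest (role-averaged)
#' percentage among roles chosen at an above-chance rate, using each
#' experiment's own resampled chance distribution built from its `(n, k)`.
#' The default criterion is exceeding the chance distribution by more than
#' 1.96 standard deviations of the pooled null; the percentage thresholds at
#' p = 0.05 / p = 0.01 are available for sensitivity analysis via
#' `criterion`. Ties between above-chance roles are resolved by the priority
#' order shortcut > adjacent > outer > cued > other, which deliberately
#' biases results towards positive shortcutting. If no role is above chance
#' the experiment is categorized as `no_pref`.
#'
#' Because the null is identical across the paths of an experiment,
#' averaging member-path percentages before normalizing is exactly
#' equivalent to averaging the member paths' z values.
#'
#' @param data validated experiment tibble.
#' @param resamples resamples per experiment's chance distribution.
#' @param seed base seed; experiment `i` (in `study_id`, `experiment_id`
#'   order) uses `seed + i - 1`, so results do not depend on row order.
#' @param z_cut z criterion for "above chance" (default 1.96).
#' @param criterion `"z"` (default; uses `z_cut`), `"p05"` or `"p01"`
#'   (percentage thresholds of the resampled null).
#' @return a tibble of class `sunburst_categories`: one row per experiment
#'   with `category`, `winning_role`, per-role percentages (`pct_*`) and
#'   normalized values (`z_*`), and the null parameters used.
#' @export
categorize_experiments <- function(data, resamples = 1000, seed = 1,
                                   z_cut = 1.96,
                                   criterion = c("z", "p05", "p01")) {
  criterion <- match.arg(criterion)
  data <- validate_experiments(data)
  sizes <- experiment_sizes(data) |>
    dplyr::arrange(.data$study_id, .data$experiment_id) |>
    dplyr::mutate(null_seed = as.integer(seed) + dplyr::row_number() - 1L)
  roles <- role_percentages(data)

  res <- purrr::pmap(sizes, function(study_id, experiment_id, n, k, null_seed) {
    null <- chance_null(n, k, resamples = resamples, seed = null_seed)
    rr <- roles[roles$study_id == study_id & roles$experiment_id == experiment_id, ]
    rr$z <- normalize_pct(rr$pct, null)$z
    rr$above <- switch(criterion,
      z = rr$z > z_cut,
      p05 = rr$pct > null$thr_05,
      p01 = rr$pct > null$thr_01
    )
    eligible <- rr[rr$above, , drop = FALSE]
    if (nrow(eligible) == 0) {
      winner <- NA_character_
      category <- "no_pref"
    } else {
      top <- eligible[eligible$pct == max(eligible$pct), , drop = FALSE]
      # priority order resolves exact ties towards shortcutting
      winner <- as.character(top$role[order(as.integer(top$role))][1])
      category <- winner
    }
    wide <- function(values, prefix) {
      out <- as.list(values)
      names(out) <- paste0(prefix, as.character(rr$role))
      out
    }
    tibble(
      study_id = study_id, experiment_id = experiment_id,
      n = n, k = k,
      category = category, winning_role = winner,
      !!!wide(rr$pct, "pct_"), !!!wide(rr$z, "z_"),
      mu_r = null$mu_r, sigma_r = null$sigma_r,
      thr_05 = null$thr_05, thr_01 = null$thr_01,
      resamples = resamples, null_seed = null_seed
    )
  })
  out <- dplyr::bind_rows(res)
  out$category <- factor(out$category, levels = CATEGORY_LEVELS)
  class(out) <- c("sunburst_categories", class(out))
  out
}

#' Category prevalence across a dataset
#'
#' The percentage of experiments falling into each preference category.
#' Accepts either a raw experiment tibble (categorized first, each
#' experiment with its own `(n, k)` chance distribution) or the result of
#' [categorize_experiments()].
#'
#' @param x experiment tibble or `sunburst_categories` tibble.
#' @param ... passed on to [categorize_experiments()] when `x` is raw data.
#' @return tibble with `category`, `n_experiments` and `pct` (summing to
#'   100 over the included experiments).
#' @export
prevalence <- function(x, ...) {
  if (!"category" %in% names(x)) {
    x <- categorize_experiments(x, ...)
  }
  if (nrow(x) == 0) {
    abort("No experiments to tabulate.", class = "sunburstmeta_error_validation")
  }
  x |>
    dplyr::count(.data$category, name = "n_experiments") |>
    dplyr::mutate(pct = 100 * .data$n_experiments / sum(.data$n_experiments))
}

#' @rdname categorize_experiments
#' @param object a `sunburst_categories` tibble.
#' @param ... unused.
#' @method autoplot sunburst_categories
#' @export
autoplot.sunburst_categories <- function(object, ...) {
  prev <- prevalence(object)
  ggplot2::ggplot(prev, ggplot2::aes(x = .data$category, y = .data$pct)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(
      x = NULL, y = "% of experiments",
      title = "Prevalence of path-preference categories"
    )
}

#' Inclusion filters for cross-study comparison
#'
#' Composable, pure and idempotent dataset filters implementing the default
#' inclusion rules for cross-study categorization:
#'
#' * `include_first_choice()` keeps experiments scored as `first_choice`.
#'   Records scored as `mixed_order` are dropped unless whitelisted via
#'   `allow` (some source studies reported only mixed-order choices and are
#'   retained on that basis).
#' * `drop_lesioned()` / `drop_untrained()` drop experiments flagged in the
#'   optional `is_lesioned` / `is_untrained` columns (non-intact animals,
#'   and groups that received no training before the probe test). Datasets
#'   without these columns pass through unchanged.
#' * `combine_groups()` merges experiments that share a non-missing value in
#'   the optional `combine_into` column (e.g. pre-operative groups tested
#'   before any lesion) into a single experiment by summing per-path counts
#'   and `n_no_choice`; member experiments must share an identical path
#'   layout.
#'
#' @param data validated experiment tibble.
#' @param allow experiment_ids exempt from the first-choice rule.
#' @return filtered experiment tibble.
#' @export
include_first_choice <- function(data, allow = NULL) {
  data <- validate_experiments(data)
  dplyr::filter(
    data,
    .data$scoring == "first_choice" | .data$experiment_id %in% allow
  )
}

#' @rdname include_first_choice
#' @export
drop_lesioned <- function(data) {
  data <- validate_experiments(data)
  if (!"is_lesioned" %in% names(data)) return(data)
  dplyr::filter(data, !(.data$is_lesioned %in% TRUE))
}

#' @rdname include_first_choice
#' @export
drop_untrained <- function(data) {
  data <- validate_experiments(data)
  if (!"is_untrained" %in% names(data)) return(data)
  dplyr::filter(data, !(.data$is_untrained %in% TRUE))
}

#' @rdname include_first_choice
#' @export
combine_groups <- function(data) {
  data <- validate_experiments(data)
  if (!"combine_into" %in% names(data)) return(data)
  to_combine <- dplyr::filter(data, !is.na(.data$combine_into))
  keep <- dplyr::filter(data, is.na(.data$combine_into))
  if (nrow(to_combine) == 0) return(data)
  combined <- to_combine |>
    dplyr::group_split(.data$study_id, .data$combine_into) |>
    purrr::map(function(grp) {
      layouts <- grp |>
        dplyr::select("experiment_id", "path_index", dplyr::all_of(PATH_FLAGS)) |>
        dplyr::group_split(.data$experiment_id, .keep = FALSE)
      if (length(unique(purrr::map_chr(layouts, \(x) paste(
        capture.output(print(dplyr::arrange(x, x$path_index))), collapse = "\n"
      )))) != 1) {
        abort(
          "Experiments combined into one group must share an identical path layout.",
          class = "sunburstmeta_error_validation"
        )
      }
      n_no <- grp |>
        dplyr::distinct(.data$experiment_id, .data$n_no_choice) |>
        dplyr::pull(.data$n_no_choice) |>
        sum()
      grp |>
        dplyr::group_by(.data$path_index) |>
        dplyr::summarise(
          dplyr::across(dplyr::all_of(PATH_FLAGS), dplyr::first),
          count = sum(.data$count),
          study_id = dplyr::first(.data$study_id),
          experiment_id = dplyr::first(.data$combine_into),
          species = dplyr::first(.data$species),
          group_label = dplyr::first(.data$combine_into),
          scoring = dplyr::first(.data$scoring),
          provenance = dplyr::first(.data$provenance),
          .groups = "drop"
        ) |>
        dplyr::mutate(n_no_choice = n_no, combine_into = NA_character_)
    }) |>
    dplyr::bind_rows()
  dplyr::bind_rows(keep, combined)
}
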