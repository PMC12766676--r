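#' Run the full meta-analysis and write a report bundle
#'
#' One-call pipeline over a dataset: applies the default inclusion filters
#' (first-choice scoring with an optional whitelist, dropping lesioned and
#' untrained groups, combining designated groups), categorizes every
#' experiment against its own chance distribution, tabulates category
#' prevalence, computes the four paired path contrasts and the
#' shortcut-vs-adjacent distribution intervals, and writes five artifacts to
#' `out_dir`:
#'
#' * `categories.csv` — one row per experiment with category, winning role,
#'   role percentages and z values, and null parameters;
#' * `prevalence.csv` — percent of experiments per category;
#' * `contrasts.csv` — per-experiment paired contrasts, stacked over the
#'   four role/mode combinations;
#' * `tests.json` — group-level contrast summaries (percent above chance
#'   per side, sign-flip permutation p-values) and the empirical
#'   distribution intervals;
#' * `manifest.json` — inputs, parameters, seed and package version; a rerun
#'   with an identical config reproduces the bundle byte for byte.
#'
#' Any stage failure aborts with a stage-labelled message and removes the
#' partial outputs.
#'
#' @param data a validated experiment tibble, or a path readable by
#'   [read_experiments()].
#' @param out_dir output directory (created if needed).
#' @param resamples,seed,z_cut,criterion chance-model parameters, see
#'   [categorize_experiments()].
#' @param n_perm permutations for the contrast group tests.
#' @param first_choice_allow experiment ids exempt from the first-choice
#'   inclusion rule.
#' @return invisibly, a list with the computed tables.
#' @export
run_analysis <- function(data, out_dir, resamples = 1000, seed = 1,
                         z_cut = 1.96, criterion = "z", n_perm = 10000,
                         first_choice_allow = NULL) {
  input_label <- if (is.character(data) && length(data) == 1) data else "<in-memory tibble>"
  written <- character(0)
  stage <- function(label, code) {
    tryCatch(code, error = function(e) {
      unlink(written)
      abort(
        paste0("Analysis stage '", label, "' failed: ", conditionMessage(e)),
        class = "sunburstmeta_error_pipeline"
      )
    })
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- function(name) file.path(out_dir, name)

  data <- stage("read", {
    if (is.character(data)) data <- read_experiments(data)
    validate_experiments(data)
  })
  data <- stage("filter", {
    data |>
      include_first_choice(allow = first_choice_allow) |>
      drop_lesioned() |>
      drop_untrained() |>
      combine_groups()
  })
  cats <- stage("categorize", {
    categorize_experiments(
      data, resamples = resamples, seed = seed, z_cut = z_cut,
      criterion = criterion
    )
  })
  prev <- stage("prevalence", prevalence(cats))
  contrast_specs <- list(
    list(fn = adjacent_contrast, role = "adjacent", mode = "intersect"),
    list(fn = adjacent_contrast, role = "adjacent", mode = "first_turn"),
    list(fn = outer_contrast, role = "outer", mode = "reward_side"),
    list(fn = outer_contrast, role = "outer", mode = "first_turn")
  )
  contrasts <- stage("contrasts", {
    purrr::map(contrast_specs, function(cs) {
      res <- cs$fn(
        data, mode = cs$mode, resamples = resamples, seed = seed,
        z_cut = z_cut, n_perm = n_perm
      )
      list(role = cs$role, mode = cs$mode, result = res)
    })
  })
  ci <- stage("distribution_ci", {
    if (nrow(cats) >= 2 &&
        all(c("z_shortcut", "z_adjacent") %in% names(cats)) &&
        sum(!is.na(cats$z_shortcut - cats$z_adjacent)) >= 2) {
      experiment_distribution_ci(cats$z_shortcut - cats$z_adjacent)
    } else {
      NULL
    }
  })

  stage("write", {
    readr::write_csv(as_tibble(cats), out("categories.csv"), progress = FALSE)
    written <<- c(written, out("categories.csv"))
    readr::write_csv(prev, out("prevalence.csv"), progress = FALSE)
    written <<- c(written, out("prevalence.csv"))
    contrast_table <- purrr::map_dfr(contrasts, function(cc) {
      tb <- tidy(cc$result)
      if (nrow(tb) == 0) return(NULL)
      dplyr::mutate(tb, role = cc$role, mode = cc$mode, .before = 1)
    })
    readr::write_csv(contrast_table, out("contrasts.csv"), progress = FALSE)
    written <<- c(written, out("contrasts.csv"))
    tests <- list(
      contrasts = purrr::map(contrasts, function(cc) {
        c(list(role = cc$role, mode = cc$mode), as.list(glance(cc$result)))
      }),
      shortcut_vs_adjacent_ci = ci
    )
    jsonlite::write_json(tests, out("tests.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    written <<- c(written, out("tests.json"))
    manifest <- list(
      input = input_label,
      n_experiments = nrow(cats),
      parameters = list(
        resamples = resamples, seed = seed, z_cut = z_cut,
        criterion = criterion, n_perm = n_perm,
        first_choice_allow = first_choice_allow
      ),
      package = "sunburstmeta",
      version = as.character(utils::packageVersion("sunburstmeta"))
    )
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  })
  invisible(list(
    data = data, categories = cats, prevalence = prev,
    contrasts = contrasts, shortcut_vs_adjacent_ci = ci
  ))
}
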