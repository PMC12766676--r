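#' Sunburst experiment tables
#'
#' A Sunburst dataset is a tibble with one row per (experiment, path).
#' Experiment-level metadata is repeated on each of the experiment's rows.
#' The canonical columns are:
#'
#' \describe{
#'   \item{study_id, experiment_id}{identify the experiment; the pair must be
#'     unique across the dataset.}
#'   \item{species}{`"rat"`, `"monkey"` or `"human"`.}
#'   \item{group_label}{free-text group descriptor.}
#'   \item{scoring}{`"first_choice"` (each subject's first committed path
#'     selection) or `"mixed_order"` (first and later choices pooled, as some
#'     source studies reported). Mixed-order records are carried but dropped
#'     by default before categorization, see [include_first_choice()].}
#'   \item{path_index}{1-based path number as printed in the source study's
#'     figure. Geometry is never modelled; the role flags below carry all
#'     spatial meaning.}
#'   \item{count}{number of subjects whose scored choice was this path.}
#'   \item{is_shortcut, is_adjacent, is_outer, is_cued, is_training,
#'     is_excluded}{path role flags. Excluded paths (e.g. the six shortened
#'     left arms of the original apparatus) never contribute to chance or
#'     category computation.}
#'   \item{intersects_training}{for an adjacent path: whether it is the one
#'     more likely to intersect the training route beyond the block.}
#'   \item{matches_first_turn}{for an adjacent or outer path: whether it heads
#'     in the direction of the first turn of the training route.}
#'   \item{reward_side}{for an outer path: whether it lies on the rewarded
#'     side of the maze.}
#'   \item{n_no_choice}{subjects that made no final choice; metadata only,
#'     never part of N.}
#'   \item{provenance}{free text describing the table/figure the counts were
#'     digitized from.}
#' }
#'
#' Extra columns are preserved untouched so that source-specific annotations
#' (e.g. lesion status) can ride along.
#'
#' @name sunburst-data
NULL

PATH_FLAGS <- c(
  "is_shortcut", "is_adjacent", "is_outer", "is_cued", "is_training",
  "is_excluded", "intersects_training", "matches_first_turn", "reward_side"
)

EXPERIMENT_COLS <- c(
  "study_id", "experiment_id", "species", "group_label", "scoring"
)

REQUIRED_COLS <- c(EXPERIMENT_COLS, "path_index", "count", PATH_FLAGS)

META_COLS <- c("n_no_choice", "provenance")

#' Validate a Sunburst experiment table
#'
#' Checks the structural invariants of the per-(experiment, path) layout:
#' required columns, non-negative integer counts, unique path indices within
#' an experiment, at most one shortcut and at most two adjacent/outer paths
#' per experiment, at most one training path, and at least one scored choice
#' per experiment. Malformed rows are reported with their row numbers.
#'
#' @param data a tibble in the layout described in [sunburst-data].
#' @return `data`, invisibly, with flag columns coerced to logical and the
#'   optional metadata columns (`n_no_choice`, `provenance`) filled in.
#' @export
validate_experiments <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(REQUIRED_COLS, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "sunburstmeta_error_schema"
    )
  }
  if (nrow(data) == 0) {
    abort("Dataset contains no rows.", class = "sunburstmeta_error_schema")
  }
  if (!"n_no_choice" %in% names(data)) data$n_no_choice <- 0L
  if (!"provenance" %in% names(data)) data$provenance <- NA_character_
  data$n_no_choice[is.na(data$n_no_choice)] <- 0L
  for (fl in PATH_FLAGS) {
    v <- data[[fl]]
    if (is.numeric(v)) {
      if (!all(v %in% c(0, 1))) {
        abort(
          paste0("Column `", fl, "` must be 0/1 or logical."),
          class = "sunburstmeta_error_schema"
        )
      }
      v <- v == 1
    }
    if (!is.logical(v)) {
      abort(
        paste0("Column `", fl, "` must be 0/1 or logical."),
        class = "sunburstmeta_error_schema"
      )
    }
    v[is.na(v)] <- FALSE
    data[[fl]] <- v
  }

  bad <- which(is.na(data$count) | data$count < 0 | data$count != round(data$count))
  if (length(bad) > 0) {
    abort(
      paste0(
        "Counts must be non-negative integers; offending row(s): ",
        paste(head(bad, 10), collapse = ", "),
        " (experiment ", data$experiment_id[bad[1]], ")"
      ),
      class = "sunburstmeta_error_validation"
    )
  }
  data$count <- as.integer(data$count)

  checks <- data |>
    dplyr::group_by(.data$study_id, .data$experiment_id) |>
    dplyr::summarise(
      dup_paths = anyDuplicated(.data$path_index) > 0,
      n_shortcut = sum(.data$is_shortcut & !.data$is_excluded),
      n_adjacent = sum(.data$is_adjacent & !.data$is_excluded),
      n_outer = sum(.data$is_outer & !.data$is_excluded),
      n_training = sum(.data$is_training),
      n_scored = sum(.data$count[!.data$is_excluded]),
      .groups = "drop"
    )
  fail <- function(cond, what) {
    if (any(cond)) {
      ids <- checks$experiment_id[cond]
      abort(
        paste0(what, " in experiment(s): ", paste(head(ids, 5), collapse = ", ")),
        class = "sunburstmeta_error_validation"
      )
    }
  }
  fail(checks$dup_paths, "Duplicate path index")
  fail(checks$n_shortcut > 1, "More than one shortcut path")
  fail(checks$n_adjacent > 2, "More than two adjacent paths")
  fail(checks$n_outer > 2, "More than two outer paths")
  fail(checks$n_training > 1, "More than one training path")
  fail(checks$n_scored < 1, "No scored choices (N = 0)")
  invisible(data)
}

#' Read a Sunburst experiment dataset
#'
#' Reads and validates a dataset in the canonical per-(experiment, path)
#' layout. CSV input uses one row per path with 0/1 role flags; an optional
#' companion metadata CSV carries experiment-level `n_no_choice` and
#' `provenance`. JSON input mirrors the same schema with one object per
#' experiment holding a nested `paths` array.
#'
#' @param path file to read.
#' @param format `"csv"` or `"json"`; guessed from the file extension when
#'   omitted.
#' @param meta optional path to a companion experiment-level CSV with columns
#'   `study_id`, `experiment_id`, `n_no_choice`, `provenance`.
#' @return a validated tibble (see [sunburst-data]).
#' @export
read_experiments <- function(path, format = NULL, meta = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "sunburstmeta_error_schema")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  data <- if (format == "csv") {
    if (file.size(path) == 0) {
      abort("Empty file.", class = "sunburstmeta_error_schema")
    }
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0) {
      abort("Empty file.", class = "sunburstmeta_error_schema")
    }
    recs <- as_tibble(raw)
    if (!"paths" %in% names(recs)) {
      abort("JSON records must carry a `paths` array.", class = "sunburstmeta_error_schema")
    }
    tidyr::unnest(recs, "paths")
  }
  if (!is.null(meta)) {
    meta_tbl <- readr::read_csv(meta, show_col_types = FALSE, progress = FALSE)
    keep <- intersect(c("study_id", "experiment_id", META_COLS), names(meta_tbl))
    data <- dplyr::left_join(
      dplyr::select(data, -dplyr::any_of(META_COLS)),
      meta_tbl[keep],
      by = c("study_id", "experiment_id")
    )
  }
  validate_experiments(data)
}

#' Write a Sunburst experiment dataset
#'
#' Writes the canonical layout so that `read_experiments()` round-trips
#' counts, flags and metadata losslessly. CSV output stores flags as 0/1 and
#' writes a companion `*_meta.csv` with the experiment-level columns; JSON
#' output nests the per-path rows under each experiment.
#'
#' @param data validated experiment tibble.
#' @param path output file.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_experiments <- function(data, path, format = NULL) {
  data <- validate_experiments(data)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    out <- data
    for (fl in PATH_FLAGS) out[[fl]] <- as.integer(out[[fl]])
    readr::write_csv(dplyr::select(out, -dplyr::any_of(META_COLS)), path, progress = FALSE)
    meta <- dplyr::distinct(
      data, .data$study_id, .data$experiment_id, .data$n_no_choice, .data$provenance
    )
    meta_path <- sub("\\.csv$", "_meta.csv", path, ignore.case = TRUE)
    readr::write_csv(meta, meta_path, progress = FALSE)
  } else {
    exp_cols <- intersect(c(EXPERIMENT_COLS, META_COLS), names(data))
    nested <- tidyr::nest(data, paths = -dplyr::all_of(exp_cols))
    jsonlite::write_json(nested, path, dataframe = "rows", auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Per-path choice percentages
#'
#' Converts counts to percentages of all scored choices, per experiment,
#' over the non-excluded paths. Excluded paths are dropped from the result
#' (reported as absent, not as zero), and the returned percentages sum to
#' 100 within each experiment.
#'
#' @param data validated experiment tibble.
#' @return the non-excluded rows of `data` with a `pct` column appended.
#' @export
path_percentages <- function(data) {
  data <- validate_experiments(data)
  data |>
    dplyr::filter(!.data$is_excluded) |>
    dplyr::group_by(.data$study_id, .data$experiment_id) |>
    dplyr::mutate(pct = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Total scored choices per experiment
#'
#' N is the sum of counts over non-excluded paths; subjects that made no
#' final choice (`n_no_choice`) never enter N.
#'
#' @param data validated experiment tibble.
#' @return tibble with `study_id`, `experiment_id`, `n` (scored choices) and
#'   `k` (number of non-excluded paths).
#' @export
experiment_sizes <- function(data) {
  data <- validate_experiments(data)
  data |>
    dplyr::filter(!.data$is_excluded) |>
    dplyr::group_by(.data$study_id, .data$experiment_id) |>
    dplyr::summarise(n = sum(.data$count), k = dplyr::n(), .groups = "drop")
}
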