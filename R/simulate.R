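#' Maze layout presets
#'
#' Builds a table of path roles for common Sunburst-maze variants. A layout
#' is the per-path half of an experiment record: `path_index` plus the role
#' flags, with no counts. Geometry is deliberately not modelled; the role
#' flags carry all spatial meaning, and the preset index assignments are a
#' fixed emulation of the source apparatus descriptions.
#'
#' Presets:
#' \describe{
#'   \item{`tolman`}{the original 18-path radial array: shortcut at printed
#'     position #6, paths 13-18 excluded from scoring (the shortened left
#'     arms), two adjacent paths flanking the blocked training direction
#'     (#9, #10; #10 intersects the training route, #9 matches the first
#'     training turn), outer scorable paths #1 (reward side) and #12
#'     (matching the first turn). 12 scorable paths, so chance is 100/12.}
#'   \item{`circular`}{a full-circle array (default `k = 12`) in which the
#'     blocked training path is itself one of the radial paths (#1), with
#'     the shortcut diametrically opposite and the adjacent paths flanking
#'     the training path.}
#'   \item{`tmaze`}{a simplified 4-path variant: a shortcut, one adjacent
#'     path and two outer paths at 90 degrees.}
#'   \item{`enclosed`}{an enclosed radial maze with no visual cues (default
#'     `k = 8`, chance 100/8 = 12.5): shortcut in the middle of the array,
#'     flanked by the two adjacent paths, outer paths at the extremes.}
#'   \item{`harley`}{a 6-path variant in which the shortcut path is also one
#'     of the adjacent paths (overlapping role flags).}
#' }
#'
#' @param preset one of `"tolman"`, `"circular"`, `"tmaze"`, `"enclosed"`,
#'   `"harley"`.
#' @param k number of paths; only presets `circular` and `enclosed` accept a
#'   custom `k`, the others have a fixed size.
#' @return tibble with `path_index` and the logical role-flag columns.
#' @export
make_layout <- function(preset = c("tolman", "circular", "tmaze", "enclosed", "harley"),
                        k = NULL) {
  preset <- match.arg(preset)
  blank <- function(k) {
    tibble(
      path_index = seq_len(k),
      is_shortcut = FALSE, is_adjacent = FALSE, is_outer = FALSE,
      is_cued = FALSE, is_training = FALSE, is_excluded = FALSE,
      intersects_training = FALSE, matches_first_turn = FALSE,
      reward_side = FALSE
    )
  }
  fixed_k <- function(expected) {
    if (!is.null(k) && k != expected) {
      abort(
        sprintf("Preset '%s' has a fixed layout of %d paths.", preset, expected),
        class = "sunburstmeta_error_layout"
      )
    }
    expected
  }
  set <- function(lay, idx, col, value = TRUE) {
    lay[[col]][lay$path_index %in% idx] <- value
    lay
  }
  lay <- switch(preset,
    tolman = {
      kk <- fixed_k(18L)
      blank(kk) |>
        set(13:18, "is_excluded") |>
        set(6, "is_shortcut") |>
        set(c(9, 10), "is_adjacent") |>
        set(10, "intersects_training") |>
        set(c(9, 12), "matches_first_turn") |>
        set(c(1, 12), "is_outer") |>
        set(1, "reward_side")
    },
    circular = {
      kk <- if (is.null(k)) 12L else as.integer(k)
      if (kk < 6) {
        abort("Preset 'circular' needs at least 6 paths.", class = "sunburstmeta_error_layout")
      }
      blank(kk) |>
        set(1, "is_training") |>
        set(1 + floor(kk / 2), "is_shortcut") |>
        set(c(2, kk), "is_adjacent") |>
        set(2, "intersects_training") |>
        set(kk, "matches_first_turn")
    },
    tmaze = {
      kk <- fixed_k(4L)
      blank(kk) |>
        set(2, "is_shortcut") |>
        set(3, "is_adjacent") |>
        set(3, "intersects_training") |>
        set(c(1, 4), "is_outer") |>
        set(1, "reward_side") |>
        set(4, "matches_first_turn")
    },
    enclosed = {
      kk <- if (is.null(k)) 8L else as.integer(k)
      if (kk < 5) {
        abort("Preset 'enclosed' needs at least 5 paths.", class = "sunburstmeta_error_layout")
      }
      mid <- as.integer(ceiling(kk / 2))
      blank(kk) |>
        set(mid, "is_shortcut") |>
        set(c(mid - 1, mid + 1), "is_adjacent") |>
        set(mid + 1, "intersects_training") |>
        set(mid - 1, "matches_first_turn") |>
        set(c(1, kk), "is_outer") |>
        set(1, "reward_side")
    },
    harley = {
      kk <- fixed_k(6L)
      blank(kk) |>
        set(4, "is_shortcut") |>
        set(c(3, 4), "is_adjacent") |>
        set(4, "intersects_training") |>
        set(3, "matches_first_turn") |>
        set(c(1, 6), "is_outer") |>
        set(1, "reward_side") |>
        set(6, "matches_first_turn")
    }
  )
  lay
}

#' Navigation strategy mixture
#'
#' Probabilities with which a simulated subject adopts each single-trial
#' choice strategy: `shortcut` (map-like choice of the shortcut path),
#' `adjacent` (stimulus-triggered response near the blocked training
#' route), `beacon` (approach the cued path; falls back to a uniform choice
#' in layouts without a cue), `outer` (thigmotaxis / route repetition to an
#' outermost path) and `uniform` (exploration with no preference).
#'
#' @param shortcut,adjacent,beacon,outer,uniform non-negative probabilities
#'   summing to 1.
#' @return a named numeric vector of class `strategy_mix`.
#' @export
strategy_mix <- function(shortcut = 0, adjacent = 0, beacon = 0, outer = 0,
                         uniform = 0) {
  p <- c(
    shortcut = shortcut, adjacent = adjacent, beacon = beacon,
    outer = outer, uniform = uniform
  )
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    abort(
      "Strategy probabilities must be non-negative and sum to 1.",
      class = "sunburstmeta_error_config"
    )
  }
  structure(p, class = "strategy_mix")
}

#' Simulation configuration
#'
#' Bundles everything needed to simulate one experiment: the maze layout,
#' the number of subjects, the strategy mixture and a seed. `smear`
#' optionally spreads the shortcut strategy geometrically over neighbouring
#' paths (weight `smear^d` at index distance `d` from the shortcut, over
#' non-excluded paths), emulating the graded choice distributions produced
#' by noisy vector-integration accounts rather than a single peaked
#' shortcut preference. `p_no_choice` is the probability that a subject
#' makes no final choice; such subjects are recorded in `n_no_choice`,
#' never in the counts.
#'
#' @param layout a layout tibble from [make_layout()] (or hand-built with
#'   the same columns).
#' @param n number of subjects.
#' @param mix a [strategy_mix()].
#' @param seed integer seed; the same config always yields the same record.
#' @param experiment_id,study_id,species,group_label,scoring record
#'   metadata.
#' @param p_no_choice probability of making no final choice.
#' @param smear geometric decay of the smeared-shortcut strategy; 0 (the
#'   default) targets the shortcut path exactly.
#' @param bias_path optional path index acting as an unannotated sensory
#'   attractor (a dark or wall-adjacent alley, say). When the layout has no
#'   cued path, the beacon strategy approaches this path instead of falling
#'   back to a uniform choice; this is how experiments whose winning path
#'   has no remarkable role ("other" preference, an apparatus artifact) are
#'   simulated.
#' @return a `sim_config` object.
#' @export
sim_config <- function(layout, n, mix, seed = 1,
                       experiment_id = "sim1", study_id = "synthetic",
                       species = "rat", group_label = "simulated",
                       scoring = "first_choice",
                       p_no_choice = 0, smear = 0, bias_path = NULL) {
  if (!is.numeric(n) || n < 1) {
    abort("`n` must be >= 1 subjects.", class = "sunburstmeta_error_config")
  }
  if (!inherits(mix, "strategy_mix")) mix <- do.call(strategy_mix, as.list(mix))
  if (p_no_choice < 0 || p_no_choice >= 1) {
    abort("`p_no_choice` must be in [0, 1).", class = "sunburstmeta_error_config")
  }
  if (smear < 0 || smear >= 1) {
    abort("`smear` must be in [0, 1).", class = "sunburstmeta_error_config")
  }
  if (!is.null(bias_path) && !bias_path %in% layout$path_index) {
    abort("`bias_path` must be one of the layout's path indices.",
          class = "sunburstmeta_error_config")
  }
  structure(
    list(
      layout = as_tibble(layout), n = as.integer(n), mix = mix,
      seed = as.integer(seed), experiment_id = experiment_id,
      study_id = study_id, species = species, group_label = group_label,
      scoring = scoring, p_no_choice = p_no_choice, smear = smear,
      bias_path = bias_path
    ),
    class = "sim_config"
  )
}

#' Simulate one Sunburst experiment
#'
#' Each of the `n` subjects independently draws a strategy from the mixture
#' and then one path: the shortcut strategy targets the shortcut path (or
#' its geometric smear, see [sim_config()]), the adjacent strategy picks one
#' of the adjacent paths uniformly, the beacon strategy picks the cued path
#' (falling back to a uniform choice when the layout has no cue), the outer
#' strategy picks one of the outer paths uniformly, and the uniform strategy
#' picks any non-excluded path. A strategy whose target paths do not exist
#' in the layout, and which has no fallback, is an error. Counts are
#' aggregated into a standard experiment record; the same config always
#' yields an identical record.
#'
#' @param config a [sim_config()].
#' @return a validated one-experiment tibble (see [sunburst-data]).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- config$layout
  scorable <- lay$path_index[!lay$is_excluded]
  shortcut_paths <- lay$path_index[lay$is_shortcut & !lay$is_excluded]
  adjacent_paths <- lay$path_index[lay$is_adjacent & !lay$is_excluded]
  outer_paths <- lay$path_index[lay$is_outer & !lay$is_excluded]
  cued_paths <- lay$path_index[lay$is_cued & !lay$is_excluded]

  pick_uniform <- function(m, paths) paths[sample.int(length(paths), m, replace = TRUE)]
  choices <- with_seed(config$seed, {
    no_choice <- stats::runif(config$n) < config$p_no_choice
    n_choosers <- sum(!no_choice)
    strategies <- sample(names(config$mix), n_choosers, replace = TRUE,
                         prob = as.numeric(config$mix))
    out <- integer(n_choosers)
    for (strat in unique(strategies)) {
      idx <- which(strategies == strat)
      out[idx] <- switch(strat,
        shortcut = {
          if (length(shortcut_paths) == 0) {
            abort("Shortcut strategy drawn but layout has no shortcut path.",
                  class = "sunburstmeta_error_config")
          }
          if (config$smear > 0) {
            w <- config$smear^abs(scorable - shortcut_paths[1])
            scorable[sample.int(length(scorable), length(idx), replace = TRUE,
                                prob = w / sum(w))]
          } else {
            rep(shortcut_paths[1], length(idx))
          }
        },
        adjacent = {
          if (length(adjacent_paths) == 0) {
            abort("Adjacent strategy drawn but layout has no adjacent paths.",
                  class = "sunburstmeta_error_config")
          }
          pick_uniform(length(idx), adjacent_paths)
        },
        beacon = {
          if (length(cued_paths) > 0) {
            rep(cued_paths[1], length(idx))
          } else if (!is.null(config$bias_path)) {
            rep(config$bias_path, length(idx))
          } else {
            pick_uniform(length(idx), scorable)
          }
        },
        outer = {
          if (length(outer_paths) == 0) {
            abort("Outer strategy drawn but layout has no outer paths.",
                  class = "sunburstmeta_error_config")
          }
          pick_uniform(length(idx), outer_paths)
        },
        uniform = pick_uniform(length(idx), scorable)
      )
    }
    list(paths = out, n_no_choice = sum(no_choice))
  })
  counts <- vapply(lay$path_index, function(p) sum(choices$paths == p), integer(1))
  rec <- dplyr::mutate(
    lay,
    study_id = config$study_id, experiment_id = config$experiment_id,
    species = config$species, group_label = config$group_label,
    scoring = config$scoring, count = counts,
    n_no_choice = choices$n_no_choice,
    provenance = "simulated",
    .before = 1
  )
  validate_experiments(rec)
}

#' Simulate a dataset of experiments
#'
#' @param configs a list of [sim_config()] objects with distinct
#'   `(study_id, experiment_id)` pairs.
#' @return a validated multi-experiment tibble.
#' @export
simulate_dataset <- function(configs) {
  if (length(configs) == 0) {
    abort("`configs` must be non-empty.", class = "sunburstmeta_error_config")
  }
  ids <- purrr::map_chr(configs, \(cf) paste(cf$study_id, cf$experiment_id, sep = "/"))
  if (anyDuplicated(ids) > 0) {
    abort(
      paste0("Duplicate experiment id(s): ", ids[duplicated(ids)][1]),
      class = "sunburstmeta_error_config"
    )
  }
  validate_experiments(dplyr::bind_rows(purrr::map(configs, simulate_experiment)))
}
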