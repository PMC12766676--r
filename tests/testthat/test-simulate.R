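test_that("layout presets carry consistent role flags", {
  tol <- make_layout("tolman")
  expect_equal(sum(!tol$is_excluded), 12)
  expect_equal(tol$path_index[tol$is_excluded], 13:18)
  expect_equal(tol$path_index[tol$is_shortcut], 6)
  expect_equal(sum(tol$is_adjacent), 2)
  expect_equal(sum(tol$is_outer), 2)
  expect_true(tol$reward_side[tol$path_index == 1])
  expect_true(validate_experiments(record_from_counts(tol, c(rep(1L, 12), rep(0L, 6))))
              |> is.data.frame())

  enc <- make_layout("enclosed")
  expect_equal(nrow(enc), 8)
  expect_equal(closed_form_null(16, sum(!enc$is_excluded))$mu, 12.5)

  # overlapping shortcut/adjacent flags are a legal layout
  har <- make_layout("harley")
  expect_true(any(har$is_shortcut & har$is_adjacent))

  expect_error(make_layout("tolman", k = 12), class = "sunburstmeta_error_layout")
  expect_error(make_layout("circular", k = 3), class = "sunburstmeta_error_layout")
})

test_that("strategy mixtures validate", {
  expect_error(strategy_mix(shortcut = 0.5), class = "sunburstmeta_error_config")
  expect_error(strategy_mix(shortcut = 1.2, uniform = -0.2),
               class = "sunburstmeta_error_config")
  mx <- strategy_mix(shortcut = 0.25, adjacent = 0.25, uniform = 0.5)
  expect_s3_class(mx, "strategy_mix")
  expect_equal(sum(mx), 1)
})

test_that("pure strategies hit their target paths", {
  lay <- make_layout("enclosed")
  lay$is_cued[lay$path_index == 2] <- TRUE

  beacon <- simulate_experiment(
    sim_config(lay, n = 25, mix = strategy_mix(beacon = 1), seed = 1)
  )
  expect_equal(beacon$count[beacon$path_index == 2], 25L)
  expect_equal(sum(beacon$count), 25L)

  sc <- simulate_experiment(
    sim_config(lay, n = 10, mix = strategy_mix(shortcut = 1), seed = 2)
  )
  expect_equal(sc$count[sc$is_shortcut], 10L)

  # uniform exploration approaches 100/K per path (3 SE tolerance)
  unif <- simulate_experiment(
    sim_config(lay, n = 20000, mix = strategy_mix(uniform = 1), seed = 3)
  )
  pct <- path_percentages(unif)$pct
  se <- 100 * sqrt((1 / 8) * (7 / 8) / 20000)
  expect_true(all(abs(pct - 100 / 8) < 3 * se))
})

test_that("strategies without target paths error unless a fallback exists", {
  bare <- toy_layout(4)
  expect_error(
    simulate_experiment(sim_config(bare, 5, strategy_mix(adjacent = 1), seed = 1)),
    class = "sunburstmeta_error_config"
  )
  expect_error(
    simulate_experiment(sim_config(bare, 5, strategy_mix(shortcut = 1), seed = 1)),
    class = "sunburstmeta_error_config"
  )
  expect_error(
    simulate_experiment(sim_config(bare, 5, strategy_mix(outer = 1), seed = 1)),
    class = "sunburstmeta_error_config"
  )
  # beacon falls back to uniform when no cue and no bias path
  rec <- simulate_experiment(sim_config(bare, 50, strategy_mix(beacon = 1), seed = 4))
  expect_equal(sum(rec$count), 50L)
  expect_gt(sum(rec$count > 0), 1)
  # ... and approaches an unannotated attractor when one is declared
  biased <- simulate_experiment(
    sim_config(bare, 30, strategy_mix(beacon = 1), seed = 5, bias_path = 3)
  )
  expect_equal(biased$count[biased$path_index == 3], 30L)
})

test_that("simulation is deterministic under seeds and leaves layout metadata alone", {
  cf <- sim_config(make_layout("tolman"), n = 40,
                   mix = strategy_mix(adjacent = 0.6, uniform = 0.4), seed = 10)
  a <- simulate_experiment(cf)
  b <- simulate_experiment(cf)
  expect_identical(a, b)
  cf2 <- sim_config(make_layout("tolman"), n = 40,
                    mix = strategy_mix(adjacent = 0.6, uniform = 0.4), seed = 11)
  c <- simulate_experiment(cf2)
  expect_false(identical(a$count, c$count))
  expect_identical(a[setdiff(names(a), "count")], c[setdiff(names(c), "count")])
})

test_that("no-choice subjects land in n_no_choice, never in counts", {
  cf <- sim_config(make_layout("enclosed"), n = 200,
                   mix = strategy_mix(uniform = 1), seed = 6, p_no_choice = 0.3)
  rec <- simulate_experiment(cf)
  expect_gt(rec$n_no_choice[1], 0)
  expect_equal(sum(rec$count) + rec$n_no_choice[1], 200)
})

test_that("smeared shortcutting spreads mass geometrically to neighbours", {
  lay <- make_layout("enclosed")  # shortcut at path 4 of 8
  cf <- sim_config(lay, n = 40000, mix = strategy_mix(shortcut = 1),
                   seed = 7, smear = 0.5)
  rec <- simulate_experiment(cf)
  cnt <- rec$count
  expect_equal(which.max(cnt), 4)
  # neighbour-to-peak ratio converges to the decay parameter
  expect_equal(cnt[3] / cnt[4], 0.5, tolerance = 0.1)
  expect_equal(cnt[5] / cnt[4], 0.5, tolerance = 0.1)
  expect_equal(cnt[2] / cnt[3], 0.5, tolerance = 0.15)
})

test_that("dataset simulation validates configs and recovers dominant strategies", {
  expect_error(simulate_dataset(list()), class = "sunburstmeta_error_config")
  cf <- sim_config(make_layout("tolman"), 10, strategy_mix(uniform = 1), seed = 1)
  expect_error(simulate_dataset(list(cf, cf)), class = "sunburstmeta_error_config")

  # argmax role follows the argmax strategy at large N, across presets
  cases <- list(
    list(preset = "tolman", mix = strategy_mix(shortcut = 0.6, uniform = 0.4),
         role = "shortcut"),
    list(preset = "enclosed", mix = strategy_mix(adjacent = 0.6, uniform = 0.4),
         role = "adjacent"),
    list(preset = "tmaze", mix = strategy_mix(outer = 0.6, uniform = 0.4),
         role = "outer")
  )
  for (cs in cases) {
    for (sd in 1:5) {
      rec <- simulate_experiment(
        sim_config(make_layout(cs$preset), n = 10000, mix = cs$mix, seed = 400 + sd)
      )
      cats <- categorize_experiments(rec, seed = 500 + sd)
      expect_equal(as.character(cats$category), cs$role,
                   info = paste(cs$preset, sd))
    }
  }
})

test_that("prevalence on a generator-built dataset recovers the intended mix", {
  lay <- make_layout("tolman")
  cued_lay <- lay
  cued_lay$is_cued[cued_lay$path_index == 4] <- TRUE
  mk <- function(i, mix, layout = lay, bias_path = NULL) {
    sim_config(layout, n = 40, mix = mix, seed = 800 + i,
               experiment_id = paste0("p", i), bias_path = bias_path)
  }
  # strategy-dominant configs: 5 shortcut, 8 adjacent, 4 outer, 3 cued, 4 other
  configs <- c(
    lapply(1:5, \(i) mk(i, strategy_mix(shortcut = 0.6, uniform = 0.4))),
    lapply(6:13, \(i) mk(i, strategy_mix(adjacent = 0.7, uniform = 0.3))),
    lapply(14:17, \(i) mk(i, strategy_mix(outer = 0.7, uniform = 0.3))),
    lapply(18:20, \(i) mk(i, strategy_mix(beacon = 0.7, uniform = 0.3),
                          layout = cued_lay)),
    lapply(21:24, \(i) mk(i, strategy_mix(beacon = 0.6, uniform = 0.4),
                          bias_path = 3))
  )
  prev <- prevalence(simulate_dataset(configs), seed = 900)
  intended <- c(shortcut = 5, adjacent = 8, outer = 4, cued = 3, other = 4) / 24
  for (cat in names(intended)) {
    got <- prev$pct[prev$category == cat]
    if (length(got) == 0) got <- 0
    se <- 100 * sqrt(intended[[cat]] * (1 - intended[[cat]]) / 24)
    expect_lt(abs(got - 100 * intended[[cat]]), 3 * se)
  }

  # pure-uniform configs: no_pref is the modal category (leakage into the
  # max-of-unlabelled 'other' role keeps this below 100%)
  unif <- simulate_dataset(lapply(1:20, function(i) {
    sim_config(lay, n = 40, mix = strategy_mix(uniform = 1), seed = 850 + i,
               experiment_id = paste0("u", i))
  }))
  prev_u <- prevalence(unif, seed = 901)
  expect_equal(
    as.character(prev_u$category[which.max(prev_u$pct)]),
    "no_pref"
  )
})
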