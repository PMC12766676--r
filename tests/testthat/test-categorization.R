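test_that("role percentages average multi-path roles and pool 'other' as a max", {
  # two adjacent paths at 40% and 20% -> adjacent role 30%
  lay <- toy_layout(5, shortcut = 1, adjacent = c(2, 3))
  rec <- record_from_counts(lay, c(1, 4, 2, 2, 1))
  rp <- role_percentages(rec)
  expect_equal(rp$pct[rp$role == "adjacent"], 30)
  expect_equal(rp$pct[rp$role == "shortcut"], 10)
  # 'other' reports the best unlabelled path, not the mean
  expect_equal(rp$pct[rp$role == "other"], 20)

  # a path that is both shortcut and adjacent contributes to both roles
  harley <- make_layout("harley")
  rec2 <- record_from_counts(harley, c(1, 1, 5, 12, 0, 0), experiment_id = "h1")
  rp2 <- role_percentages(rec2)
  expect_equal(rp2$pct[rp2$role == "shortcut"], 100 * 12 / 19)
  expect_equal(rp2$pct[rp2$role == "adjacent"], 100 * mean(c(5, 12)) / 19)
})

test_that("the Tolman-style record is categorized as shortcut", {
  cats <- categorize_experiments(tolman_record(), seed = 3)
  expect_equal(as.character(cats$category), "shortcut")
  expect_gt(cats$z_shortcut, 2.326)
})

test_that("uniform counts give no preference", {
  rec <- record_from_counts(
    toy_layout(5, shortcut = 1, adjacent = c(2, 3), outer = c(4, 5)),
    rep(8L, 5)
  )
  cats <- categorize_experiments(rec, seed = 2)
  expect_equal(as.character(cats$category), "no_pref")
  expect_true(is.na(cats$winning_role))
})

test_that("heavy adjacent mass wins on a wide layout", {
  # 80% of 50 choices split over the two adjacent paths of an 18-path array
  lay <- toy_layout(18, shortcut = 9, adjacent = c(12, 13), outer = c(1, 18))
  counts <- integer(18)
  counts[12] <- 20L; counts[13] <- 20L
  counts[c(2, 4, 6, 8, 10, 14, 16, 17, 3, 5)] <- 1L
  rec <- record_from_counts(lay, counts)
  cats <- categorize_experiments(rec, seed = 8)
  expect_equal(as.character(cats$category), "adjacent")
})

test_that("categorization matches an independently coded rule on random toy records", {
  set.seed(2024)
  for (i in 1:40) {
    rec <- random_toy_record(k = sample(3:5, 1), n_total = sample(c(10, 25, 60), 1),
                             id = paste0("r", i))
    cats <- categorize_experiments(rec, resamples = 1000, seed = 50 + i)
    null <- chance_null(sum(rec$count), nrow(rec), resamples = 1000,
                        seed = cats$null_seed)
    expect_equal(as.character(cats$category), oracle_categorize(rec, null),
                 info = paste("record", i))
  }
})

test_that("exact ties among above-chance roles resolve towards shortcutting", {
  # shortcut and the adjacent average both at 40%, both far above chance
  lay <- toy_layout(5, shortcut = 1, adjacent = c(2, 3))
  rec <- record_from_counts(lay, c(20L, 20L, 20L, 5L, 5L) * 2L)
  cats <- categorize_experiments(rec, seed = 6)
  rp <- role_percentages(rec)
  expect_equal(rp$pct[rp$role == "shortcut"], rp$pct[rp$role == "adjacent"])
  expect_equal(as.character(cats$category), "shortcut")
})

test_that("categorization is invariant to path order and stable under count scaling", {
  rec <- tolman_record()
  shuffled <- rec[sample(nrow(rec)), ]
  a <- categorize_experiments(rec, seed = 4)
  b <- categorize_experiments(shuffled, seed = 4)
  expect_equal(as.character(a$category), as.character(b$category))
  expect_equal(a$z_shortcut, b$z_shortcut)

  # scaling all counts by an integer factor grows z but keeps the winner
  for (fac in c(2L, 5L)) {
    big <- rec
    big$count <- big$count * fac
    bb <- categorize_experiments(big, seed = 4)
    expect_equal(as.character(bb$winning_role), as.character(a$winning_role))
    expect_gt(bb$z_shortcut, a$z_shortcut)
  }
})

test_that("averaging percentages then normalizing equals averaging z values", {
  nl <- chance_null(50, 12, 2000, seed = 5)
  pcts <- c(31, 17)
  z_of_mean <- normalize_pct(mean(pcts), nl)$z
  mean_of_z <- mean(normalize_pct(pcts, nl)$z)
  expect_equal(z_of_mean, mean_of_z, tolerance = 1e-12)
})

test_that("prevalence sums to 100 and degenerate datasets behave", {
  cats <- categorize_experiments(tolman_record(), seed = 3)
  prev <- prevalence(cats)
  expect_equal(sum(prev$pct), 100)
  expect_equal(prev$pct[prev$category == "shortcut"], 100)

  unif <- dplyr::bind_rows(lapply(1:4, function(i) {
    record_from_counts(
      toy_layout(6, shortcut = 1, adjacent = c(2, 3)),
      rep(5L, 6), experiment_id = paste0("u", i)
    )
  }))
  prev_u <- prevalence(unif, seed = 11)
  expect_equal(prev_u$pct[prev_u$category == "no_pref"], 100)
})

test_that("inclusion filters are pure, idempotent and respect the whitelist", {
  rec1 <- tolman_record()
  rec2 <- record_from_counts(make_layout("enclosed"), c(1, 2, 10, 3, 2, 1, 1, 2),
                             experiment_id = "mixed", scoring = "mixed_order")
  data <- dplyr::bind_rows(rec1, rec2)

  kept <- include_first_choice(data)
  expect_setequal(unique(kept$experiment_id), "original")
  expect_identical(include_first_choice(kept), kept)
  expect_setequal(
    unique(include_first_choice(data, allow = "mixed")$experiment_id),
    c("original", "mixed")
  )

  # optional columns drive the lesion/training filters
  data$is_lesioned <- data$experiment_id == "mixed"
  expect_setequal(unique(drop_lesioned(data)$experiment_id), "original")
  expect_identical(drop_untrained(data)$experiment_id, data$experiment_id)
})

test_that("combine_groups sums counts and no-choice across designated groups", {
  lay <- make_layout("enclosed")
  r1 <- record_from_counts(lay, c(0, 1, 5, 2, 1, 0, 1, 0), experiment_id = "preop_sham",
                           n_no_choice = 1)
  r2 <- record_from_counts(lay, c(1, 0, 4, 3, 0, 1, 0, 1), experiment_id = "preop_hpc",
                           n_no_choice = 2)
  r3 <- record_from_counts(lay, c(2, 2, 2, 2, 2, 2, 2, 2), experiment_id = "solo")
  data <- dplyr::bind_rows(r1, r2, r3)
  data$combine_into <- ifelse(grepl("^preop", data$experiment_id), "preop", NA)

  merged <- combine_groups(data)
  expect_setequal(unique(merged$experiment_id), c("solo", "preop"))
  pre <- dplyr::arrange(dplyr::filter(merged, experiment_id == "preop"), path_index)
  expect_equal(pre$count, c(1L, 1L, 9L, 5L, 1L, 1L, 1L, 1L))
  expect_equal(unique(pre$n_no_choice), 3)
  expect_identical(combine_groups(merged)$count, merged$count)
})
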