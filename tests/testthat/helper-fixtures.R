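# Fixtures are built in code from the counts printed in the source studies;
# where a study did not print every per-path count, the remainder is spread
# synthetically and the record is marked as such in its provenance.

# Build a one-experiment tibble from a layout and a count vector (ordered by
# path_index).
record_from_counts <- function(layout, counts, experiment_id = "exp1",
                               study_id = "study", species = "rat",
                               group_label = "g", scoring = "first_choice",
                               n_no_choice = 0,
                               provenance = "synthetic fixture") {
  stopifnot(nrow(layout) == length(counts))
  dplyr::mutate(
    layout,
    study_id = study_id, experiment_id = experiment_id, species = species,
    group_label = group_label, scoring = scoring,
    count = as.integer(counts), n_no_choice = n_no_choice,
    provenance = provenance,
    .before = 1
  )
}

# A minimal K-path layout with roles given as index vectors.
toy_layout <- function(k, shortcut = integer(), adjacent = integer(),
                       outer = integer(), cued = integer(),
                       training = integer(), excluded = integer(),
                       intersects = integer(), first_turn = integer(),
                       reward = integer()) {
  tibble::tibble(
    path_index = seq_len(k),
    is_shortcut = seq_len(k) %in% shortcut,
    is_adjacent = seq_len(k) %in% adjacent,
    is_outer = seq_len(k) %in% outer,
    is_cued = seq_len(k) %in% cued,
    is_training = seq_len(k) %in% training,
    is_excluded = seq_len(k) %in% excluded,
    intersects_training = seq_len(k) %in% intersects,
    matches_first_turn = seq_len(k) %in% first_turn,
    reward_side = seq_len(k) %in% reward
  )
}

# Tolman-style record: 19/53 on the shortcut (#6), 9/53 on outer path #1,
# the remaining 25 choices spread over the other 10 scorable paths
# (synthetic split; only the shortcut and #1 counts are printed), 3 rats
# making no choice out of 56.
tolman_record <- function() {
  lay <- make_layout("tolman")
  counts <- integer(18)
  counts[6] <- 19L
  counts[1] <- 9L
  rest <- setdiff(1:12, c(1, 6))
  counts[rest] <- rep(c(3L, 2L), 5)
  record_from_counts(
    lay, counts,
    study_id = "tolman1946", experiment_id = "original",
    n_no_choice = 3,
    provenance = "printed shortcut/outer counts; remainder synthetic"
  )
}

# The independent categorization oracle: same inputs, independently coded
# decision rule (role table -> above-chance filter -> max percentage ->
# priority tie-break).
oracle_categorize <- function(record, null, z_cut = 1.96) {
  priority <- c("shortcut", "adjacent", "outer", "cued", "other")
  d <- record[!record$is_excluded, ]
  pct <- 100 * d$count / sum(d$count)
  role_pct <- c(
    shortcut = if (any(d$is_shortcut)) mean(pct[d$is_shortcut]) else NA,
    adjacent = if (any(d$is_adjacent)) mean(pct[d$is_adjacent]) else NA,
    outer = if (any(d$is_outer)) mean(pct[d$is_outer]) else NA,
    cued = if (any(d$is_cued)) mean(pct[d$is_cued]) else NA,
    other = {
      plain <- !d$is_shortcut & !d$is_adjacent & !d$is_outer & !d$is_cued & !d$is_training
      if (any(plain)) max(pct[plain]) else NA
    }
  )
  role_pct <- role_pct[!is.na(role_pct)]
  z <- (role_pct - null$mu_r) / null$sigma_r
  above <- names(role_pct)[z > z_cut]
  if (length(above) == 0) return("no_pref")
  best <- above[role_pct[above] == max(role_pct[above])]
  priority[min(match(best, priority))]
}

# Random small record on a toy layout, for property-style enumeration.
random_toy_record <- function(k = 5, n_total = 40, id = "r1") {
  roles <- sample(c("none", "shortcut", "adjacent", "outer", "cued"), k,
                  replace = TRUE)
  # respect multiplicity caps
  cap <- function(role, m) {
    idx <- which(roles == role)
    if (length(idx) > m) roles[idx[-seq_len(m)]] <<- "none"
  }
  cap("shortcut", 1); cap("adjacent", 2); cap("outer", 2); cap("cued", 1)
  lay <- toy_layout(
    k,
    shortcut = which(roles == "shortcut"),
    adjacent = which(roles == "adjacent"),
    outer = which(roles == "outer"),
    cued = which(roles == "cued")
  )
  counts <- as.integer(rmultinom(1, n_total, prob = runif(k) + 0.05))
  record_from_counts(lay, counts, experiment_id = id)
}
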