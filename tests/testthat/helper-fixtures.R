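# Shared fixtures: tiny hand-built cohorts and generator shortcuts.

# a deterministic aligned cohort with n_per members per stage on a fixed grid
toy_cohort <- function(n_per = 3L, grid = c(1000, 2000, 3000, 4000),
                       leaf = leaf_meta()) {
  members <- list()
  for (s in stage_levels()) {
    shift <- (match(s, stage_levels()) - 1) * 10
    members[[s]] <- lapply(seq_len(n_per), function(k)
      spectrum_matrix(grid, seq_along(grid) + shift + k / 10, s, k, leaf))
  }
  cohort(members, leaf)
}

small_cohort <- function(seed, n_peaks = 40L, per_stage = 8L,
                         effect_size = 2, noise_sd = 0.35) {
  generate_cohort(synthetic_cohort_config(
    n_peaks = n_peaks, per_stage = per_stage, effect_size = effect_size,
    noise_sd = noise_sd, seed = seed))
}

cohort_accuracy <- function(co, method, split_seed, k = 3L) {
  sp <- split_cohort(co, 0.7, seed = split_seed)
  res <- classify_cohort(sp$test, sp$train,
                         classifier_config(method, k = k))
  mean(res$predictions$stage == res$predictions$predicted)
}

stage_of <- function(mats) vapply(mats, function(m) m$stage, character(1))
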