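# Synthetic SELDI cohort generator.
#
# Intensity model, per peak i, sample k of stage with severity s(stage):
#   log I_{ki} = b_i - s * log(effect_size) * [i discriminative] + u_k + e_{ki}
# with b_i ~ N(baseline_log_mean, baseline_log_sd^2) a fixed peak baseline,
# u_k ~ N(0, sample_scale_sd^2) a per-sample loading/ionization factor shared
# across peaks, and e_{ki} ~ N(0, noise_sd^2) peak-level noise. Severity is
# 0 (CON), 1 (MCI), 2 (TAD): discriminative peaks are progressively
# down-regulated with disease severity, so stage-mean log-intensities are
# strictly monotone (decreasing) in severity and projected cluster spread
# under a fixed eigenbasis shrinks with severity.

#' Configuration of a synthetic SELDI cohort
#'
#' Parameters of the log-normal intensity model used by [generate_cohort()].
#' Defaults mirror the study design: a shared grid of differentially
#' expressed peaks (178 for a low-energy leaf), 20 data points per stage and
#' a 2-20 kDa m/z range.
#'
#' @param n_peaks grid size (number of differentially expressed peaks).
#' @param per_stage data points per stage (design default 20).
#' @param n_discriminative number of stage-affected peaks
#'   (default: all of them; the grid consists of differentially expressed
#'   ions by construction).
#' @param effect_size multiplicative intensity change per severity step,
#'   `>= 1`; discriminative peaks are divided by this factor once for MCI and
#'   twice for TAD. `1` yields a null cohort with exchangeable stages.
#' @param noise_sd standard deviation of peak-level log-intensity noise.
#' @param sample_scale_sd standard deviation of the per-sample log-scale
#'   factor shared across all peaks of a data point (sample loading /
#'   ionization variability).
#' @param baseline_log_mean,baseline_log_sd mean and sd of the fixed per-peak
#'   baseline log-intensity.
#' @param mass_range numeric length-2, m/z range in Daltons.
#' @param seed integer seed; the full cohort is reproducible from it.
#' @return An object of class `synthetic_cohort_config`.
#' @seealso [make_separability_presets()]
#' @export
#' @examples
#' synthetic_cohort_config(n_peaks = 50, seed = 7)
synthetic_cohort_config <- function(n_peaks = 178L,
                                    per_stage = 20L,
                                    n_discriminative = n_peaks,
                                    effect_size = 2,
                                    noise_sd = 0.35,
                                    sample_scale_sd = 0.2,
                                    baseline_log_mean = log(50),
                                    baseline_log_sd = 0.7,
                                    mass_range = c(2000, 20000),
                                    seed = 1L) {
  cfg <- list(n_peaks = as.integer(n_peaks),
              per_stage = as.integer(per_stage),
              n_discriminative = as.integer(n_discriminative),
              effect_size = as.numeric(effect_size),
              noise_sd = as.numeric(noise_sd),
              sample_scale_sd = as.numeric(sample_scale_sd),
              baseline_log_mean = as.numeric(baseline_log_mean),
              baseline_log_sd = as.numeric(baseline_log_sd),
              mass_range = as.numeric(mass_range),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_cohort_config")
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (is.na(n_peaks) || n_peaks < 1L)
      stop("n_peaks must be a positive integer", call. = FALSE)
    if (is.na(per_stage) || per_stage < 1L)
      stop("per_stage must be a positive integer", call. = FALSE)
    if (is.na(n_discriminative) || n_discriminative < 0L ||
        n_discriminative > n_peaks)
      stop("n_discriminative must lie in [0, n_peaks]", call. = FALSE)
    if (!is.finite(effect_size) || effect_size < 1)
      stop("effect_size must be >= 1", call. = FALSE)
    if (!is.finite(noise_sd) || noise_sd < 0)
      stop("noise_sd must be >= 0", call. = FALSE)
    if (!is.finite(sample_scale_sd) || sample_scale_sd < 0)
      stop("sample_scale_sd must be >= 0", call. = FALSE)
    if (length(mass_range) != 2L || any(!is.finite(mass_range)) ||
        mass_range[1] <= 0 || mass_range[2] <= mass_range[1])
      stop("mass_range must be an increasing positive pair", call. = FALSE)
    if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  })
  invisible(cfg)
}

#' @export
print.synthetic_cohort_config <- function(x, ...) {
  cat("<synthetic_cohort_config>\n")
  cat(sprintf("  n_peaks=%d per_stage=%d n_discriminative=%d\n",
              x$n_peaks, x$per_stage, x$n_discriminative))
  cat(sprintf("  effect_size=%.3g noise_sd=%.3g sample_scale_sd=%.3g\n",
              x$effect_size, x$noise_sd, x$sample_scale_sd))
  cat(sprintf("  mass_range=[%g, %g] seed=%d\n",
              x$mass_range[1], x$mass_range[2], x$seed))
  invisible(x)
}

severity_step <- function(stage) {
  match(as_stage(stage), stage_levels()) - 1L
}

#' Generate a synthetic SELDI cohort
#'
#' Draws one shared, strictly increasing mass grid and per-stage data points
#' from the log-normal intensity model described in
#' [synthetic_cohort_config()]. Discriminative peaks are down-regulated by a
#' factor `effect_size` per severity step (CON -> MCI -> TAD), all other
#' peaks are exchangeable across stages. Fully reproducible from
#' `config$seed`; the caller's RNG state is untouched.
#'
#' @param config a [synthetic_cohort_config()].
#' @param leaf a [leaf_meta()] describing the emulated design leaf.
#' @return A `seldi_cohort`, already aligned (all members share the grid),
#'   with attributes `grid` (the mass grid), `discriminative` (indices of
#'   stage-affected peaks) and `stage_log_means` (3 x n matrix of per-stage
#'   mean log-intensities, rows CON/MCI/TAD).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_cohort_config(n_peaks = 30,
#'                                                   per_stage = 5,
#'                                                   seed = 42))
#' cohort_sizes(cohort)
generate_cohort <- function(config, leaf = leaf_meta()) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  validate_synthetic_config(config)
  out <- with_local_seed(config$seed, {
    grid <- sort(stats::runif(config$n_peaks,
                              config$mass_range[1], config$mass_range[2]))
    while (anyDuplicated(grid)) {   # runif collisions are measure-zero
      grid <- sort(stats::runif(config$n_peaks,
                                config$mass_range[1], config$mass_range[2]))
    }
    baseline <- stats::rnorm(config$n_peaks,
                             config$baseline_log_mean, config$baseline_log_sd)
    disc <- sort(sample.int(config$n_peaks, config$n_discriminative))
    shift_unit <- numeric(config$n_peaks)
    shift_unit[disc] <- -log(config$effect_size)
    stage_log_means <- rbind(CON = baseline,
                             MCI = baseline + shift_unit,
                             TAD = baseline + 2 * shift_unit)
    members <- list()
    for (s in stage_levels()) {
      mu <- stage_log_means[s, ]
      members[[s]] <- lapply(seq_len(config$per_stage), function(k) {
        u <- stats::rnorm(1L, 0, config$sample_scale_sd)
        e <- stats::rnorm(config$n_peaks, 0, config$noise_sd)
        spectrum_matrix(grid, exp(mu + u + e), s, k, leaf)
      })
    }
    list(members = members, grid = grid, disc = disc,
         stage_log_means = stage_log_means)
  })
  res <- cohort(out$members, leaf)
  attr(res, "grid") <- out$grid
  attr(res, "discriminative") <- out$disc
  attr(res, "stage_log_means") <- out$stage_log_means
  res
}

#' Separability presets emulating the laser-energy contrast
#'
#' High-energy leaves of the original design yield well separated stage
#' clusters, low-energy leaves heavily overlapping ones. The presets encode
#' that contrast: `high_energy` (299 grid peaks, effect size 2.0, peak noise
#' sd 0.35) produces separable classes, `low_energy` (178 grid peaks, effect
#' size 1.4, peak noise sd 0.6) overlapping ones. Both use 20 data points
#' per stage, all grid peaks discriminative and a per-sample scale sd of 0.2.
#'
#' @param seed integer seed stored in both configs.
#' @param n_peaks optional grid size overriding both presets' defaults
#'   (299 high / 178 low, the peak counts of the CM10 leaves).
#' @return Named list of two [synthetic_cohort_config()] objects,
#'   `low_energy` and `high_energy`.
#' @export
#' @examples
#' make_separability_presets(seed = 1)
make_separability_presets <- function(seed = 1L, n_peaks = NULL) {
  low <- synthetic_cohort_config(n_peaks = n_peaks %||% 178L,
                                 per_stage = 20L,
                                 effect_size = 1.4,
                                 noise_sd = 0.6,
                                 sample_scale_sd = 0.2,
                                 seed = seed)
  high <- synthetic_cohort_config(n_peaks = n_peaks %||% 299L,
                                  per_stage = 20L,
                                  effect_size = 2,
                                  noise_sd = 0.35,
                                  sample_scale_sd = 0.2,
                                  seed = seed)
  list(low_energy = low, high_energy = high)
}
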