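# Cohort configuration for the synthetic generator.

#' Configuration for a synthetic longitudinal cohort
#'
#' Defines the study conditions the generator emulates: a cohort of dogs
#' labeled successful / non-successful, scanned at `n_timepoints` timepoints
#' with `runs_per_tp` resting-state runs of `volumes_per_run` volumes at
#' `tr_seconds` TR, together with integrated behavioral scores (IBS =
#' retrieve + hunt + environmental soundness, each 1-5) that rise from the
#' first to the second timepoint and then plateau. Planted structure:
#'
#' * `periphery_edges`: edges whose Fisher-z FC gains `fc_gain` on average at
#'   TP2/TP3, with the per-dog gain coupled to the dog's realized IBS change
#'   so that corr(deltaFC, deltaIBS) = `coupling_rho` across dogs.
#' * `core_edges`: edges offset by `group_effect_d * noise_sd` (z scale) in
#'   successful dogs at every timepoint (stable group difference).
#'
#' @param n_success,n_fail dogs per outcome group (defaults 13 / 17).
#' @param n_regions number of atlas regions (default 40).
#' @param n_timepoints number of timepoints (default 3: TP1, TP2, TP3).
#' @param runs_per_tp resting-state runs per dog per timepoint (default 2).
#' @param volumes_per_run volumes per run (default 200).
#' @param tr_seconds repetition time in seconds (default 1).
#' @param periphery_edges data.frame with columns `i`, `j`, `coupling_rho`,
#'   `fc_gain` (1-based region indices, i < j), or NULL for none.
#' @param core_edges data.frame with columns `i`, `j`, `group_effect_d`,
#'   or NULL for none.
#' @param behavior_gain_mean,behavior_gain_sd mean and across-dog SD of the
#'   TP1 to TP2 IBS gain, in IBS points.
#' @param behavior_tp3_sd SD of the pure-noise TP2 to TP3 subscore drift.
#' @param subscore_base_mean latent mean of each 1-5 subscore at TP1 for
#'   non-successful dogs.
#' @param subscore_success_shift additive latent subscore advantage of
#'   successful dogs (gives the weak behavioral predictivity of success).
#' @param subscore_sd across-dog SD of each latent subscore.
#' @param noise_sd across-dog SD of baseline edge FC (correlation scale).
#' @param periphery_spread_sd across-dog SD of the planted periphery FC
#'   increment (Fisher-z scale).
#' @param periphery_group_d standardized TP1 group effect (successful minus
#'   non-successful, units of `noise_sd`) on periphery edges; gives the
#'   flexible network its weak pre-training predictivity.
#' @param n_latent_factors latent factors in the baseline connectome model.
#' @param n_complete number of dogs with usable data at all timepoints
#'   (remaining dogs have only TP1 scans); NULL = all dogs complete.
#' @param spike_prob per-frame probability of a motion spike.
#' @param spike_mm translation magnitude of a spike in mm.
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   cohort bit for bit.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_success = 13, n_fail = 17, n_regions = 40,
                          n_timepoints = 3, runs_per_tp = 2,
                          volumes_per_run = 200, tr_seconds = 1,
                          periphery_edges = NULL, core_edges = NULL,
                          behavior_gain_mean = 2, behavior_gain_sd = 1,
                          behavior_tp3_sd = 0.2,
                          subscore_base_mean = 2.8,
                          subscore_success_shift = 0.2,
                          subscore_sd = 0.8,
                          noise_sd = 0.25, periphery_spread_sd = 0.3,
                          periphery_group_d = 0.5,
                          n_latent_factors = 5,
                          n_complete = NULL,
                          spike_prob = 0.02, spike_mm = 0.5,
                          seed = 1L) {
  cfg <- list(
    n_success = as.integer(n_success), n_fail = as.integer(n_fail),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    runs_per_tp = as.integer(runs_per_tp),
    volumes_per_run = as.integer(volumes_per_run), tr_seconds = tr_seconds,
    periphery_edges = periphery_edges, core_edges = core_edges,
    behavior_gain_mean = behavior_gain_mean, behavior_gain_sd = behavior_gain_sd,
    behavior_tp3_sd = behavior_tp3_sd,
    subscore_base_mean = subscore_base_mean,
    subscore_success_shift = subscore_success_shift,
    subscore_sd = subscore_sd,
    noise_sd = noise_sd, periphery_spread_sd = periphery_spread_sd,
    periphery_group_d = periphery_group_d,
    n_latent_factors = as.integer(n_latent_factors),
    n_complete = if (is.null(n_complete)) NULL else as.integer(n_complete),
    spike_prob = spike_prob, spike_mm = spike_mm,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_success + n_fail >= 4, n_success >= 0, n_fail >= 0,
      n_regions >= 2, n_timepoints >= 1, runs_per_tp >= 1,
      volumes_per_run >= 10, tr_seconds > 0,
      behavior_gain_sd >= 0, subscore_sd >= 0, behavior_tp3_sd >= 0,
      noise_sd >= 0, periphery_spread_sd >= 0,
      spike_prob >= 0, spike_prob <= 1, spike_mm >= 0,
      n_latent_factors >= 1
    )
  })
  if (cfg$noise_sd * sqrt(cfg$n_latent_factors) >= 1) {
    stop("noise_sd too large for the latent-factor baseline model; ",
         "require noise_sd < 1/sqrt(n_latent_factors)")
  }
  if (!is.null(cfg$n_complete)) {
    stopifnot(cfg$n_complete >= 0, cfg$n_complete <= cfg$n_success + cfg$n_fail)
  }
  check_edges <- function(ed, extra_cols) {
    if (is.null(ed)) return(NULL)
    ed <- as.data.frame(ed)
    stopifnot(all(c("i", "j", extra_cols) %in% names(ed)))
    stopifnot(all(ed$i >= 1), all(ed$j <= cfg$n_regions), all(ed$i < ed$j))
    ed
  }
  pe <- check_edges(cfg$periphery_edges, c("coupling_rho", "fc_gain"))
  ce <- check_edges(cfg$core_edges, "group_effect_d")
  if (!is.null(pe)) {
    stopifnot(all(abs(pe$coupling_rho) < 1))
    if (any(abs(pe$fc_gain) + 3 * cfg$periphery_spread_sd > 3)) {
      stop("fc_gain too large: planted correlations would leave (-1, 1)")
    }
  }
  if (!is.null(pe) && !is.null(ce)) {
    keys <- function(ed) paste(ed$i, ed$j)
    if (length(intersect(keys(pe), keys(ce)))) {
      stop("periphery and core edge lists must be disjoint")
    }
  }
  invisible(cfg)
}

#' Default planted-cohort configuration
#'
#' The study conditions used throughout the package's simulations: 30 dogs
#' (13 successful / 17 non-successful), 24 with complete data at all three
#' timepoints, five planted periphery edges (coupling_rho 0.8, mean Fisher-z
#' gain 0.36 against an across-dog increment SD of 0.30, i.e. a paired effect
#' of about 1.2 SD) and seven planted core edges (group effect d = 1.5).
#'
#' @param seed RNG seed.
#' @param ... overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
planted_cohort_config <- function(seed = 1L, ...) {
  periphery <- data.frame(
    i = c(1, 3, 5, 7, 9), j = c(2, 4, 6, 8, 10),
    coupling_rho = 0.8, fc_gain = 0.36
  )
  core <- data.frame(
    i = c(11, 13, 15, 17, 19, 21, 23), j = c(12, 14, 16, 18, 20, 22, 24),
    group_effect_d = 1.5
  )
  defaults <- list(
    n_success = 13, n_fail = 17, n_complete = 24,
    periphery_edges = periphery, core_edges = core, seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

#' Fully null cohort configuration
#'
#' No planted edges, no behavioral group shift, no behavior-coupled FC: every
#' selection stage should then operate at its nominal false-positive level.
#' Defaults to the 24-dog complete cohort used for calibration checks.
#'
#' @param n_success,n_fail group sizes (defaults 10 / 14).
#' @param seed RNG seed.
#' @param ... overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
null_cohort_config <- function(n_success = 10, n_fail = 14, seed = 1L, ...) {
  defaults <- list(
    n_success = n_success, n_fail = n_fail,
    periphery_edges = NULL, core_edges = NULL,
    subscore_success_shift = 0, periphery_group_d = 0,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}
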