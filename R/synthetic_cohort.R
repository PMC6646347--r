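#' Cohort simulation configuration
#'
#' Defines a synthetic cohort emulating the recorded study population:
#' 5 susceptible and 6 resilient rats with LFP, a 30-min pre and a 120-min
#' post rest session per rat. Susceptible rats develop post-stress cardiac
#' dysfunction (arrhythmia rate 0.4/min and RR coefficient of variation 0.07,
#' i.e. deltas at about twice the classification thresholds of 0.2/min and
#' 0.02); resilient rats are unchanged. Resilient rats carry a higher
#' theta-band envelope correlation (0.6 vs 0.25) while all other bands share
#' rho = 0.3 across groups. The default missing-region plan reproduces the
#' recorded configuration: one region missed in 3 susceptible and 3 resilient
#' rats and two regions missed in 1 resilient rat.
#'
#' @param n_susceptible,n_resilient Group sizes.
#' @param cardiac_pre,cardiac_post_susceptible,cardiac_post_resilient
#'   [cardiac_sim_config()]s for the pre phase (both groups) and each group's
#'   post phase.
#' @param lfp_susceptible,lfp_resilient [lfp_sim_config()]s per group.
#' @param emg An [emg_sim_config()].
#' @param missing_region_plan Named list mapping rat id to regions dropped
#'   from that rat's sessions; `NULL` for the default plan above. Use
#'   `list()` for no missing regions.
#' @param duration_pre,duration_post Session durations in seconds.
#' @param post_lfp Logical; simulate LFP in post sessions (default `TRUE`).
#'   Disabling it gives ECG/EMG-only post sessions for cardiac-focused runs.
#' @param seed Integer seed; a fixed seed makes the cohort bit-reproducible.
#' @return A config list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    n_susceptible = 5, n_resilient = 6,
    cardiac_pre = cardiac_sim_config(rr_cv = 0.03, arrhythmia_rate = 0),
    cardiac_post_susceptible = cardiac_sim_config(rr_cv = 0.07, arrhythmia_rate = 0.4),
    cardiac_post_resilient = cardiac_sim_config(rr_cv = 0.03, arrhythmia_rate = 0),
    lfp_susceptible = lfp_sim_config(band_params = default_band_params(rho = 0.3, theta_rho = 0.25)),
    lfp_resilient = lfp_sim_config(band_params = default_band_params(rho = 0.3, theta_rho = 0.6)),
    emg = emg_sim_config(),
    missing_region_plan = NULL,
    duration_pre = 1800, duration_post = 7200,
    post_lfp = TRUE,
    seed = 1) {
  stopifnot(n_susceptible >= 0, n_resilient >= 0,
            duration_pre >= 60, duration_post >= 60)
  ids <- c(if (n_susceptible > 0) paste0("S", seq_len(n_susceptible)),
           if (n_resilient > 0) paste0("R", seq_len(n_resilient)))
  if (is.null(missing_region_plan)) {
    missing_region_plan <- list(S1 = "V1", S2 = "RSC", S3 = "PL",
                                R1 = "V1", R2 = "HPC", R3 = "S1",
                                R4 = c("V1", "RSC"))
    missing_region_plan <- missing_region_plan[names(missing_region_plan) %in% ids]
  }
  structure(
    list(n_susceptible = n_susceptible, n_resilient = n_resilient,
         rat_ids = ids,
         cardiac_pre = cardiac_pre,
         cardiac_post_susceptible = cardiac_post_susceptible,
         cardiac_post_resilient = cardiac_post_resilient,
         lfp_susceptible = lfp_susceptible, lfp_resilient = lfp_resilient,
         emg = emg, missing_region_plan = missing_region_plan,
         duration_pre = duration_pre, duration_post = duration_post,
         post_lfp = post_lfp, seed = as.integer(seed)),
    class = "cohort_sim_config")
}

rat_group <- function(rat_id) {
  if (startsWith(rat_id, "S")) "susceptible" else "resilient"
}

# deterministic per-rat seed stream (kept below 2^31)
rat_seed <- function(seed, i) (as.integer(seed) + i * 100003L) %% 2147483647L

#' Simulate one rat's pre and post sessions
#'
#' Generates both phases of a single rat under the cohort configuration,
#' using a seed derived from `cfg$seed` and the rat index so that cohorts can
#' be generated rat-by-rat (bounded memory) with the same result as
#' [simulate_cohort()].
#'
#' @param cfg A [cohort_sim_config()].
#' @param i Rat index in `cfg$rat_ids`.
#' @return List of two [recording_session()]s (`pre`, `post`), each carrying
#'   ground truth (`true_beat_times`, `true_arrhythmia_times`,
#'   `true_sleep_intervals`, `true_band_pair_correlations`, `true_group`).
#' @export
simulate_rat <- function(cfg, i) {
  rat_id <- cfg$rat_ids[i]
  group <- rat_group(rat_id)
  set.seed(rat_seed(cfg$seed, i))
  lfp_cfg <- if (group == "susceptible") cfg$lfp_susceptible else cfg$lfp_resilient
  drop <- cfg$missing_region_plan[[rat_id]]
  regions <- setdiff(lfp_cfg$regions, drop)
  out <- list()
  for (phase in c("pre", "post")) {
    duration <- if (phase == "pre") cfg$duration_pre else cfg$duration_post
    card_cfg <- if (phase == "pre") cfg$cardiac_pre
      else if (group == "susceptible") cfg$cardiac_post_susceptible
      else cfg$cardiac_post_resilient
    ecg <- simulate_ecg(card_cfg, duration)
    emg <- simulate_emg(cfg$emg, duration)
    channels <- list(ecg$signal, emg$signal)
    truth <- list(true_beat_times = ecg$beat_times,
                  true_arrhythmia_times = ecg$arrhythmia_times,
                  true_sleep_intervals = emg$sleep_intervals,
                  true_group = group)
    if (length(regions) > 0 && (phase == "pre" || isTRUE(cfg$post_lfp))) {
      lfp_cfg_rat <- lfp_cfg
      lfp_cfg_rat$regions <- regions
      lfp <- simulate_lfp(lfp_cfg_rat, duration)
      channels <- c(channels, unname(lfp$signals))
      truth$true_band_pair_correlations <- lfp$band_pair_correlations
    }
    out[[phase]] <- recording_session(rat_id, phase, duration, channels,
                                      ground_truth = truth)
  }
  out
}

#' Simulate a full cohort
#'
#' Generates pre and post [recording_session()]s for every rat in the
#' configuration. Deterministic under a fixed `cfg$seed`.
#'
#' @param cfg A [cohort_sim_config()].
#' @return A list with one element per rat (named by rat id), each a list of
#'   `pre` and `post` sessions.
#' @export
simulate_cohort <- function(cfg) {
  out <- lapply(seq_along(cfg$rat_ids), function(i) simulate_rat(cfg, i))
  names(out) <- cfg$rat_ids
  out
}
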