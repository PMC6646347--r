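#!/usr/bin/env Rscript
# Simulate a synthetic cohort of defeated rats and write it to disk as
# session containers, one directory per rat and phase, plus a ground-truth
# manifest. The cohort carries the study-group structure (5 susceptible /
# 6 resilient rats, susceptible rats developing post-stress arrhythmias and
# elevated HRV, resilient rats carrying higher theta-band connectivity, the
# recorded missing-region plan) at desk-scale problem sizes: 15-min pre /
# 31-min post sessions and 400 Hz LFP, so the full analysis chain
# (01 -> 04) runs in a few minutes.

suppressPackageStartupMessages(library(stressconn))

out_dir <- "results/cohort"
seed <- 20240901

cfg <- cohort_sim_config(
  cardiac_pre = cardiac_sim_config(rr_cv = 0.03, arrhythmia_rate = 0, ecg_fs = 500),
  cardiac_post_susceptible = cardiac_sim_config(rr_cv = 0.07, arrhythmia_rate = 0.4,
                                                ecg_fs = 500),
  cardiac_post_resilient = cardiac_sim_config(rr_cv = 0.03, arrhythmia_rate = 0,
                                              ecg_fs = 500),
  lfp_susceptible = lfp_sim_config(fs = 400,
    band_params = default_band_params(rho = 0.3, theta_rho = 0.25)),
  lfp_resilient = lfp_sim_config(fs = 400,
    band_params = default_band_params(rho = 0.3, theta_rho = 0.6)),
  emg = emg_sim_config(fs = 200),
  duration_pre = 900, duration_post = 1860, post_lfp = FALSE,
  seed = seed)

dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
truth <- list()
for (i in seq_along(cfg$rat_ids)) {
  id <- cfg$rat_ids[i]
  sess <- simulate_rat(cfg, i)
  for (phase in c("pre", "post"))
    write_session(sess[[phase]], file.path(out_dir, paste0(id, "_", phase)))
  truth[[id]] <- list(true_group = sess$pre$ground_truth$true_group,
                      regions = session_regions(sess$pre))
  cat(sprintf("rat %-3s (%s): pre %d s, post %d s, %d LFP regions\n",
              id, truth[[id]]$true_group, cfg$duration_pre, cfg$duration_post,
              length(truth[[id]]$regions)))
}
jsonlite::write_json(truth, file.path(out_dir, "truth_manifest.json"),
                     auto_unbox = TRUE)
cat(sprintf("wrote %d rats (%d sessions) under %s\n",
            length(cfg$rat_ids), 2 * length(cfg$rat_ids), out_dir))
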