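#!/usr/bin/env Rscript
# Pre-session functional connectivity: downsample each LFP channel to
# 200 Hz, compute 5-s Hann-tapered FFT spectrograms (0.2 Hz bins, bands
# delta/4-6/theta/beta/gamma on [1,45) Hz), correlate band-power time series
# for every region pair, and compare the pooled pair-correlation
# distributions of the ECG-defined susceptible and resilient groups with the
# two-sample KS test. Also runs the per-frequency t-test/FDR comparison of
# average spectra per region.

suppressPackageStartupMessages(library(stressconn))

cohort_dir <- "results/cohort"
cardiac <- read.csv("results/cardiac.csv", stringsAsFactors = FALSE)
labels <- setNames(cardiac$label, cardiac$rat_id)

conn <- list(); spectra <- list(); regions_per_rat <- list()
for (id in cardiac$rat_id) {
  pre <- read_session(file.path(cohort_dir, paste0(id, "_pre")))
  regions_per_rat[[id]] <- session_regions(pre)
  if (length(regions_per_rat[[id]]) < 2) next
  sp <- session_spectrograms(pre)
  conn[[id]] <- session_connectivity(sp)
  for (r in names(sp)) spectra[[r]][[id]] <- average_spectrum(sp[[r]])
  cat(sprintf("rat %-3s: %d regions, %d windows\n", id,
              length(sp), length(sp[[1]]$window_times)))
}

counts <- count_available_pairs(regions_per_rat[names(conn)], labels[names(conn)])
cat(sprintf("pooled pairs: susceptible %d, resilient %d\n",
            counts["susceptible"], counts["resilient"]))

ds <- build_cohort_dataset(conn, labels)
ks <- pooled_ks_by_band(ds)
write.csv(ks, "results/ks_pre.csv", row.names = FALSE)
print(ks, digits = 3)
cat(sprintf("\ntheta band: D_max = %.2f, p = %.2g (%s)\n",
            ks$d_max[ks$band == "theta"], ks$p[ks$band == "theta"],
            if (ks$p[ks$band == "theta"] < 0.05)
              "groups differ" else "no significant difference"))

for (b in names(ds$bands))
  write.csv(data.frame(rat_id = rownames(ds$bands[[b]]),
                       label = unname(labels[rownames(ds$bands[[b]])]),
                       ds$bands[[b]], check.names = FALSE),
            sprintf("results/connectivity_%s_pre.csv", b), row.names = FALSE)

q_sig <- 0
for (r in names(spectra)) {
  rats <- names(spectra[[r]])
  if (length(unique(labels[rats])) < 2 || min(table(labels[rats])) < 2) next
  res <- per_frequency_group_test(do.call(rbind, spectra[[r]]), labels[rats])
  write.csv(res, sprintf("results/spectral_test_%s.csv", r), row.names = FALSE)
  q_sig <- q_sig + sum(res$q < 0.05, na.rm = TRUE)
}
cat(sprintf("per-frequency group tests: %d significant bins (q < 0.05) across regions\n",
            q_sig))
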