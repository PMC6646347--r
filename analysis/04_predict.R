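#!/usr/bin/env Rscript
# Predict susceptibility from pre-stress connectivity: impute missing pairs
# with same-group means, project each band's 15-dimensional pair-correlation
# vectors with PCA (3 components, for visualization), train a linear SVM on
# the raw pair vectors, and estimate the leave-one-out cross-validated
# failure percentage per band.

suppressPackageStartupMessages(library(stressconn))

cardiac <- read.csv("results/cardiac.csv", stringsAsFactors = FALSE)
labels <- setNames(cardiac$label, cardiac$rat_id)

conn <- list()
for (b in lfp_bands()$name) {
  f <- sprintf("results/connectivity_%s_pre.csv", b)
  tab <- read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -(1:2)])
  rownames(m) <- tab$rat_id
  for (id in tab$rat_id) {
    if (is.null(conn[[id]]))
      conn[[id]] <- matrix(NA_real_, nrow(lfp_bands()), ncol(m),
                           dimnames = list(lfp_bands()$name, colnames(m)))
    conn[[id]][b, ] <- m[id, ]
  }
}

ds <- impute_missing(restrict_to_imputable_pairs(
  build_cohort_dataset(conn, labels)))

rows <- list()
for (b in names(ds$bands)) {
  X <- ds$bands[[b]]
  pca <- pca_project(X)
  fit <- train_linear_svm(X, ds$labels)
  cv <- loocv_failure(X, ds$labels)
  rows[[b]] <- data.frame(band = b, failure_percent = cv$failure_percent,
                          pc1_ratio = pca$contribution_ratios[1],
                          top_pair = names(which.max(abs(fit$weights))))
  cat(sprintf("%-6s LOOCV failure %5.1f%%  PC1 ratio %.2f  top |weight| pair %s\n",
              b, cv$failure_percent, pca$contribution_ratios[1],
              rows[[b]]$top_pair))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/loocv.csv", row.names = FALSE)
best <- tab$band[which.min(tab$failure_percent)]
cat(sprintf("\nbest-separating band: %s (%.1f%% failure over %d rats)\n",
            best, min(tab$failure_percent), nrow(ds$bands[[1]])))
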