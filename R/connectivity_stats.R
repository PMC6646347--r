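#' Canonical unordered region pairs
#'
#' All unordered pairs of the given regions, ordered by the fixed
#' anterior-to-posterior region order (PL, S1, PPC, HPC, RSC, V1); the full
#' set yields `choose(6, 2) = 15` pairs.
#'
#' @param regions Regions to pair (default all of [LFP_REGIONS]).
#' @return Data frame with columns `a`, `b` and `pair` (e.g. `"PL-S1"`).
#' @export
region_pairs <- function(regions = LFP_REGIONS) {
  regions <- LFP_REGIONS[LFP_REGIONS %in% regions]
  if (length(regions) < 2)
    return(data.frame(a = character(0), b = character(0), pair = character(0),
                      stringsAsFactors = FALSE))
  cmb <- utils::combn(regions, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ],
             pair = paste(cmb[1, ], cmb[2, ], sep = "-"),
             stringsAsFactors = FALSE)
}

#' Pairwise band-power correlation (functional connectivity)
#'
#' Pearson correlation of the per-window band-power time series for every
#' unordered pair of recorded regions, aligned by window index. Pairs
#' involving an absent region are `NA`; a zero-variance series also yields
#' `NA`, with the affected pairs reported in the `"diagnostics"` attribute.
#'
#' @param spectrograms Named list of `band_power_series` (one per region),
#'   e.g. from [session_spectrograms()].
#' @param band Band name from [lfp_bands()].
#' @return Named numeric vector over the 15 canonical pairs (`NA` for
#'   unavailable pairs), with attributes `n_windows` and `diagnostics`.
#' @export
pairwise_power_correlation <- function(spectrograms, band) {
  stopifnot(band %in% lfp_bands()$name)
  pairs <- region_pairs()
  out <- stats::setNames(rep(NA_real_, nrow(pairs)), pairs$pair)
  diagnostics <- character(0)
  present <- names(spectrograms)
  n_windows <- NA_integer_
  if (length(present) >= 2) {
    n_windows <- min(vapply(spectrograms, function(s) nrow(s$band_power), integer(1)))
    if (n_windows < 10)
      stop("regions share only ", n_windows, " aligned windows; need >= 10")
    series <- vapply(spectrograms,
                     function(s) s$band_power[seq_len(n_windows), band],
                     numeric(n_windows))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$a[i]; b <- pairs$b[i]
      if (a %in% present && b %in% present) {
        if (stats::sd(series[, a]) == 0 || stats::sd(series[, b]) == 0) {
          diagnostics <- c(diagnostics,
                           paste0(pairs$pair[i], ": zero-variance band-power series"))
        } else {
          out[i] <- stats::cor(series[, a], series[, b])
        }
      }
    }
  }
  attr(out, "n_windows") <- n_windows
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Connectivity vectors for all bands of a session
#'
#' @param spectrograms Named list of `band_power_series`.
#' @return Matrix of bands (rows) by 15 canonical pairs (columns).
#' @export
session_connectivity <- function(spectrograms) {
  bands <- lfp_bands()$name
  t(vapply(bands, function(b)
    as.numeric(pairwise_power_correlation(spectrograms, b)),
    numeric(nrow(region_pairs())))) -> m
  dimnames(m) <- list(bands, region_pairs()$pair)
  m
}

#' Assemble a cohort connectivity dataset
#'
#' @param connectivity Named list (by rat id) of band x pair matrices from
#'   [session_connectivity()].
#' @param labels Named character vector of group labels
#'   (`"susceptible"`/`"resilient"`) per rat.
#' @return A `cohort_dataset` list: `rat_ids`, `labels`, and `bands`, a list
#'   mapping each band to a rats x 15 matrix of pair correlations (`NA` =
#'   missing).
#' @export
build_cohort_dataset <- function(connectivity, labels) {
  rat_ids <- names(connectivity)
  stopifnot(length(rat_ids) > 0, all(rat_ids %in% names(labels)))
  bands <- lfp_bands()$name
  per_band <- lapply(bands, function(b) {
    m <- t(vapply(connectivity, function(cm) cm[b, ],
                  numeric(nrow(region_pairs()))))
    rownames(m) <- rat_ids
    m
  })
  names(per_band) <- bands
  structure(list(rat_ids = rat_ids, labels = labels[rat_ids], bands = per_band),
            class = "cohort_dataset")
}

#' Pooled pair counts per group
#'
#' Each rat with `k` recorded regions contributes `choose(k, 2)` pairs;
#' counts are summed within groups. A complete 6-region rat contributes 15;
#' the recorded cohort's missing-region configuration yields 60 susceptible
#' and 66 resilient pairs.
#'
#' @param regions_per_rat Named list of recorded regions per rat.
#' @param labels Named group labels per rat.
#' @return Named integer vector of pooled pair counts per group.
#' @export
count_available_pairs <- function(regions_per_rat, labels) {
  k <- vapply(regions_per_rat, length, integer(1))
  per_rat <- choose(k, 2)
  out <- tapply(per_rat, factor(labels[names(regions_per_rat)]), sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Drop pairs without an observed donor in every group
#'
#' Pairs that no rat of some group recorded cannot be imputed by group means;
#' this restricts a cohort dataset to the pairs observed at least once in
#' each group (all 15 for the full-region cohort).
#'
#' @param cohort A `cohort_dataset`.
#' @return The cohort with unimputable pair columns removed (same columns
#'   across bands).
#' @export
restrict_to_imputable_pairs <- function(cohort) {
  groups <- unique(cohort$labels)
  ok <- rep(TRUE, ncol(cohort$bands[[1]]))
  for (b in names(cohort$bands))
    for (g in groups) {
      m <- cohort$bands[[b]][cohort$labels == g, , drop = FALSE]
      ok <- ok & colSums(!is.na(m)) > 0
    }
  cohort$bands <- lapply(cohort$bands, function(m) m[, ok, drop = FALSE])
  cohort
}

#' Impute missing pair correlations by group means
#'
#' Each missing (rat, pair, band) entry is replaced by the mean of the
#' observed values for that pair and band among the other rats of the same
#' group; observed entries are untouched. Errors if a (group, pair, band) has
#' no observed donor.
#'
#' @param cohort A `cohort_dataset` from [build_cohort_dataset()].
#' @return The cohort with complete 15-entry vectors per band.
#' @export
impute_missing <- function(cohort) {
  for (b in names(cohort$bands)) {
    m <- cohort$bands[[b]]
    for (g in unique(cohort$labels)) {
      rows <- which(cohort$labels == g)
      for (j in seq_len(ncol(m))) {
        miss <- rows[is.na(m[rows, j])]
        if (length(miss)) {
          donors <- m[rows, j][!is.na(m[rows, j])]
          if (length(donors) == 0)
            stop("no observed donor for group '", g, "', pair '",
                 colnames(m)[j], "', band '", b, "'")
          m[miss, j] <- mean(donors)
        }
      }
    }
    cohort$bands[[b]] <- m
  }
  cohort
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `d_max` is the supremum gap between the two empirical CDFs; the p-value is
#' the two-sided asymptotic approximation.
#'
#' @param x,y Numeric samples (each >= 2 values).
#' @return List with `d_max` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(d_max = unname(kt$statistic), p_value = kt$p.value)
}

#' Per-frequency two-group comparison of average spectra
#'
#' Two-sample Student's t-test (pooled variance) per frequency bin, followed
#' by Benjamini-Hochberg FDR correction across bins. Bins with zero variance
#' within both groups are flagged and excluded from the correction.
#'
#' @param spectra Rats x bins matrix of time-averaged power (column names =
#'   Hz).
#' @param labels Group label per rat (>= 2 rats per group).
#' @return Data frame with `freq`, `t`, `p`, `q` and `excluded`.
#' @export
per_frequency_group_test <- function(spectra, labels) {
  labels <- as.character(labels)
  groups <- unique(labels)
  stopifnot(length(groups) == 2)
  i1 <- labels == groups[1]; i2 <- labels == groups[2]
  n1 <- sum(i1); n2 <- sum(i2)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- colMeans(spectra[i1, , drop = FALSE])
  m2 <- colMeans(spectra[i2, , drop = FALSE])
  v1 <- apply(spectra[i1, , drop = FALSE], 2, stats::var)
  v2 <- apply(spectra[i2, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  excluded <- se == 0
  t_stat <- ifelse(excluded, NA_real_, (m1 - m2) / se)
  p <- 2 * stats::pt(abs(t_stat), df = n1 + n2 - 2, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[!excluded] <- stats::p.adjust(p[!excluded], method = "BH")
  freq <- suppressWarnings(as.numeric(colnames(spectra)))
  data.frame(freq = if (all(is.finite(freq))) freq else seq_along(p),
             t = t_stat, p = p, q = q, excluded = excluded)
}

#' Correlate per-animal connectivity with a cardiac delta metric
#'
#' For each band, the per-rat mean pair correlation (mean of the 15 pair
#' values) is correlated (Pearson, two-sided test) with the chosen delta
#' metric across rats.
#'
#' @param cohort An imputed `cohort_dataset`.
#' @param delta Named numeric vector of the delta metric per rat.
#' @return Data frame with `band`, `r` and `p`.
#' @export
correlate_connectivity_with_deltas <- function(cohort, delta) {
  stopifnot(length(cohort$rat_ids) >= 3, all(cohort$rat_ids %in% names(delta)))
  d <- delta[cohort$rat_ids]
  rows <- lapply(names(cohort$bands), function(b) {
    mpr <- rowMeans(cohort$bands[[b]])
    if (stats::sd(mpr) == 0 || stats::sd(d) == 0)
      stop("zero variance in band '", b, "' mean connectivity or delta metric")
    ct <- stats::cor.test(mpr, d)
    data.frame(band = b, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare per-rat behavioral scalars between groups
#'
#' Student's t-test (pooled variance) per variable, optionally followed by
#' Bonferroni correction (p multiplied by the number of variables, capped at
#' 1).
#'
#' @param values Rats x variables matrix (or named columns data frame).
#' @param labels Group label per rat (>= 2 per group).
#' @param correction `"bonferroni"` or `"none"`.
#' @return Data frame with `variable`, `t`, `p` (corrected when requested).
#' @export
behavior_group_compare <- function(values, labels, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  values <- as.matrix(values)
  labels <- as.character(labels)
  groups <- unique(labels)
  stopifnot(length(groups) == 2, min(table(labels)) >= 2)
  res <- lapply(seq_len(ncol(values)), function(j) {
    x <- values[labels == groups[1], j]
    y <- values[labels == groups[2], j]
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    se <- sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    # degenerate zero-variance data: identical groups test as no difference
    t_stat <- if (se == 0) { if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y)) }
      else (mean(x) - mean(y)) / se
    p <- 2 * stats::pt(abs(t_stat), df = length(x) + length(y) - 2,
                       lower.tail = FALSE)
    data.frame(variable = colnames(values)[j] %||% paste0("v", j),
               t = t_stat, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (correction == "bonferroni") res$p <- pmin(1, res$p * ncol(values))
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
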