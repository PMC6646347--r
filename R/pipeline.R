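#' Run configuration for the full analysis pipeline
#'
#' @param cohort Either a [cohort_sim_config()] (the cohort is simulated) or a
#'   path to a directory of session containers (two per rat,
#'   `<rat>_pre/` and `<rat>_post/`).
#' @param pre_window_min,post_window_min Cardiac delta windows in minutes
#'   (defaults: last 10 min of pre, first 30 min of post).
#' @param post_lfp_window_s Post-session LFP analysis window in seconds
#'   (default 1800, the first 30 min, mirroring the cardiac window).
#' @param svm_cost Linear SVM cost parameter.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort, pre_window_min = 10, post_window_min = 30,
                       post_lfp_window_s = 1800, svm_cost = 1) {
  structure(list(cohort = cohort, pre_window_min = pre_window_min,
                 post_window_min = post_window_min,
                 post_lfp_window_s = post_lfp_window_s, svm_cost = svm_cost),
            class = "run_config")
}

stage <- function(name, rat_id, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed for rat '", rat_id, "': ",
         conditionMessage(e), call. = FALSE))
}

load_rat_sessions <- function(cfg, i) {
  if (inherits(cfg$cohort, "cohort_sim_config")) {
    simulate_rat(cfg$cohort, i)
  } else {
    id <- cohort_rat_ids(cfg)[i]
    list(pre = read_session(file.path(cfg$cohort, paste0(id, "_pre"))),
         post = read_session(file.path(cfg$cohort, paste0(id, "_post"))))
  }
}

cohort_rat_ids <- function(cfg) {
  if (inherits(cfg$cohort, "cohort_sim_config")) return(cfg$cohort$rat_ids)
  dirs <- list.dirs(cfg$cohort, recursive = FALSE, full.names = FALSE)
  unique(sub("_(pre|post)$", "", dirs[grepl("_(pre|post)$", dirs)]))
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, rat by rat (bounded memory): ECG R-peak detection, arrhythmia
#' and HRV scoring, delta metrics and susceptibility classification; EMG rms
#' and sleep scoring on the pre session; LFP downsampling, spectrograms and
#' band-power connectivity on the pre session (full) and the first 30 min of
#' the post session. Then, at the cohort level: pooled-pair
#' Kolmogorov-Smirnov comparisons of the connectivity distributions between
#' the detected groups, per-frequency t-tests of the average spectra per
#' region (FDR corrected), group-mean imputation of missing pairs,
#' connectivity-vs-delta correlations, behavioral group comparison (sleep
#' duration), and per-band PCA plus linear-SVM leave-one-out prediction.
#' Deterministic given a fixed cohort seed.
#'
#' @param config A [run_config()] (a bare [cohort_sim_config()] is accepted
#'   and wrapped).
#' @return A `cohort_report` list; see [make_report()] for the serialized
#'   form.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "cohort_sim_config")) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  rat_ids <- cohort_rat_ids(config)
  n <- length(rat_ids)
  pairs <- region_pairs()

  cardiac_rows <- list(); behavior_rows <- list()
  conn_pre <- list(); conn_post <- list()
  spectra_pre <- list()  # region -> rat -> avg spectrum
  regions_per_rat <- list()
  truth <- list()

  for (i in seq_len(n)) {
    id <- rat_ids[i]
    sess <- stage("load", id, load_rat_sessions(config, i))
    if (!is.null(sess$pre$ground_truth))
      truth[[id]] <- sess$pre$ground_truth$true_group

    card <- stage("cardiac", id, {
      a <- cardiac_analysis(sess$pre, sess$post)
      d <- compute_deltas(a$pre, a$post, config$pre_window_min,
                          config$post_window_min)
      data.frame(rat_id = id, delta_arr = d$delta_arr, delta_hrv = d$delta_hrv,
                 label = classify_susceptibility(d$delta_arr, d$delta_hrv),
                 stringsAsFactors = FALSE)
    })
    cardiac_rows[[id]] <- card

    behavior_rows[[id]] <- stage("emg", id, {
      rms <- compute_rms(sess$pre$channels$EMG)
      sl <- detect_sleep(rms)
      sp <- if (!is.null(sess$pre$position))
        mean(compute_speed(sess$pre$position)$speed) else NA_real_
      data.frame(rat_id = id, sleep_s_pre = sleep_duration(sl),
                 mean_speed_pre = sp, stringsAsFactors = FALSE)
    })

    regions_per_rat[[id]] <- session_regions(sess$pre)
    if (length(regions_per_rat[[id]]) >= 2) {
      sp_pre <- stage("spectra", id, session_spectrograms(sess$pre))
      conn_pre[[id]] <- stage("connectivity", id, session_connectivity(sp_pre))
      for (r in names(sp_pre))
        spectra_pre[[r]][[id]] <- average_spectrum(sp_pre[[r]])
      if (length(session_regions(sess$post)) >= 2) {
        sp_post <- stage("spectra-post", id,
          session_spectrograms(sess$post,
                               max_duration_s = config$post_lfp_window_s))
        conn_post[[id]] <- stage("connectivity-post", id,
                                 session_connectivity(sp_post))
      }
    }
    rm(sess)
  }

  cardiac_tab <- do.call(rbind, cardiac_rows)
  rownames(cardiac_tab) <- NULL
  behavior_tab <- do.call(rbind, behavior_rows)
  rownames(behavior_tab) <- NULL
  labels <- stats::setNames(cardiac_tab$label, cardiac_tab$rat_id)

  report <- list(cardiac = cardiac_tab, behavior = behavior_tab,
                 true_group = if (length(truth)) unlist(truth) else NULL,
                 config = config)

  two_groups <- length(unique(labels[names(conn_pre)])) == 2 &&
    min(table(labels[names(conn_pre)])) >= 2

  if (length(conn_pre) >= 2) {
    lfp_rats <- names(conn_pre)
    report$pair_counts <- count_available_pairs(regions_per_rat[lfp_rats],
                                                labels[lfp_rats])
    ds_pre <- build_cohort_dataset(conn_pre, labels)
    report$connectivity_pre <- ds_pre
    if (two_groups) {
      report$ks_pre <- pooled_ks_by_band(ds_pre)
      ds_imp <- impute_missing(restrict_to_imputable_pairs(ds_pre))
      report$connectivity_pre_imputed <- ds_imp
      deltas_arr <- stats::setNames(cardiac_tab$delta_arr, cardiac_tab$rat_id)
      deltas_hrv <- stats::setNames(cardiac_tab$delta_hrv, cardiac_tab$rat_id)
      report$conn_delta_arr <- correlate_connectivity_with_deltas(ds_imp, deltas_arr)
      report$conn_delta_hrv <- correlate_connectivity_with_deltas(ds_imp, deltas_hrv)
      report$ml <- lapply(names(ds_imp$bands), function(b) {
        X <- ds_imp$bands[[b]]
        fit <- train_linear_svm(X, ds_imp$labels, C = config$svm_cost)
        cv <- loocv_failure(X, ds_imp$labels, C = config$svm_cost)
        pca <- pca_project(X)
        list(band = b, failure_percent = cv$failure_percent,
             weights = fit$weights, bias = fit$bias,
             pca_scores = pca$scores,
             contribution_ratios = pca$contribution_ratios)
      })
      names(report$ml) <- names(ds_imp$bands)
      report$spectral_tests <- lapply(spectra_pre, function(per_rat) {
        rats <- names(per_rat)
        if (length(unique(labels[rats])) < 2 || min(table(labels[rats])) < 2)
          return(NULL)
        per_frequency_group_test(do.call(rbind, per_rat), labels[rats])
      })
      report$behavior_tests <- behavior_group_compare(
        cbind(sleep_s_pre = behavior_tab$sleep_s_pre),
        labels[behavior_tab$rat_id], correction = "none")
    }
    if (length(conn_post) >= 4) {
      ds_post <- build_cohort_dataset(conn_post, labels)
      report$connectivity_post <- ds_post
      if (length(unique(labels[names(conn_post)])) == 2 &&
          min(table(labels[names(conn_post)])) >= 2)
        report$ks_post <- pooled_ks_by_band(ds_post)
    }
  }
  class(report) <- "cohort_report"
  report
}

#' Pooled-pair KS comparison per band
#'
#' Pools each group's observed (non-imputed) pair correlations across rats
#' and compares the two group distributions with the two-sample KS test, per
#' band. Pairs from the same rat are pooled as independent observations.
#'
#' @param dataset A `cohort_dataset`.
#' @return Data frame with `band`, `d_max`, `p` and the pooled group sizes.
#' @export
pooled_ks_by_band <- function(dataset) {
  groups <- sort(unique(dataset$labels))
  stopifnot(length(groups) == 2)
  rows <- lapply(names(dataset$bands), function(b) {
    m <- dataset$bands[[b]]
    x <- m[dataset$labels == groups[1], ]; x <- x[!is.na(x)]
    y <- m[dataset$labels == groups[2], ]; y <- y[!is.na(y)]
    ks <- ks_two_sample(x, y)
    out <- data.frame(band = b, d_max = ks$d_max, p = ks$p_value,
                      stringsAsFactors = FALSE)
    out[[paste0("n_", groups[1])]] <- length(x)
    out[[paste0("n_", groups[2])]] <- length(y)
    out
  })
  do.call(rbind, rows)
}

#' Serialize a cohort report to disk
#'
#' Writes deterministic CSV and JSON tables: per-rat cardiac and behavior
#' tables, per-band connectivity matrices (raw and imputed; rows in cohort
#' order, 15 columns in the fixed pair order), KS results, per-region
#' spectral q-values, per-band SVM/LOOCV/PCA results and the resolved run
#' configuration. Regenerating with an identical config and seed reproduces
#' byte-identical files.
#'
#' @param report A `cohort_report` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Invisible character vector of the files written.
#' @export
make_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wcsv <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wcsv(report$cardiac %||% data.frame(rat_id = character(0)), "cardiac.csv")
  wcsv(report$behavior %||% data.frame(rat_id = character(0)), "behavior.csv")
  conn_csv <- function(ds, suffix) {
    for (b in names(ds$bands)) {
      m <- ds$bands[[b]]
      df <- data.frame(rat_id = rownames(m), label = unname(ds$labels[rownames(m)]),
                       m, check.names = FALSE, stringsAsFactors = FALSE)
      wcsv(df, paste0("connectivity_", b, suffix, ".csv"))
    }
  }
  if (!is.null(report$connectivity_pre)) conn_csv(report$connectivity_pre, "_pre")
  if (!is.null(report$connectivity_pre_imputed))
    conn_csv(report$connectivity_pre_imputed, "_pre_imputed")
  if (!is.null(report$connectivity_post)) conn_csv(report$connectivity_post, "_post")
  if (!is.null(report$ks_pre)) wcsv(report$ks_pre, "ks_pre.csv")
  if (!is.null(report$ks_post)) wcsv(report$ks_post, "ks_post.csv")
  if (!is.null(report$conn_delta_arr)) wcsv(report$conn_delta_arr, "conn_delta_arr.csv")
  if (!is.null(report$conn_delta_hrv)) wcsv(report$conn_delta_hrv, "conn_delta_hrv.csv")
  if (!is.null(report$behavior_tests)) wcsv(report$behavior_tests, "behavior_tests.csv")
  for (r in names(report$spectral_tests %||% list()))
    if (!is.null(report$spectral_tests[[r]]))
      wcsv(report$spectral_tests[[r]], paste0("spectral_test_", r, ".csv"))
  if (!is.null(report$ml)) {
    loocv <- data.frame(
      band = names(report$ml),
      failure_percent = vapply(report$ml, `[[`, numeric(1), "failure_percent"))
    rownames(loocv) <- NULL
    wcsv(loocv, "loocv.csv")
    ml_json <- lapply(report$ml, function(m)
      list(band = m$band, failure_percent = m$failure_percent,
           weights = as.list(m$weights), bias = m$bias,
           contribution_ratios = m$contribution_ratios,
           pca_scores = apply(m$pca_scores, 1, as.list, simplify = FALSE)))
    f <- file.path(outdir, "ml.json")
    jsonlite::write_json(ml_json, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  prov <- list(
    seed = if (inherits(report$config$cohort, "cohort_sim_config"))
      report$config$cohort$seed else NULL,
    n_rats = nrow(report$cardiac),
    pre_window_min = report$config$pre_window_min,
    post_window_min = report$config$post_window_min,
    post_lfp_window_s = report$config$post_lfp_window_s,
    svm_cost = report$config$svm_cost,
    package_version = as.character(utils::packageVersion("stressconn")))
  f <- file.path(outdir, "config.json")
  jsonlite::write_json(prov, f, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, f)
  invisible(files)
}
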