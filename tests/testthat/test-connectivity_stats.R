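fake_sp <- function(region, series) {
  bp <- matrix(rep(series, 5), ncol = 5,
               dimnames = list(NULL, lfp_bands()$name))
  structure(list(region = region, window_times = seq_along(series) * 5 - 5,
                 freq = seq(1, 44.8, by = 0.2),
                 power = matrix(0, length(series), 220), band_power = bp),
            class = "band_power_series")
}

test_that("pairwise correlation recovers identity, negation and flags degeneracy", {
  set.seed(1)
  x <- rnorm(50) + 5
  sps <- list(PL = fake_sp("PL", x), S1 = fake_sp("S1", x),
              PPC = fake_sp("PPC", 10 - x), HPC = fake_sp("HPC", rep(2, 50)))
  r <- pairwise_power_correlation(sps, "theta")
  expect_equal(unname(r["PL-S1"]), 1)
  expect_equal(unname(r["PL-PPC"]), -1)
  expect_true(is.na(r["PL-HPC"]))
  expect_true(any(grepl("zero-variance", attr(r, "diagnostics"))))
  expect_true(is.na(r["RSC-V1"]))  # absent regions stay missing
  expect_equal(sum(!is.na(r)), 3)
})

test_that("correlations are invariant to per-region affine rescaling of band power", {
  set.seed(2)
  a <- rnorm(60) + 10; b <- 0.5 * a + rnorm(60)
  r1 <- pairwise_power_correlation(list(PL = fake_sp("PL", a),
                                        V1 = fake_sp("V1", b)), "delta")
  r2 <- pairwise_power_correlation(list(PL = fake_sp("PL", 3 * a + 7),
                                        V1 = fake_sp("V1", 0.1 * b - 2)), "delta")
  expect_equal(r1[["PL-V1"]], r2[["PL-V1"]], tolerance = 1e-12)
})

test_that("pooled pair counts reproduce the combinatorial worked examples", {
  # one complete rat: choose(6,2) = 15
  one <- count_available_pairs(list(r1 = LFP_REGIONS),
                               c(r1 = "susceptible"))
  expect_equal(unname(one["susceptible"]), 15)
  # 5 susceptible rats, 3 missing one region: 2*15 + 3*10 = 60
  # 6 resilient rats: 3 missing one, 1 missing two, 2 complete: 30 + 6 + 30 = 66
  regs <- list(S1 = LFP_REGIONS[-6], S2 = LFP_REGIONS[-5], S3 = LFP_REGIONS[-1],
               S4 = LFP_REGIONS, S5 = LFP_REGIONS,
               R1 = LFP_REGIONS[-6], R2 = LFP_REGIONS[-4], R3 = LFP_REGIONS[-2],
               R4 = LFP_REGIONS[1:4], R5 = LFP_REGIONS, R6 = LFP_REGIONS)
  labs <- c(rep("susceptible", 5), rep("resilient", 6))
  names(labs) <- names(regs)
  counts <- count_available_pairs(regs, labs)
  expect_equal(unname(counts["susceptible"]), 60)
  expect_equal(unname(counts["resilient"]), 66)
})

make_dataset <- function(mats, labels) {
  bands <- lfp_bands()$name
  per_band <- lapply(bands, function(b) mats)
  names(per_band) <- bands
  structure(list(rat_ids = rownames(mats), labels = labels, bands = per_band),
            class = "cohort_dataset")
}

test_that("imputation fills missing pairs with same-group means and nothing else", {
  m <- matrix(rnorm(45), 3, 15, dimnames = list(c("a", "b", "c"),
                                                region_pairs()$pair))
  m[3, 2] <- NA
  m[1, 2] <- 0.2; m[2, 2] <- 0.4
  labs <- c(a = "resilient", b = "resilient", c = "resilient")
  ds <- make_dataset(m, labs)
  imp <- impute_missing(ds)
  expect_equal(imp$bands$theta[3, 2], 0.3)
  # observed entries untouched, across every band
  for (b in names(imp$bands))
    expect_identical(imp$bands[[b]][-3, ], ds$bands[[b]][-3, ])
  # identity when nothing is missing
  ds2 <- make_dataset(matrix(rnorm(30), 2, 15,
                             dimnames = list(c("a", "b"), region_pairs()$pair)),
                      labs[1:2])
  expect_identical(impute_missing(ds2), ds2)
  # no donor in group -> error
  m3 <- m; m3[, 5] <- NA
  expect_error(impute_missing(make_dataset(m3, labs)), "donor")
})

test_that("KS statistic equals the exhaustive ECDF-gap maximum", {
  brute_d <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
  }
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$d_max, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$d_max, 1)
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(sample(5:20, 1)); y <- rnorm(sample(5:20, 1), mean = runif(1, 0, 2))
    ks <- ks_two_sample(x, y)
    expect_equal(ks$d_max, brute_d(x, y), tolerance = 1e-12)
    expect_true(ks$p_value > 0 && ks$p_value <= 1)
  }
  expect_error(ks_two_sample(1, c(1, 2)), ">= 2")
})

test_that("per-frequency t statistics match the pooled-variance closed form", {
  x <- rbind(matrix(c(1, 2, 3), 3, 1), matrix(c(4, 5, 6), 3, 1))
  colnames(x) <- "10.0"
  res <- per_frequency_group_test(x, rep(c("g1", "g2"), each = 3))
  # hand computation: means 2 and 5, pooled var 1, se = sqrt(2/3)
  expect_equal(res$t, (2 - 5) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(abs(res$t), 4, lower.tail = FALSE), tolerance = 1e-12)
  # duplicate groups: t = 0, q = 1
  set.seed(4)
  sp <- matrix(rnorm(40), 4, 10, dimnames = list(NULL, as.character(1:10)))
  dup <- rbind(sp[1:2, ], sp[1:2, ])
  res2 <- per_frequency_group_test(dup, rep(c("a", "b"), each = 2))
  expect_true(all(res2$t == 0))
  expect_true(all(res2$q == 1))
  # zero-variance bin is excluded, not propagated
  spz <- sp; spz[, 3] <- 7
  res3 <- per_frequency_group_test(spz, rep(c("a", "b"), each = 2))
  expect_true(res3$excluded[3])
  expect_true(is.na(res3$q[3]))
  expect_false(any(res3$excluded[-3]))
})

test_that("FDR correction controls the rejected-bin fraction under the null", {
  set.seed(5)
  frac <- vapply(1:50, function(i) {
    sp <- matrix(rlnorm(11 * 50), 11, 50,
                 dimnames = list(NULL, as.character(1:50)))
    res <- per_frequency_group_test(sp, c(rep("s", 5), rep("r", 6)))
    mean(res$q < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("connectivity-delta correlation recovers exact affine relations", {
  set.seed(6)
  m <- matrix(runif(60, -1, 1), 4, 15,
              dimnames = list(paste0("r", 1:4), region_pairs()$pair))
  ds <- make_dataset(m, setNames(rep(c("susceptible", "resilient"), 2),
                                 paste0("r", 1:4)))
  mpr <- rowMeans(m)
  res <- correlate_connectivity_with_deltas(ds, setNames(2 * mpr + 1, paste0("r", 1:4)))
  expect_equal(res$r, rep(1, 5), tolerance = 1e-9)
  res2 <- correlate_connectivity_with_deltas(ds, setNames(-mpr, paste0("r", 1:4)))
  expect_equal(res2$r, rep(-1, 5), tolerance = 1e-9)
  expect_error(correlate_connectivity_with_deltas(
    ds, setNames(rep(1, 4), paste0("r", 1:4))), "zero variance")
})

test_that("behavioral comparison applies Student's t and capped Bonferroni", {
  v <- cbind(a = c(1, 2, 3, 4, 5, 6))
  res <- behavior_group_compare(v, rep(c("g1", "g2"), each = 3), "none")
  expect_equal(res$t, (2 - 5) / sqrt(2 / 3), tolerance = 1e-12)
  # Bonferroni multiplies by the number of variables and caps at 1
  set.seed(7)
  v5 <- matrix(rnorm(30), 6, 5, dimnames = list(NULL, letters[1:5]))
  raw <- behavior_group_compare(v5, rep(c("g1", "g2"), each = 3), "none")
  cor5 <- behavior_group_compare(v5, rep(c("g1", "g2"), each = 3), "bonferroni")
  expect_equal(cor5$p, pmin(1, raw$p * 5), tolerance = 1e-12)
  # identical groups: p capped at 1
  vid <- cbind(x = c(1, 2, 1, 2))
  expect_equal(behavior_group_compare(vid, c("g1", "g1", "g2", "g2"),
                                      "bonferroni")$p, 1)
})
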