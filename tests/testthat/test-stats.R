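# direct simulation of a long metrics table for the FFR-vs-LLR layer
make_long_table <- function(seed, n_young = 22, n_old = 17,
                            ffr_snr_shift = 1.5, llr_snr_shift = 0,
                            ffr_lat_shift = -2, llr_lat_shift = 0,
                            ffr_amp_shift = 0.1, llr_amp_shift = 1.5) {
  set.seed(seed)
  subj <- sprintf("s%02d", 1:(n_young + n_old))
  age <- c(runif(n_young, 23, 41), runif(n_old, 401, 740))
  grp <- rep(c(0, 1), c(n_young, n_old))
  rows <- list()
  add <- function(kind, measure, base, shift, sdv) {
    for (tone in c("ga2", "ga4", "ga3")) {
      rows[[length(rows) + 1L]] <<- data.frame(
        subject_id = subj, age_days = age, tone = tone,
        nativeness = ifelse(tone == "ga3", "nonnative", "native"),
        response_kind = kind, measure = measure,
        value = base + shift * grp + rnorm(length(age), 0, sdv),
        stringsAsFactors = FALSE)
    }
  }
  add("ffr", "snr", 2, ffr_snr_shift, 1)
  add("ffr", "amplitude", 0.2, ffr_amp_shift, 0.08)
  add("ffr", "latency", 25, ffr_lat_shift, 1)
  add("llr", "snr", 8, llr_snr_shift, 2)
  add("llr", "amplitude", 5, llr_amp_shift, 1.2)
  add("llr", "latency", 270, llr_lat_shift, 25)
  do.call(rbind, rows)
}

test_that("partial eta squared reproduces every reference (F, df) pairing", {
  reference <- list(
    list(19.21, 1, 473, 0.04), # age on FFR SNR
    list(10.91, 1, 473, 0.02), # age on lower band power
    list(17.48, 1, 473, 0.04), # age on middle band power
    list(7.24, 1, 473, 0.02),  # age on pitch strength
    list(4.12, 2, 473, 0.02),  # tone on pitch strength
    list(9.14, 1, 409, 0.02),  # age on P1 amplitude
    list(9.92, 1, 620, 0.02),  # age category, combined model
    list(5.62, 1, 620, 0.01),  # age x ERP-type interaction
    list(10.6, 1, 317, 0.03),  # split: early-latency age effect
    list(0.14, 1, 11, 0.01)    # quadratic term in the trend model
  )
  for (p in reference) {
    expect_equal(round(partial_eta_sq(p[[1]], p[[2]], p[[3]]), 2), p[[4]])
  }
  expect_lt(partial_eta_sq(0.018, 1, 303), 0.001)
})

test_that("reference Bonferroni ratios imply a 13-metric battery", {
  expect_equal(bonferroni_factor_check(1.44e-5, 2e-4), 13.9, tolerance = 0.01)
  expect_equal(bonferroni_factor_check(0.0010, 0.0133), 13.3,
               tolerance = 0.01)
  x <- c(0.003, 0.04)
  expect_equal(bonferroni_factor_check(x, pmin(1, 13 * x)), c(13, 13))
  expect_error(bonferroni_factor_check(0, 0.1), "p values")
})

test_that("the metric LME recovers age effects and reports the battery", {
  spec <- cohort_spec(n_subjects = 60)
  tbl <- simulate_metrics(spec, seed = 21, b0 = 2, b_age = 0.004,
                          re_sd = 0.8, sigma = 1)
  names(tbl)[names(tbl) == "value"] <- "snr_db"
  res <- fit_metric_lme(tbl, "snr_db")
  expect_setequal(res$effect, c("age_days", "tone", "age_days:tone"))
  age <- res[res$effect == "age_days", ]
  expect_lt(age$p, 1e-6)
  expect_equal(age$p_bonferroni, min(1, age$p * 13))
  expect_equal(age$partial_eta_sq,
               age$F * age$df1 / (age$F * age$df1 + age$df2))
  expect_gt(res$p[res$effect == "age_days:tone"], 0.01)
  # row order does not matter
  res2 <- fit_metric_lme(tbl[sample(nrow(tbl)), ], "snr_db")
  expect_equal(res2$F, res$F, tolerance = 1e-8)
  expect_error(fit_metric_lme(tbl, "missing_metric"), "missing_metric")
})

test_that("the rank-sum test agrees with an exact enumeration oracle (n <= 8)", {
  # oracle: enumerate every assignment of pooled ranks to group 1
  oracle_p <- function(x, y) {
    n1 <- length(x); n <- n1 + length(y)
    rk <- rank(c(x, y))
    W <- sum(rk[seq_len(n1)])
    mu <- n1 * (n + 1) / 2
    sums <- utils::combn(rk, n1, sum)
    mean(abs(sums - mu) >= abs(W - mu) - 1e-12)
  }
  set.seed(14)
  for (i in 1:6) {
    x <- round(rnorm(sample(3:4, 1)), 1)
    y <- round(rnorm(sample(3:4, 1), mean = i / 4), 1)
    t <- rank_sum_test(x, y, exact = TRUE)
    expect_equal(t$p, oracle_p(x, y))
  }
  # normal approximation matches the independent base-R implementation
  set.seed(15)
  x <- rnorm(60); y <- rnorm(55, 0.5)
  t <- rank_sum_test(x, y, exact = FALSE)
  ref <- stats::wilcox.test(x, y, correct = FALSE, exact = FALSE)
  expect_equal(t$p, ref$p.value, tolerance = 1e-9)
  expect_equal(t$r, t$Z / sqrt(115))
})

test_that("the 165-day cutoff analysis isolates native-only latency change", {
  set.seed(22)
  n <- 70
  subj <- sprintf("s%02d", 1:n)
  age <- c(runif(n / 2, 30, 160), runif(n / 2, 170, 700))
  mk <- function(tone) {
    native <- tone != "ga3"
    shift <- ifelse(native & age > 165, -40, 0)
    data.frame(subject_id = subj, age_days = age, tone = tone,
               nativeness = ifelse(native, "native", "nonnative"),
               p1_latency_ms = 280 + shift + rnorm(n, 0, 18),
               stringsAsFactors = FALSE)
  }
  tbl <- rbind(mk("ga2"), mk("ga4"), mk("ga3"))
  res <- wilcoxon_cutoff(tbl, "p1_latency_ms")
  expect_setequal(res$group,
                  c("native_pooled", "native_averaged", "nonnative"))
  native <- res[res$group == "native_pooled", ]
  expect_lt(native$Z, 0) # latency shortens after the cutoff
  expect_lt(native$p, 0.001)
  expect_lt(res$Z[res$group == "native_averaged"], 0)
  expect_gt(res$p[res$group == "nonnative"], 0.05)
  expect_equal(native$r, native$Z / sqrt(native$n_young + native$n_old))
  # identical distributions: Z near zero
  tbl0 <- tbl
  tbl0$p1_latency_ms <- rep_len(c(250, 260, 270, 280), nrow(tbl0))
  res0 <- wilcoxon_cutoff(tbl0, "p1_latency_ms")
  expect_lt(abs(res0$Z[1]), 1)
  expect_gt(res0$p[1], 0.1)
})

test_that("normalized age-group effect sizes separate FFR and LLR maturation", {
  long <- make_long_table(seed = 31)
  es <- age_group_effect_sizes(long)
  expect_setequal(unique(es$measure), c("snr", "amplitude", "latency"))
  ffr_snr <- es[es$response_kind == "ffr" & es$measure == "snr", ]
  llr_snr <- es[es$response_kind == "llr" & es$measure == "snr", ]
  expect_gt(ffr_snr$slope, llr_snr$slope)
  expect_gt(ffr_snr$ci_lo, llr_snr$ci_hi) # non-overlapping CIs
  expect_true(all(es$ci_lo <= es$slope & es$slope <= es$ci_hi))
  # null measure: slope CI spans zero
  expect_lt(llr_snr$ci_lo, 0)
  expect_gt(llr_snr$ci_hi, 0)
  # a unit (1 SD) group effect is recovered within its CI
  set.seed(5)
  g <- rep(c(0, 1), c(39, 39))
  val <- g * 1 + rnorm(78) # 1 SD shift before normalization
  tbl1 <- data.frame(subject_id = sprintf("s%d", 1:78),
                     age_days = ifelse(g == 1, 500, 30), tone = "ga2",
                     nativeness = "native", response_kind = "ffr",
                     measure = "snr", value = val)
  es1 <- age_group_effect_sizes(tbl1)
  z_effect <- 1 / stats::sd(val) # the shift on the z-scored scale
  expect_true(es1$ci_lo < z_effect && z_effect < es1$ci_hi)
})

test_that("the combined LME finds the age x ERP-type interaction and splits", {
  # FFR-only maturation: every LLR measure is null
  long <- make_long_table(seed = 33, ffr_snr_shift = 2, ffr_lat_shift = -3,
                          llr_amp_shift = 0)
  res <- combined_lme(long)
  eff <- res$combined
  expect_true(all(c("age_cat", "age_cat:erp_type") %in% eff$effect))
  expect_lt(eff$p[eff$effect == "age_cat:erp_type"], 0.05)
  expect_lt(res$splits$ffr$p[res$splits$ffr$effect == "age_cat"], 0.01)
  expect_gt(res$splits$llr$p[res$splits$llr$effect == "age_cat"], 0.05)
  # sign-flipping latency leaves the age-category F unchanged when the
  # flip switch compensates
  long_flipped <- long
  sel <- long_flipped$measure == "latency"
  long_flipped$value[sel] <- -long_flipped$value[sel]
  res2 <- combined_lme(long_flipped, flip_latency = FALSE)
  expect_equal(res2$combined$F[res2$combined$effect == "age_cat"],
               eff$F[eff$effect == "age_cat"], tolerance = 1e-6)
  # statistics are invariant to row order
  res3 <- combined_lme(long[sample(nrow(long)), ])
  expect_equal(sort(res3$combined$F), sort(eff$F), tolerance = 1e-8)
})
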