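## Inferential layer: mixed-effects age x tone models with Bonferroni
## adjustment and partial eta squared, rank-sum tests across the 165-day
## cutoff, normalized 42/400-day age-group effect sizes, and the combined
## four-factor mixed model with split follow-ups.

# Bonferroni multiplier: the metric battery size (reverse-engineered from
# the reported raw/adjusted p ratios (~13 across the documented cases))
BONFERRONI_M <- 13

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`.
#'
#' @param f F value.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @export
partial_eta_sq <- function(f, df1, df2) {
  f * df1 / (f * df1 + df2)
}

#' Implied Bonferroni battery size
#'
#' Ratio of an adjusted to a raw p value, used to document the multiplier a
#' reported battery implies (`p_adj = min(1, m * p_raw)` below saturation).
#'
#' @param p_raw,p_adj Raw and adjusted p values in (0, 1].
#' @return `p_adj / p_raw`.
#' @export
bonferroni_factor_check <- function(p_raw, p_adj) {
  assert_that(all(p_raw > 0 & p_raw <= 1) && all(p_adj > 0 & p_adj <= 1),
              "p values must be in (0, 1]")
  p_adj / p_raw
}

#' Linear mixed-effects model for one metric
#'
#' Fits `value ~ age_days * tone` with a subject random intercept (REML),
#' and reports marginal (type-III style, sum-to-zero contrasts) F tests for
#' the fixed effects with Bonferroni-adjusted p values and partial eta
#' squared. Denominator degrees of freedom follow nlme's within-group rule;
#' this approximation is a documented configuration choice.
#'
#' @param tbl data.frame with columns `subject_id`, `age_days`, `tone`,
#'   and the metric column.
#' @param metric Name of the metric column.
#' @param m_bonferroni Battery size for the Bonferroni adjustment.
#' @return data.frame of class `lme_stat_result`: effect, F, df1, df2, p,
#'   p_bonferroni, partial_eta_sq, singular flag.
#' @export
fit_metric_lme <- function(tbl, metric, m_bonferroni = BONFERRONI_M) {
  assert_that(metric %in% names(tbl), paste("no column", metric))
  d <- tbl[!is.na(tbl[[metric]]), ]
  assert_that(length(unique(d$subject_id)) >= 2, "need >= 2 subjects")
  d$.value <- d[[metric]]
  d$tone <- factor(d$tone)
  d$subject_id <- factor(d$subject_id)
  singular <- FALSE
  fit <- withCallingHandlers(
    tryCatch(
      nlme::lme(.value ~ age_days * tone, random = ~ 1 | subject_id,
                data = d, method = "REML",
                contrasts = list(tone = "contr.sum")),
      error = function(e) {
        singular <<- TRUE
        # fall back to a tiny-variance-tolerant fit
        nlme::lme(.value ~ age_days * tone, random = ~ 1 | subject_id,
                  data = d, method = "REML",
                  contrasts = list(tone = "contr.sum"),
                  control = nlme::lmeControl(opt = "optim",
                                             returnObject = TRUE))
      }),
    warning = function(w) { singular <<- TRUE; invokeRestart("muffleWarning") })
  av <- stats::anova(fit, type = "marginal")
  keep <- rownames(av) != "(Intercept)"
  res <- data.frame(
    effect = rownames(av)[keep],
    F = av$`F-value`[keep],
    df1 = av$numDF[keep],
    df2 = av$denDF[keep],
    p = av$`p-value`[keep],
    stringsAsFactors = FALSE
  )
  res$p_bonferroni <- pmin(1, res$p * m_bonferroni)
  res$partial_eta_sq <- partial_eta_sq(res$F, res$df1, res$df2)
  res$singular <- singular
  class(res) <- c("lme_stat_result", "data.frame")
  res
}

# --- rank-sum machinery ----------------------------------------------------

#' Wilcoxon rank-sum test (normal approximation or exact enumeration)
#'
#' Midranks handle ties; the normal approximation uses the tie-corrected
#' variance and no continuity correction. With `exact = TRUE` (feasible for
#' small samples) the two-sided p value is computed by enumerating all
#' assignments of the pooled observations to the first group.
#'
#' @param x,y Numeric samples (x is the "test" group; a negative Z means x
#'   tends to be smaller than y).
#' @param exact Force exact enumeration (default: exact when
#'   `choose(n, nx) <= 2e5`).
#' @return list(Z, p, r, W, n, exact): `r = Z / sqrt(n)` is the rank effect
#'   size.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  assert_that(length(x) > 0 && length(y) > 0, "both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  Z <- if (v > 0) (W - mu) / sqrt(v) else 0
  if (is.null(exact)) exact <- choose(n, n1) <= 2e5
  if (exact) {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(rk[combs], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(W - mu) - 1e-12)
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
  }
  list(Z = Z, p = min(p, 1), r = Z / sqrt(n), W = W, n = n, exact = exact)
}

#' Age-cutoff rank-sum tests by nativeness
#'
#' Splits a metric at an age cutoff (default 165 days ~ 6 months) and runs
#' rank-sum tests of old vs. young separately for native tones -- both
#' pooled (/ga2/ and /ga4/ rows) and averaged (per subject-visit mean of the
#' two) -- and for the non-native tone. Effect size r = Z / sqrt(N).
#'
#' @param tbl data.frame with `subject_id`, `age_days`, `tone`,
#'   `nativeness`, and the metric column; one row per subject-visit-tone.
#' @param metric Metric column name.
#' @param cutoff_days Age cutoff in days.
#' @param exact Passed to [rank_sum_test()].
#' @return data.frame: group, Z, p, r, n_young, n_old.
#' @export
wilcoxon_cutoff <- function(tbl, metric, cutoff_days = 165, exact = FALSE) {
  assert_that(metric %in% names(tbl), paste("no column", metric))
  d <- tbl[!is.na(tbl[[metric]]), ]
  run <- function(dd, label) {
    young <- dd[[metric]][dd$age_days <= cutoff_days]
    old <- dd[[metric]][dd$age_days > cutoff_days]
    assert_that(length(young) > 0 && length(old) > 0,
                paste("empty age group for", label))
    t <- rank_sum_test(old, young, exact = exact)
    data.frame(group = label, Z = t$Z, p = t$p, r = t$r,
               n_young = length(young), n_old = length(old),
               stringsAsFactors = FALSE)
  }
  native <- d[d$nativeness == "native", ]
  nonnative <- d[d$nativeness == "nonnative", ]
  avg <- stats::aggregate(native[[metric]],
                          by = list(subject_id = native$subject_id,
                                    age_days = native$age_days),
                          FUN = mean)
  names(avg)[3] <- metric
  avg$nativeness <- "native"
  rbind(
    run(native, "native_pooled"),
    run(avg, "native_averaged"),
    run(nonnative, "nonnative")
  )
}

# --- 42/400-day effect sizes ----------------------------------------------

#' Normalized age-group effect sizes for FFR vs. LLR measures
#'
#' Restricts the table to the extreme age groups (younger than `young_max`
#' days, older than `old_min` days), z-scores each (response kind, measure)
#' across the two groups, and reports the slope of the normalized metric on
#' the old-group indicator with its 95% CI -- the maturation effect size on
#' a common scale.
#'
#' @param tbl Long data.frame: `subject_id`, `age_days`, `response_kind`
#'   (`"ffr"`/`"llr"`), `measure` (`"snr"`, `"amplitude"`, `"latency"`),
#'   `value`.
#' @param young_max,old_min Age-group cutoffs in days.
#' @return data.frame: response_kind, measure, slope, ci_lo, ci_hi,
#'   n_young, n_old.
#' @export
age_group_effect_sizes <- function(tbl, young_max = 42, old_min = 400) {
  d <- tbl[!is.na(tbl$value) &
           (tbl$age_days < young_max | tbl$age_days > old_min), ]
  assert_that(nrow(d) > 0, "no observations in the extreme age groups")
  d$old <- d$age_days > old_min
  out <- list()
  for (kind in unique(d$response_kind)) {
    for (ms in unique(d$measure[d$response_kind == kind])) {
      dd <- d[d$response_kind == kind & d$measure == ms, ]
      if (length(unique(dd$old)) < 2 || nrow(dd) < 4) {
        message("skipping ", kind, "/", ms, ": a group is empty")
        next
      }
      z <- (dd$value - mean(dd$value)) / stats::sd(dd$value)
      fit <- stats::lm(z ~ old, data = data.frame(z = z, old = dd$old))
      ci <- stats::confint(fit)["oldTRUE", ]
      out[[paste(kind, ms)]] <- data.frame(
        response_kind = kind, measure = ms,
        slope = unname(stats::coef(fit)["oldTRUE"]),
        ci_lo = ci[1], ci_hi = ci[2],
        n_young = sum(!dd$old), n_old = sum(dd$old),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combined four-factor mixed model with split follow-ups
#'
#' Z-scores each (response kind, measure) across the two extreme age groups
#' (latency is sign-flipped by default so that maturation is positive for
#' every measure), then fits a mixed model with Age category, Tone, ERP type
#' and ERP measure as fixed effects (main effects and two-way interactions)
#' and subject as a random intercept. Follow-up models split by ERP type
#' test the age-category effect within each response class.
#'
#' @inheritParams age_group_effect_sizes
#' @param flip_latency Sign-flip latency so shorter = more mature.
#' @return list(combined, splits): marginal F-test tables (with partial eta
#'   squared) for the combined model and for each split.
#' @export
combined_lme <- function(tbl, young_max = 42, old_min = 400,
                         flip_latency = TRUE) {
  d <- tbl[!is.na(tbl$value) &
           (tbl$age_days < young_max | tbl$age_days > old_min), ]
  assert_that(all(c("ffr", "llr") %in% d$response_kind),
              "both response kinds must be present")
  d$age_cat <- factor(ifelse(d$age_days > old_min, "old", "young"),
                      levels = c("young", "old"))
  parts <- list()
  for (kind in unique(d$response_kind)) {
    for (ms in unique(d$measure)) {
      dd <- d[d$response_kind == kind & d$measure == ms, ]
      if (nrow(dd) == 0) next
      dd$value <- (dd$value - mean(dd$value)) / stats::sd(dd$value)
      if (flip_latency && ms == "latency") dd$value <- -dd$value
      parts[[paste(kind, ms)]] <- dd
    }
  }
  d <- do.call(rbind, parts)
  d$erp_type <- factor(d$response_kind)
  d$measure <- factor(d$measure)
  d$tone <- factor(d$tone)
  d$subject_id <- factor(d$subject_id)
  ctr <- list(age_cat = "contr.sum", tone = "contr.sum",
              erp_type = "contr.sum", measure = "contr.sum")
  fit <- tryCatch(
    nlme::lme(value ~ (age_cat + tone + erp_type + measure)^2,
              random = ~ 1 | subject_id, data = d, method = "REML",
              contrasts = ctr),
    error = function(e) {
      stop("combined model is rank-deficient or failed: ", conditionMessage(e),
           call. = FALSE)
    })
  ftab <- function(f) {
    av <- stats::anova(f, type = "marginal")
    keep <- rownames(av) != "(Intercept)"
    data.frame(effect = rownames(av)[keep], F = av$`F-value`[keep],
               df1 = av$numDF[keep], df2 = av$denDF[keep],
               p = av$`p-value`[keep],
               partial_eta_sq = partial_eta_sq(av$`F-value`[keep],
                                               av$numDF[keep],
                                               av$denDF[keep]),
               stringsAsFactors = FALSE)
  }
  splits <- lapply(split(d, d$erp_type), function(dd) {
    f <- nlme::lme(value ~ age_cat + tone + measure,
                   random = ~ 1 | subject_id, data = droplevels(dd),
                   method = "REML",
                   contrasts = ctr[c("age_cat", "tone", "measure")])
    ftab(f)
  })
  list(combined = ftab(fit), splits = splits)
}
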