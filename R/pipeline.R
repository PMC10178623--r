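## End-to-end driver: simulate -> preprocess (FFR and LLR) -> metrics ->
## classification -> group statistics, with a run manifest that fully
## determines a re-run. Blocks are generated and preprocessed one at a time
## so cohort size is bounded by disk, not memory.

cohort_spec_from_config <- function(config) {
  keys <- intersect(names(config), names(formals(cohort_spec)))
  do.call(cohort_spec, config[keys])
}

#' Run the full analysis pipeline
#'
#' Executes simulate, the two preprocessing pipelines, FFR and LLR metrics,
#' per-month classification and the group-statistics battery, writing every
#' stage's outputs (and a run manifest) to `out_dir`. All randomness derives
#' from the master seed; re-running with the same configuration reproduces
#' the metrics tables byte-for-byte.
#'
#' @param config Named list or path to a flat key-value config file. Keys:
#'   `seed` (mandatory), any [cohort_spec()] argument, plus `B` (bootstrap
#'   count, default 200), `min_obs` (month-bin threshold, default 10),
#'   `tracking` (compute per-block ITPC tracking r^2; slow, default FALSE),
#'   `keep_dataset` (also write the raw dataset, default FALSE).
#' @param out_dir Writable output directory.
#' @return Invisibly, the run manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  assert_that(!is.null(config$seed), "config must set `seed`")
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), "output directory is not writable")
  spec <- cohort_spec_from_config(config)
  B <- if (is.null(config$B)) 200 else config$B
  min_obs <- if (is.null(config$min_obs)) 10 else config$min_obs
  tracking <- isTRUE(config$tracking)

  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("ffrdev")),
                   stages = list())

  ## stage: simulate (visit structure; blocks are generated lazily below)
  visits <- cohort_visits(spec, seed)
  utils::write.csv(visits, file.path(out_dir, "visits.csv"), row.names = FALSE)
  manifest$stages$simulate <- list(n_subjects = length(unique(visits$subject_id)),
                                   n_visits = nrow(visits))

  stimuli <- lapply(spec$tones, synthesize_stimulus,
                    sampling_rate = spec$sampling_rate)
  names(stimuli) <- spec$tones
  cfg_ffr <- pipeline_config("ffr")
  cfg_llr <- pipeline_config("llr")

  qc_rows <- list()
  ffr_rows <- list()
  llr_rows <- list()
  ffr_averages <- list()
  dataset_dir <- file.path(out_dir, "dataset")
  if (isTRUE(config$keep_dataset)) {
    dir.create(file.path(dataset_dir, "blocks"), recursive = TRUE,
               showWarnings = FALSE)
  }

  for (i in seq_len(nrow(visits))) {
    sid <- visits$subject_id[i]
    v <- visits$visit[i]
    age <- visits$age_days[i]
    prof <- draw_profile(spec, sid, visits$age_days[visits$subject_id == sid],
                         derive_seed(seed, sid, "prof"))
    for (tone in spec$tones) {
      for (kind in spec$response_kinds) {
        bs <- block_seed(seed, sid, v, tone, kind)
        blk <- if (kind == "ffr") {
          generate_ffr_block(prof, stimuli[[tone]], bs, age_days = age,
                             n_sweeps = spec$n_sweeps)
        } else {
          generate_llr_block(prof, stimuli[[tone]], bs, age_days = age,
                             n_sweeps = spec$n_sweeps)
        }
        if (isTRUE(config$keep_dataset)) {
          saveRDS(blk, file.path(dataset_dir, "blocks",
                                 paste(sid, v, tone, kind, "raw.rds",
                                       sep = "_")))
        }
        pp <- preprocess_block(blk, if (kind == "ffr") cfg_ffr else cfg_llr)
        qc_rows[[length(qc_rows) + 1L]] <- data.frame(
          subject_id = sid, visit = v, age_days = age, tone = tone,
          response_kind = kind, rejected_count = pp$qc$rejected_count,
          decision = if (pp$qc$accept) "accept" else "reject",
          reason = pp$qc$reason, stringsAsFactors = FALSE)
        if (!pp$qc$accept) {
          message("QC reject [", kind, "] ", sid, " v", v, " ", tone, ": ",
                  pp$qc$reason)
          next
        }
        if (kind == "ffr") {
          ffr_rows[[length(ffr_rows) + 1L]] <-
            ffr_block_metrics(pp, stimulus = if (tracking) stimuli[[tone]])
          ffr_averages[[length(ffr_averages) + 1L]] <- pp$averaged
        } else {
          llr_rows[[length(llr_rows) + 1L]] <- llr_block_metrics(pp)
        }
      }
    }
  }

  qc_log <- do.call(rbind, qc_rows)
  utils::write.csv(qc_log, file.path(out_dir, "qc_log.csv"), row.names = FALSE)
  manifest$stages$preprocess <- list(
    n_blocks = nrow(qc_log),
    n_accepted = sum(qc_log$decision == "accept"),
    n_rejected = sum(qc_log$decision == "reject"))

  metrics_ffr <- do.call(rbind, ffr_rows)
  metrics_llr <- do.call(rbind, llr_rows)
  utils::write.csv(metrics_ffr, file.path(out_dir, "metrics_ffr.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics_llr, file.path(out_dir, "metrics_llr.csv"),
                   row.names = FALSE)
  manifest$stages$metrics <- list(ffr_rows = nrow(metrics_ffr),
                                  llr_rows = nrow(metrics_llr))

  ## stage: classification
  classification <- tryCatch({
    feats <- build_features(ffr_averages)
    res <- classify_by_month(feats, B = B, seed = derive_seed(seed, "classify"),
                             min_obs = min_obs)
    utils::write.csv(res$summary, file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    trend <- if (nrow(res$summary) >= 4) {
      accuracy_age_trend(res$summary$month, res$summary$real_median)
    }
    list(summary = res$summary, trend = trend)
  }, error = function(e) {
    message("classification stage skipped: ", conditionMessage(e))
    list(skipped = conditionMessage(e))
  })
  manifest$stages$classification <-
    if (!is.null(classification$skipped)) list(skipped = classification$skipped)
    else list(n_bins = nrow(classification$summary), B = B)

  ## stage: group statistics
  stats_report <- list()
  lme_try <- function(tbl, metric) {
    tryCatch(fit_metric_lme(tbl, metric),
             error = function(e) list(skipped = conditionMessage(e)))
  }
  if (!is.null(metrics_ffr) && nrow(metrics_ffr) > 0) {
    stats_report$ffr_lme <- lapply(
      c("snr_db", "pitch_strength", "low_power", "mid_power"),
      function(m) lme_try(metrics_ffr, m))
    names(stats_report$ffr_lme) <- c("snr_db", "pitch_strength", "low_power",
                                     "mid_power")
  }
  if (!is.null(metrics_llr) && nrow(metrics_llr) > 0) {
    stats_report$llr_lme <- lapply(
      c("snr_db", "p1_amplitude_uv", "p1_latency_ms"),
      function(m) lme_try(metrics_llr, m))
    names(stats_report$llr_lme) <- c("snr_db", "p1_amplitude_uv",
                                     "p1_latency_ms")
    stats_report$wilcoxon <- lapply(
      c("p1_latency_ms", "p1_amplitude_uv"),
      function(m) tryCatch(wilcoxon_cutoff(metrics_llr, m),
                           error = function(e) list(skipped = conditionMessage(e))))
    names(stats_report$wilcoxon) <- c("p1_latency_ms", "p1_amplitude_uv")
  }
  long <- tryCatch(metrics_long_table(metrics_ffr, metrics_llr),
                   error = function(e) NULL)
  if (!is.null(long)) {
    stats_report$effect_sizes <- tryCatch(
      age_group_effect_sizes(long),
      error = function(e) list(skipped = conditionMessage(e)))
    stats_report$combined_lme <- tryCatch(
      combined_lme(long),
      error = function(e) list(skipped = conditionMessage(e)))
  }
  stats_report$classification <- classification
  jsonlite::write_json(stats_report, file.path(out_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")

  outputs <- c("visits.csv", "qc_log.csv", "metrics_ffr.csv",
               "metrics_llr.csv", "stats_report.json")
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  manifest$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(file.path(out_dir, outputs))), outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(manifest)
}

#' Long-format metrics table for the FFR vs. LLR comparison
#'
#' Assembles the three measures shared by both response kinds (SNR, peak
#' amplitude, peak latency) into the long format consumed by
#' [age_group_effect_sizes()] and [combined_lme()].
#'
#' @param metrics_ffr,metrics_llr Metric tables from the pipeline.
#' @return Long data.frame: subject_id, age_days, tone, nativeness,
#'   response_kind, measure, value.
#' @export
metrics_long_table <- function(metrics_ffr, metrics_llr) {
  pull <- function(d, kind, map) {
    do.call(rbind, lapply(names(map), function(ms) {
      data.frame(subject_id = d$subject_id, age_days = d$age_days,
                 tone = d$tone, nativeness = d$nativeness,
                 response_kind = kind, measure = ms,
                 value = d[[map[[ms]]]], stringsAsFactors = FALSE)
    }))
  }
  rbind(
    pull(metrics_ffr, "ffr", list(snr = "snr_db",
                                  amplitude = "peak_amplitude_uv",
                                  latency = "peak_latency_ms")),
    pull(metrics_llr, "llr", list(snr = "snr_db",
                                  amplitude = "p1_amplitude_uv",
                                  latency = "p1_latency_ms"))
  )
}
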