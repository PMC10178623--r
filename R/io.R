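## Dataset container, flat-text configuration, and QC logging.
##
## A cohort is stored as a directory: a `visits.csv` subject/visit table,
## a `spec.json` snapshot, a `manifest.csv` (one row per block with its
## checksum) and one serialized epoch block per file under `blocks/`.
## Epoch matrices round-trip exactly.

#' Write a cohort dataset to a directory
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(file.path(dir, "blocks"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(spec[!vapply(spec, is.function, logical(1))],
                       file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  rows <- lapply(names(cohort$blocks), function(key) {
    b <- cohort$blocks[[key]]
    f <- file.path("blocks", paste0(key, ".rds"))
    saveRDS(b, file.path(dir, f))
    data.frame(key = key, file = f, subject_id = b$subject_id,
               age_days = b$age_days, tone = b$tone_id,
               response_kind = b$response_kind,
               n_sweeps = nrow(b$epochs),
               checksum = unname(tools::md5sum(file.path(dir, f))),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$seed)) {
    writeLines(paste0("seed: ", cohort$seed), file.path(dir, "seed.txt"))
  }
  invisible(manifest)
}

#' Read a cohort dataset from a directory
#'
#' Verifies per-block checksums against the manifest.
#'
#' @param dir Dataset directory written by [write_dataset()].
#' @return A `cohort` (without subject profiles).
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  assert_that(file.exists(man_path),
              paste("not a dataset directory (no manifest):", dir))
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  visits <- utils::read.csv(file.path(dir, "visits.csv"),
                            stringsAsFactors = FALSE)
  blocks <- list()
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[i])
    assert_that(file.exists(f), paste("missing block file:", f))
    ck <- unname(tools::md5sum(f))
    if (!identical(ck, manifest$checksum[i])) {
      stop("checksum mismatch for ", manifest$file[i],
           " (corrupt dataset)", call. = FALSE)
    }
    blocks[[manifest$key[i]]] <- readRDS(f)
  }
  structure(list(visits = visits, blocks = blocks,
                 spec = jsonlite::read_json(file.path(dir, "spec.json"),
                                            simplifyVector = TRUE)),
            class = "cohort")
}

#' Read a flat key-value configuration file
#'
#' One `key: value` pair per line; `#` starts a comment. Values are parsed
#' as numerics, logicals, or comma-separated vectors where possible. A
#' `seed` key is mandatory.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), paste("config file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    assert_that(length(m) == 3, paste("malformed config line:", ln))
    cfg[[m[2]]] <- parse_config_value(m[3])
  }
  assert_that(!is.null(cfg$seed), "config must set `seed`")
  cfg
}

parse_config_value <- function(s) {
  s <- trimws(s)
  if (grepl(",", s)) {
    return(vapply(strsplit(s, ",")[[1]],
                  function(v) parse_config_value(v), numeric(1)))
  }
  if (toupper(s) %in% c("TRUE", "FALSE")) return(as.logical(s))
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  s
}

#' Write a configuration list as flat key-value text
#'
#' @param cfg Named list of scalars or numeric vectors.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  fmt <- vapply(cfg, function(v) paste(v, collapse = ","), character(1))
  writeLines(paste0(names(cfg), ": ", fmt), path)
  invisible(path)
}
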