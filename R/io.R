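#' Write a cycle record to a trace file with JSON sidecar
#'
#' The trace file is a delimited text table with one row per frame:
#' column `time_ms`, strain columns `strain_seg01..strain_seg16` (%),
#' `volume_global` and `volume_seg01..volume_seg16` (mL). Values are
#' written with 17 significant digits so a write-read round trip preserves
#' doubles exactly. The sidecar `<path>.json` stores `rr_interval_ms`,
#' `es_index` (0-based frame index), `subject_id`, `visit` and, when
#' present on the record, the simulator `group` label.
#'
#' @param record a `cycle_record`.
#' @param path output file; the delimiter is chosen from the extension
#'   (`.tsv` tab, otherwise comma).
#' @return `path`, invisibly.
#' @export
write_cycle_record <- function(record, path) {
  validate_cycle_record(record)
  d <- data.frame(time_ms = record$times)
  for (i in 1:16) d[[sprintf("strain_seg%02d", i)]] <- record$strain[, i]
  d$volume_global <- record$global_volume
  for (i in 1:16) d[[sprintf("volume_seg%02d", i)]] <- record$seg_volume[, i]
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  fmt <- vapply(d, function(col) sprintf("%.17g", col), character(nrow(d)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(d), collapse = sep), con)
  writeLines(apply(fmt, 1, paste, collapse = sep), con)
  sidecar <- list(rr_interval_ms = record$rr_interval,
                  es_index = record$es_index - 1L,
                  subject_id = record$subject_id,
                  visit = record$visit)
  if (!is.null(attr(record, "group"))) sidecar$group <- attr(record, "group")
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cycle record from a trace file
#'
#' Reads the trace format written by [write_cycle_record()] (or exported
#' from a vendor workstation into the same layout). The delimiter is
#' auto-detected (comma or tab), header names are matched
#' case-insensitively, and all 16 strain and volume segments must be
#' present. The end-systolic frame is taken from the JSON sidecar when one
#' exists (`es_index`, 0-based); otherwise it falls back to the frame of
#' minimum global volume ([detect_es_index()]). Missing or non-numeric
#' cells and a non-monotone time column are errors naming the offending
#' rows/columns.
#'
#' @param path trace file path; `<path>.json` is the optional sidecar.
#' @param es_mode `"sidecar"` (sidecar when present, else min-volume) or
#'   `"min_volume"` (always min-volume).
#' @return A `cycle_record`.
#' @export
read_cycle_record <- function(path, es_mode = c("sidecar", "min_volume")) {
  es_mode <- match.arg(es_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
  d <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  want <- c("time_ms", sprintf("strain_seg%02d", 1:16), "volume_global",
            sprintf("volume_seg%02d", 1:16))
  missing <- setdiff(want, names(d))
  if (length(missing) > 0L) {
    stop("trace file is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in want) {
    v <- d[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop("non-numeric or missing values in `", col, "` at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    d[[col]] <- v
  }
  if (any(diff(d$time_ms) <= 0)) {
    stop("`time_ms` must be strictly increasing")
  }
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  rr <- sidecar$rr_interval_ms %||%
    (max(d$time_ms) + diff(utils::tail(d$time_ms, 2L)))
  es_index <- if (es_mode == "sidecar" && !is.null(sidecar$es_index)) {
    as.integer(sidecar$es_index) + 1L
  } else {
    detect_es_index(d$volume_global)
  }
  rec <- cycle_record(
    times = d$time_ms,
    strain = unname(as.matrix(d[sprintf("strain_seg%02d", 1:16)])),
    seg_volume = unname(as.matrix(d[sprintf("volume_seg%02d", 1:16)])),
    global_volume = d$volume_global,
    rr_interval = rr,
    es_index = es_index,
    subject_id = sidecar$subject_id %||% sub("\\.[^.]+$", "", basename(path)),
    visit = sidecar$visit %||% "baseline"
  )
  if (!is.null(sidecar$group)) attr(rec, "group") <- sidecar$group
  rec
}

#' Write a simulated cohort to a directory of trace files
#'
#' @param records list of `cycle_record`s from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"tsv"`.
#' @return Character vector of file paths, invisibly.
#' @export
write_cohort <- function(records, dir, format = c("csv", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(records, function(rec) {
    path <- file.path(dir, sprintf("%s_%s.%s", rec$subject_id, rec$visit,
                                   format))
    write_cycle_record(rec, path)
    path
  }, character(1))
  invisible(paths)
}

#' Run the per-subject analysis pipeline over a directory of trace files
#'
#' Reads every `.csv`/`.tsv` trace file in `input_dir`, computes the
#' per-subject loop metrics ([subject_metrics()]), attaches response labels
#' where baseline/follow-up pairs exist ([add_response()]), and writes
#' `metrics.csv` (all subject-visits) and `response.csv` (baseline rows
#' with response labels) into `output_dir`. Files that fail to parse are
#' skipped and reported; the run is deterministic given the inputs.
#'
#' @param input_dir directory of trace files (+ optional JSON sidecars).
#' @param output_dir report directory (created if needed); `NULL` writes
#'   nothing.
#' @param segments wall selection from [select_midwall_segments()].
#' @param es_mode forwarded to [read_cycle_record()].
#' @param r2_cutoff response-prediction constant (default 0.55).
#' @return A list of class `sv_pipeline`: `metrics`, `response`, `files`,
#'   `failures` (named character vector of error messages), `n_ok`,
#'   `n_failed`.
#' @export
run_pipeline <- function(input_dir, output_dir = NULL,
                         segments = select_midwall_segments(),
                         es_mode = "sidecar", r2_cutoff = 0.55) {
  files <- list.files(input_dir, pattern = "\\.(csv|tsv)$",
                      full.names = TRUE)
  if (length(files) == 0L) stop("no trace files found in ", input_dir)
  records <- list()
  failures <- character(0)
  for (f in files) {
    rec <- tryCatch(read_cycle_record(f, es_mode = es_mode),
                    error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      failures[basename(f)] <- rec
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  if (length(records) == 0L) {
    stop("no readable trace files in ", input_dir)
  }
  metrics <- cohort_metrics(records, segments = segments)
  response <- add_response(metrics, r2_cutoff = r2_cutoff)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(output_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(response, file.path(output_dir, "response.csv"),
                     row.names = FALSE)
  }
  structure(list(metrics = metrics, response = response, files = files,
                 failures = failures, n_ok = length(records),
                 n_failed = length(failures)),
            class = "sv_pipeline")
}

#' @export
print.sv_pipeline <- function(x, ...) {
  cat("<sv_pipeline> ", x$n_ok, " subject-visits analysed, ",
      x$n_failed, " file(s) failed\n", sep = "")
  if (x$n_failed > 0) {
    for (f in names(x$failures)) cat("  FAILED ", f, ": ", x$failures[[f]],
                                     "\n", sep = "")
  }
  invisible(x)
}
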