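PROFILE_FORMAT_VERSION <- "1"

#' Read a chest-strap RR interval export
#'
#' Two plain-text dialects: `"single-column-ms"` (one interval in
#' milliseconds per row, no header — the common chest-strap export) and
#' `"two-column"` (comma-separated `time,rr_ms` with a header row; time
#' either seconds or an ISO-8601 timestamp). Intervals must lie in
#' (0, 5000] ms; every data row must parse or an error names the
#' offending line.
#'
#' @param path file path.
#' @param dialect `"single-column-ms"` (default) or `"two-column"`.
#' @return an [rr_series()] with all flags `FALSE` and
#'   `corrected = FALSE`.
#' @export
read_rr_export <- function(path, dialect = c("single-column-ms", "two-column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (dialect == "single-column-ms") {
    if (length(lines) == 0L) stopf("no intervals in %s", path)
    vals <- suppressWarnings(as.numeric(lines))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      stopf("parse error in %s at line %d: '%s'", path, line_no[bad[1L]],
            lines[bad[1L]])
    }
    intervals <- vals
    times <- NULL
  } else {
    if (length(lines) < 2L) stopf("no intervals in %s", path)
    header <- tolower(trimws(strsplit(lines[1L], ",")[[1L]]))
    if (length(header) < 2L) stopf("two-column dialect needs a 'time,rr_ms' header")
    body <- lines[-1L]
    parts <- strsplit(body, ",")
    bad <- which(lengths(parts) < 2L)
    if (length(bad) > 0L) stopf("parse error in %s at line %d", path, line_no[bad[1L] + 1L])
    t_raw <- trimws(vapply(parts, `[`, character(1), 1L))
    rr_raw <- trimws(vapply(parts, `[`, character(1), 2L))
    intervals <- suppressWarnings(as.numeric(rr_raw))
    bad <- which(is.na(intervals))
    if (length(bad) > 0L) {
      stopf("parse error in %s at line %d: '%s'", path, line_no[bad[1L] + 1L],
            rr_raw[bad[1L]])
    }
    t_num <- suppressWarnings(as.numeric(t_raw))
    if (anyNA(t_num)) {
      ts <- as.POSIXct(t_raw, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
      if (anyNA(ts)) stopf("unparseable timestamp at line %d", line_no[which(is.na(ts))[1L] + 1L])
      t_num <- as.numeric(ts) - as.numeric(ts[1L])
    }
    times <- t_num - t_num[1L] + intervals[1L] / 1000
  }
  bad <- which(intervals <= 0 | intervals > 5000)
  if (length(bad) > 0L) {
    stopf("invalid interval %g ms at line %d (must be in (0, 5000])",
          intervals[bad[1L]],
          line_no[bad[1L] + if (dialect == "two-column") 1L else 0L])
  }
  rr_series(intervals, beat_times = times)
}

#' Write an RR series as a single-column millisecond export
#' @param path file path.
#' @param rr an [rr_series()].
#' @export
write_rr_export <- function(path, rr) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(fmt_num(rr$intervals), path)
  invisible(path)
}

#' Read a continuous heart-rate export
#'
#' CSV with header `time,hr`: elapsed seconds and bpm.
#'
#' @param path file path.
#' @return an [hr_series()].
#' @export
read_hr_export <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("time", "hr") %in% names(df))) stopf("expected header 'time,hr'")
  hr_series(df$time, df$hr)
}

#' Write a heart-rate series as CSV
#' @param path file path.
#' @param hr an [hr_series()].
#' @export
write_hr_export <- function(path, hr) {
  stopifnot(inherits(hr, "hr_series"))
  df <- data.frame(time = fmt_num(hr$times), hr = fmt_num(hr$hr))
  df$hr[is.na(hr$hr)] <- "NA"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a step incremental test file
#'
#' Comment lines `# key: value` before the header carry the metadata
#' (`hr_rest`, `hr_max`); the CSV body has header
#' `stage,speed,hr,bla,rpe`. The lactate baseline is set to the lowest
#' BLa across stages.
#'
#' @param path file path.
#' @return a [step_test()].
#' @export
read_step_test <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":")[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- as.numeric(trimws(kv[2L]))
  }
  if (is.null(meta$hr_rest) || is.null(meta$hr_max)) {
    stopf("missing hr_rest/hr_max metadata in %s", path)
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  need <- c("stage", "speed", "hr", "bla", "rpe")
  if (!all(need %in% names(df))) {
    stopf("expected header columns: %s", paste(need, collapse = ","))
  }
  names(df)[names(df) == "hr"] <- "hr_last30"
  step_test(df, hr_rest = meta$hr_rest, hr_max = meta$hr_max)
}

#' Write a step test file
#' @param path file path.
#' @param test a [step_test()].
#' @export
write_step_test <- function(path, test) {
  stopifnot(inherits(test, "step_test"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# hr_rest: %s", fmt_num(attr(test, "hr_rest"))),
               sprintf("# hr_max: %s", fmt_num(attr(test, "hr_max"))),
               "stage,speed,hr,bla,rpe"), con)
  writeLines(sprintf("%d,%s,%s,%s,%s", test$stage, fmt_num(test$speed),
                     fmt_num(test$hr_last30), fmt_num(test$bla),
                     fmt_num(test$rpe)), con)
  invisible(path)
}

#' Write a DFA grid as CSV
#'
#' Header comments carry the window parameters; one data line per grid
#' row.
#'
#' @param path file path.
#' @param grid a [dfa_grid()].
#' @export
write_grid <- function(path, grid) {
  stopifnot(inherits(grid, "dfa_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# window_s: %s", fmt_num(attr(grid, "window_s"))),
               sprintf("# step_s: %s", fmt_num(attr(grid, "step_s"))),
               "time,hr,alpha1,n_beats,valid"), con)
  num <- function(x) ifelse(is.na(x), "NA", fmt_num(x))
  writeLines(sprintf("%s,%s,%s,%d,%d", num(grid$time), num(grid$hr),
                     num(grid$alpha1), grid$n_beats, as.integer(grid$valid)),
             con)
  invisible(path)
}

#' Read a DFA grid written by [write_grid()]
#' @param path file path.
#' @return a [dfa_grid()].
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  for (ml in grep("^#", lines, value = TRUE)) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":")[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- as.numeric(trimws(kv[2L]))
  }
  df <- utils::read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"))
  dfa_grid(time = df$time, hr = df$hr, alpha1 = df$alpha1,
           n_beats = as.integer(df$n_beats), valid = df$valid > 0,
           window_s = meta$window_s %||% 120, step_s = meta$step_s %||% 5)
}

.profile_keys <- c("format_version", "id", "hr_rest", "hr_max",
                   "a_i", "b_i", "itrimp_rss", "itrimp_n",
                   "p", "q_i", "atrimp_rss", "atrimp_n",
                   "dfa_rest", "dfa_maximal")

#' Write an athlete profile as a flat key:value document
#'
#' The coefficient file that drives all future session scoring; carries
#' a format-version field so stale files are rejected rather than
#' silently reinterpreted.
#'
#' @param path file path.
#' @param profile an [athlete_profile()].
#' @export
write_profile <- function(path, profile) {
  stopifnot(inherits(profile, "athlete_profile"))
  out <- c(sprintf("format_version: %s", PROFILE_FORMAT_VERSION),
           sprintf("id: %s", profile$id),
           sprintf("hr_rest: %s", fmt_num(profile$hr_rest)),
           sprintf("hr_max: %s", fmt_num(profile$hr_max)))
  if (!is.null(profile$itrimp)) {
    out <- c(out,
             sprintf("a_i: %s", fmt_num(profile$itrimp$a)),
             sprintf("b_i: %s", fmt_num(profile$itrimp$b)))
    if (!is.null(profile$itrimp$rss)) {
      out <- c(out, sprintf("itrimp_rss: %s", fmt_num(profile$itrimp$rss)),
               sprintf("itrimp_n: %d", as.integer(profile$itrimp$n)))
    }
  }
  if (!is.null(profile$atrimp)) {
    out <- c(out,
             sprintf("p: %s", fmt_num(profile$atrimp$p)),
             sprintf("q_i: %s", fmt_num(profile$atrimp$q)))
    if (!is.null(profile$atrimp$rss)) {
      out <- c(out, sprintf("atrimp_rss: %s", fmt_num(profile$atrimp$rss)),
               sprintf("atrimp_n: %d", as.integer(profile$atrimp$n)))
    }
  }
  if (is.finite(profile$dfa_rest)) {
    out <- c(out, sprintf("dfa_rest: %s", fmt_num(profile$dfa_rest)),
             sprintf("dfa_maximal: %s", fmt_num(profile$dfa_maximal)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an athlete profile file
#'
#' Unknown keys and unknown format versions are rejected; an incomplete
#' coefficient pair (e.g. `p` without `q_i`) is an error listing the
#' missing key.
#'
#' @param path file path.
#' @return an [athlete_profile()].
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) stopf("malformed profile line %d: '%s'", bad[1L], lines[bad[1L]])
  keys <- trimws(vapply(kv, `[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  unknown <- setdiff(keys, .profile_keys)
  if (length(unknown) > 0L) {
    stopf("unknown profile key(s): %s", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(keys)) stopf("duplicate profile key: %s", keys[duplicated(keys)][1L])
  get_k <- function(k) if (k %in% keys) vals[keys == k] else NULL
  ver <- get_k("format_version")
  if (is.null(ver)) stopf("missing key: format_version")
  if (ver != PROFILE_FORMAT_VERSION) stopf("unknown profile format version '%s'", ver)
  for (k in c("id", "hr_rest", "hr_max")) {
    if (is.null(get_k(k))) stopf("missing key: %s", k)
  }
  num_k <- function(k) {
    v <- get_k(k)
    if (is.null(v)) NULL else as.numeric(v)
  }
  itrimp <- NULL
  if (any(c("a_i", "b_i") %in% keys)) {
    for (k in c("a_i", "b_i")) if (!(k %in% keys)) stopf("missing key: %s", k)
    itrimp <- list(a = num_k("a_i"), b = num_k("b_i"),
                   rss = num_k("itrimp_rss"), n = num_k("itrimp_n"))
  }
  atrimp <- NULL
  if (any(c("p", "q_i") %in% keys)) {
    for (k in c("p", "q_i")) if (!(k %in% keys)) stopf("missing key: %s", k)
    atrimp <- list(p = num_k("p"), q = num_k("q_i"),
                   rss = num_k("atrimp_rss"), n = num_k("atrimp_n"))
  }
  athlete_profile(id = get_k("id"), hr_rest = num_k("hr_rest"),
                  hr_max = num_k("hr_max"), itrimp = itrimp, atrimp = atrimp,
                  dfa_rest = num_k("dfa_rest") %||% NA_real_,
                  dfa_maximal = num_k("dfa_maximal") %||% NA_real_)
}

#' Write a one-row session TRIMP report
#'
#' @param path file path.
#' @param result a [trimp_result()].
#' @param session_id identifier written into the row.
#' @export
write_trimp_report <- function(path, result, session_id = "session") {
  stopifnot(inherits(result, "trimp_result"))
  df <- data.frame(session_id = session_id, method = result$method,
                   convention = result$convention,
                   duration_min = result$duration_min,
                   mean_delta_hr = result$mean_delta_hr,
                   trimp = result$total)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
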