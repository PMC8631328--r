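# Oddball reaction-time extraction and session-table validation.

#' Extract reaction times from an oddball event log
#'
#' For each deviant stimulus, the first unassigned button press inside the
#' valid-response window `(onset + lower, onset + upper]` is taken as its
#' response; the reaction time is press minus onset. Deviants with no such
#' press are misses; presses matching no deviant (including anticipations
#' faster than the window floor) are false alarms. Each press is assigned
#' to at most one deviant, so `hits + misses = deviant count` always.
#'
#' The 0.1 s floor excludes anticipations; the 1.0 s ceiling equals the
#' inter-stimulus interval, so a response can never be reassigned across
#' stimuli.
#'
#' @param log an `oddball_log` or a data.frame with columns `time_s` and
#'   `kind` (values `standard`, `deviant`, `press`).
#' @param valid_window_s numeric pair: valid-response window in seconds.
#' @return list with `mean_rt_s` (NA when there are no hits), `n_hits`,
#'   `n_misses`, `n_false_alarms`, `n_deviants` and `rts` (per-hit
#'   reaction times).
#' @export
extract_reaction_times <- function(log, valid_window_s = c(0.1, 1.0)) {
  if (!is.data.frame(log) || !all(c("time_s", "kind") %in% names(log)))
    abort_renyieeg("log must be a data.frame with time_s and kind columns")
  if (nrow(log) == 0L) abort_renyieeg("log is empty")
  lo <- valid_window_s[1]; hi <- valid_window_s[2]
  onsets <- log$time_s[log$kind == "deviant"]
  presses <- sort(log$time_s[log$kind == "press"])
  used <- logical(length(presses))
  rts <- rep(NA_real_, length(onsets))
  for (i in seq_along(onsets)) {
    ok <- which(!used & presses > onsets[i] + lo & presses <= onsets[i] + hi)
    if (length(ok)) {
      used[ok[1L]] <- TRUE
      rts[i] <- presses[ok[1L]] - onsets[i]
    }
  }
  hits <- sum(!is.na(rts))
  list(mean_rt_s = if (hits) mean(rts, na.rm = TRUE) else NA_real_,
       n_hits = hits,
       n_misses = length(onsets) - hits,
       n_false_alarms = sum(!used),
       n_deviants = length(onsets),
       rts = rts[!is.na(rts)])
}

#' Validate a session assessment table
#'
#' Checks the schema and value constraints of a session table: SSS scores
#' must be integers in 1..7, sleep durations non-negative, reaction times
#' positive or missing, and `(subject, session)` pairs unique. All
#' violations are reported with their row indices; offending rows are
#' excluded from the validated table.
#'
#' @param table data.frame with at least `subject`, `session`, `sss`,
#'   `sleep_min` columns (`rt_audio_s`, `rt_visual_s` optional).
#' @return list with `table` (rows passing all checks) and `issues`
#'   (data.frame: row, column, problem).
#' @export
validate_session_table <- function(table) {
  required <- c("subject", "session", "sss", "sleep_min")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols))
    abort_renyieeg(sprintf("missing required column(s): %s",
                           paste(missing_cols, collapse = ", ")),
                   class = "renyieeg_schema_error")
  issues <- list()
  flag <- function(rows, column, problem) {
    if (length(rows))
      issues[[length(issues) + 1L]] <<-
        data.frame(row = rows, column = column, problem = problem)
  }
  flag(which(!is.na(table$sss) &
               (table$sss < 1 | table$sss > 7 |
                  table$sss != round(table$sss))),
       "sss", "SSS score outside integer range 1..7")
  flag(which(!is.na(table$sleep_min) & table$sleep_min < 0),
       "sleep_min", "negative sleep duration")
  for (rtcol in intersect(c("rt_audio_s", "rt_visual_s"), names(table)))
    flag(which(!is.na(table[[rtcol]]) & table[[rtcol]] <= 0),
         rtcol, "non-positive reaction time")
  key <- paste(table$subject, table$session, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  for (k in dup_keys)
    flag(which(key == k), "subject/session", "duplicated (subject, session)")
  issues <- if (length(issues)) do.call(rbind, issues)
            else data.frame(row = integer(), column = character(),
                            problem = character())
  bad <- unique(issues$row)
  list(table = if (length(bad)) table[-bad, , drop = FALSE] else table,
       issues = issues)
}
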