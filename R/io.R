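# Readers and writers for session and schedule tables. Tab-separated, header
# row, UTF-8; missing latency written as an empty field.

SESSION_COLS <- c("subject_id", "group", "phase", "schedule_kind",
                  "session_id", "trial", "config_id", "choice", "reward",
                  "latency_ms")

#' Write sessions to a TSV file
#'
#' One row per trial, columns `subject_id`, `group`, `phase`,
#' `schedule_kind`, `session_id`, `trial`, `config_id`, `choice`, `reward`,
#' `latency_ms`. Missing latencies become empty fields.
#'
#' @param sessions A `bandit_session` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  sessions <- as_session_list(sessions)
  rows <- do.call(rbind, lapply(sessions, function(s) {
    cbind(session_meta(s)[rep(1L, nrow(s$trials)), , drop = FALSE],
          s$trials[, c("trial", "config_id", "choice", "reward",
                       "latency_ms")])
  }))
  rownames(rows) <- NULL
  utils::write.table(rows[, SESSION_COLS], path, sep = "\t", na = "",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Default schedule provider
#'
#' Reconstructs the schedule for a session read from file, matching the
#' schedules [simulate_cohort()] uses: fixed kinds are regenerated from
#' `base_probs`, varying kinds from the per-(kind, phase, session) seed
#' derived from `seed`.
#'
#' @param seed Master seed the cohort was simulated with.
#' @param base_probs Fixed-schedule base probabilities.
#' @return A function `(kind, phase, session_id) -> reward_schedule`.
#' @export
default_schedule_provider <- function(seed = 1L,
                                      base_probs = c(0.8, 0.5, 0.2)) {
  function(kind, phase, session_id) {
    if (kind %in% FIXED_KINDS) {
      generate_fixed_schedule(as.integer(substring(kind, 6L)), base_probs)
    } else {
      generate_varying_schedule(
        kind, seed = session_seed(seed, "schedule", phase, kind, session_id))
    }
  }
}

stop_at <- function(path, line, msg) {
  stop(sprintf("%s:%s: %s", path, line, msg), call. = FALSE)
}

#' Read sessions from TSV files
#'
#' Validates the schema row by row (option codes 0-2, rewards 0/1, positive
#' latencies, contiguous 1-based trial indices per session) and reports the
#' offending file and line on failure. The schedule backing each session is
#' obtained from `schedules`.
#'
#' @param paths Character vector of TSV file paths.
#' @param schedules Either a function `(kind, phase, session_id) ->
#'   reward_schedule` (see [default_schedule_provider()]), a single
#'   `reward_schedule` used for every session, or `NULL` for the default
#'   provider with seed 1.
#' @return A list of `bandit_session` objects.
#' @export
read_sessions <- function(paths, schedules = NULL) {
  if (is.null(schedules)) schedules <- default_schedule_provider()
  if (inherits(schedules, "reward_schedule")) {
    sched_obj <- schedules
    schedules <- function(kind, phase, session_id) sched_obj
  }
  stopifnot(is.function(schedules))
  out <- list()
  for (path in paths) {
    if (!file.exists(path)) stop("file not found: ", path)
    d <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
    miss <- setdiff(SESSION_COLS, names(d))
    if (length(miss)) {
      stop_at(path, 1L, paste("missing columns:", paste(miss, collapse = ", ")))
    }
    lines <- seq_len(nrow(d)) + 1L  # header is line 1
    bad <- which(!(d$choice %in% 0:2))
    if (length(bad)) {
      stop_at(path, lines[bad[1]],
              sprintf("choice out of range: %s", d$choice[bad[1]]))
    }
    bad <- which(!(d$reward %in% 0:1))
    if (length(bad)) {
      stop_at(path, lines[bad[1]],
              sprintf("reward out of range: %s", d$reward[bad[1]]))
    }
    bad <- which(!is.na(d$latency_ms) & d$latency_ms <= 0)
    if (length(bad)) {
      stop_at(path, lines[bad[1]], "latency_ms must be positive")
    }
    key <- interaction(d$subject_id, d$group, d$phase, d$schedule_kind,
                       d$session_id, drop = TRUE)
    for (k in levels(key)) {
      rows <- d[key == k, , drop = FALSE]
      if (!identical(as.integer(rows$trial), seq_len(nrow(rows)))) {
        stop_at(path, lines[which(key == k)[1]],
                "trial indices not contiguous from 1 within session")
      }
      sched <- schedules(rows$schedule_kind[1], rows$phase[1],
                         rows$session_id[1])
      out[[length(out) + 1L]] <- bandit_session(
        rows$subject_id[1], rows$group[1], rows$phase[1], sched,
        data.frame(trial = as.integer(rows$trial),
                   config_id = as.integer(rows$config_id),
                   choice = as.integer(rows$choice),
                   reward = as.integer(rows$reward),
                   latency_ms = rows$latency_ms),
        session_id = rows$session_id[1])
    }
  }
  out
}

#' Write a reward schedule to TSV
#'
#' Columns `trial`, `p_opt0`, `p_opt1`, `p_opt2`, preceded by `#`-prefixed
#' metadata lines (`kind`, `seed`, `reversal_trial`).
#'
#' @param schedule A `reward_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "reward_schedule"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", schedule$kind),
               sprintf("# seed: %s", schedule$seed),
               sprintf("# reversal_trial: %s", schedule$reversal_trial)),
             con)
  d <- data.frame(trial = seq_len(n_trials(schedule)), schedule$probs)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reward schedule from TSV
#'
#' @param path File written by [write_schedule()] (or any TSV with the same
#'   columns; metadata lines are optional, defaulting to kind `"stable"`).
#' @return A `reward_schedule`.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 10L)
  meta <- list(kind = "stable", seed = NA, reversal_trial = NA)
  for (ln in grep("^#", hdr, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*(\\S+):\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
  }
  d <- utils::read.delim(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("trial", "p_opt0", "p_opt1", "p_opt2")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_at(path, 1L, paste("missing columns:", paste(miss, collapse = ", ")))
  }
  rt <- suppressWarnings(as.integer(meta$reversal_trial))
  reward_schedule(meta$kind,
                  as.matrix(d[, c("p_opt0", "p_opt1", "p_opt2")]),
                  reversal_trial = if (is.na(rt)) NA_integer_ else rt,
                  seed = suppressWarnings(as.integer(meta$seed)))
}
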