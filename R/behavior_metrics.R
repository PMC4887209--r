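# Descriptive behavioural analyses: performance and learning criterion,
# switch/stay conditioned on the previous outcome and reversal phase,
# choice-history (A_kB) and choice-frequency tables, latency summaries, and
# the fixed-schedule EARLY LOW / EARLY HIGH classification.

as_session_list <- function(sessions) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  if (!length(sessions)) stop("`sessions` must be non-empty")
  stopifnot(all(vapply(sessions, inherits, logical(1), "bandit_session")))
  sessions
}

session_meta <- function(s) {
  data.frame(subject_id = s$subject_id, group = s$group, phase = s$phase,
             schedule_kind = s$schedule$kind, session_id = s$session_id,
             stringsAsFactors = FALSE)
}

# Resolve per-session label vectors: a list parallel to sessions, a single
# vector recycled to every session, or NULL meaning schedule-derived labels.
resolve_labels <- function(sessions, labels) {
  if (is.null(labels)) {
    return(lapply(sessions, function(s) v1_sch_labels(s$schedule)))
  }
  if (!is.list(labels)) labels <- rep(list(labels), length(sessions))
  if (length(labels) != length(sessions)) {
    stop("`labels` must match `sessions` in length")
  }
  for (k in seq_along(sessions)) {
    if (length(labels[[k]]) != nrow(sessions[[k]]$trials)) {
      stop("label vector length must equal the session's trial count")
    }
  }
  labels
}

#' Switch/stay probabilities conditioned on the previous outcome
#'
#' A switch at trial n means the choice differs from the choice at trial
#' n-1 (within a session). Events are conditioned on whether the previous
#' trial's choice was rewarded, and optionally split at the schedule's
#' reversal trial into pre- and post-reversal segments (a trial belongs to
#' the post segment when its own index exceeds the reversal trial).
#'
#' @param sessions A `bandit_session` or list of them (pooled).
#' @param split_reversal Split into pre-/post-reversal segments where the
#'   schedule defines a reversal.
#' @return Data frame with `segment`, `prev_outcome`, `n`, `n_switch`,
#'   `p_switch`.
#' @export
switch_stay_table <- function(sessions, split_reversal = FALSE) {
  sessions <- as_session_list(sessions)
  rows <- lapply(sessions, function(s) {
    ch <- s$trials$choice; rw <- s$trials$reward
    tn <- length(ch)
    if (tn < 2L) return(NULL)
    n <- 2:tn
    seg <- if (split_reversal && !is.na(s$schedule$reversal_trial)) {
      ifelse(n <= s$schedule$reversal_trial, "pre", "post")
    } else "all"
    data.frame(
      segment = seg,
      prev_outcome = ifelse(rw[n - 1L] == 1L, "reward", "no_reward"),
      switch = as.integer(ch[n] != ch[n - 1L])
    )
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) stop("no session has at least 2 trials")
  agg <- stats::aggregate(switch ~ segment + prev_outcome, data = ev,
                          FUN = function(x) c(n = length(x), s = sum(x)))
  out <- data.frame(segment = agg$segment, prev_outcome = agg$prev_outcome,
                    n = agg$switch[, "n"], n_switch = agg$switch[, "s"])
  out$p_switch <- out$n_switch / out$n
  out[order(out$segment, out$prev_outcome), , drop = FALSE]
}

akb_bin_label <- function(k) if (k >= 4L) "4-7" else as.character(k)

#' Choice-history (A_kB) conditional next-choice table
#'
#' An A_kB event at trial n is a history in which one stimulus A was chosen
#' on trials n-2 down to n-(k+1) (a homogeneous run of length k), then a
#' different stimulus B was chosen on trial n-1. The table gives the
#' probability that the next choice (trial n) is B again, returns to A, or
#' moves to the third stimulus C, conditional on the run-length bin (1, 2,
#' 3 or "4-7") and on whether the B choice was rewarded.
#'
#' Runs are assessed within a 7-trial lookback window (trials n-2 to n-8,
#' truncated at the session start). By default the run must be maximal (the
#' trial before it was not A) and clean: a history whose run stimulus
#' reappears earlier within the lookback window (e.g. C, A, C then B) mixes
#' identities and is not an A_kB condition, so it is excluded. Runs of 4 or
#' more are pooled into the "4-7" bin; runs extending beyond the window are
#' capped into that bin by default or discarded with
#' `pool_long_runs = FALSE`.
#'
#' @param sessions A `bandit_session` or list of them (pooled).
#' @param maximal Require the A run to be maximal and clean (default
#'   `TRUE`). With `FALSE` neither requirement applies and an event whose
#'   run has length r contributes to every bin k <= r (bins then count
#'   "at least k" histories).
#' @param pool_long_runs Pool runs longer than 7 into "4-7" (default)
#'   rather than discarding them.
#' @return A `history_condition_table` data frame with `condition`,
#'   `prior_outcome`, `n_events`, `p_next_B`, `p_next_A`, `p_next_C`.
#' @export
akb_table <- function(sessions, maximal = TRUE, pool_long_runs = TRUE) {
  sessions <- as_session_list(sessions)
  recs <- list()
  for (s in sessions) {
    ch <- s$trials$choice; rw <- s$trials$reward
    tn <- length(ch)
    if (tn < 3L) next
    for (n in 3:tn) {
      b <- ch[n - 1L]
      a <- ch[n - 2L]
      if (a == b) next
      w_lo <- max(1L, n - 8L)
      # maximal homogeneous run of A ending at n-2 (uncapped length)
      k_true <- 1L
      while (n - 2L - k_true >= 1L && ch[n - 2L - k_true] == a) {
        k_true <- k_true + 1L
      }
      if (k_true > 7L && !pool_long_runs) next
      k <- min(k_true, 7L)
      if (maximal) {
        pre_run <- seq_len(max(0L, (n - 2L - k) - w_lo + 1L)) + w_lo - 1L
        if (length(pre_run) && any(ch[pre_run] == a)) next
      }
      ks <- if (maximal) k else seq_len(k)
      for (kk in ks) {
        recs[[length(recs) + 1L]] <- data.frame(
          condition = akb_bin_label(kk),
          prior_outcome = ifelse(rw[n - 1L] == 1L, "reward", "no_reward"),
          nxt = c("B", "A", "C")[1L + (ch[n] == a) + 2L *
                                   (ch[n] != a & ch[n] != b)]
        )
      }
    }
  }
  if (!length(recs)) stop("no A_kB events found")
  ev <- do.call(rbind, recs)
  keys <- unique(ev[, c("condition", "prior_outcome")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
    sub <- ev[ev$condition == keys$condition[r] &
                ev$prior_outcome == keys$prior_outcome[r], ]
    data.frame(condition = keys$condition[r],
               prior_outcome = keys$prior_outcome[r],
               n_events = nrow(sub),
               p_next_B = mean(sub$nxt == "B"),
               p_next_A = mean(sub$nxt == "A"),
               p_next_C = mean(sub$nxt == "C"))
  }))
  out <- out[order(out$condition, out$prior_outcome), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("history_condition_table", class(out))
  out
}

#' Choice-frequency conditional repetition table
#'
#' For each trial n whose previous choice was some stimulus B, counts how
#' often B had been selected over the 5 earlier trials (n-2 to n-6, count
#' 0-5) and tabulates the probability of repeating B on trial n, split by
#' whether the B choice at n-1 was rewarded.
#'
#' @param sessions A `bandit_session` or list of them (pooled).
#' @return A `history_condition_table` data frame with `condition` (the
#'   count), `prior_outcome`, `n_events`, `p_repeat`.
#' @export
choice_frequency_table <- function(sessions) {
  sessions <- as_session_list(sessions)
  rows <- lapply(sessions, function(s) {
    ch <- s$trials$choice; rw <- s$trials$reward
    tn <- length(ch)
    if (tn < 7L) return(NULL)
    n <- 7:tn
    b <- ch[n - 1L]
    cnt <- vapply(seq_along(n), function(k) {
      sum(ch[(n[k] - 6L):(n[k] - 2L)] == b[k])
    }, integer(1))
    data.frame(
      condition = cnt,
      prior_outcome = ifelse(rw[n - 1L] == 1L, "reward", "no_reward"),
      rep = as.integer(ch[n] == b)
    )
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) stop("no session has at least 7 trials")
  agg <- stats::aggregate(rep ~ condition + prior_outcome, data = ev,
                          FUN = function(x) c(n = length(x), s = sum(x)))
  out <- data.frame(condition = agg$condition,
                    prior_outcome = agg$prior_outcome,
                    n_events = agg$rep[, "n"])
  out$p_repeat <- agg$rep[, "s"] / out$n_events
  out <- out[order(out$condition, out$prior_outcome), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("history_condition_table", class(out))
  out
}

#' Trials to reach the learning criterion
#'
#' The criterion is met at the first trial t such that the proportion of
#' best-option choices over the trailing window of `window` trials (fully
#' inside the segment) is at least `threshold`. For the post-reversal
#' segment, trials are counted from the first post-reversal trial, so the
#' smallest attainable value is again `window`. Sessions that never meet the
#' criterion (including segments shorter than the window) are reported as
#' not reached with an `NA` trial.
#'
#' @param sessions A `bandit_session` or list of them.
#' @param labels Per-trial best-option labels: a list parallel to
#'   `sessions`, one vector recycled, or `NULL` to use schedule-derived
#'   [v1_sch_labels()].
#' @param threshold Criterion proportion (default 0.65, inclusive).
#' @param window Window width in trials (default 20).
#' @param segment `"acquisition"` (session start to reversal, or whole
#'   session when there is none) or `"post_reversal"`.
#' @return A list of class `criterion_result`: `per_session` (one row per
#'   session with `criterion_trial` and `reached`) and `per_subject`
#'   (median across sessions; `NA` if any contributing session is `NA`-free
#'   medians are over reached sessions' values with unreached counted as
#'   `Inf`).
#' @export
trials_to_criterion <- function(sessions, labels = NULL, threshold = 0.65,
                                window = 20L,
                                segment = c("acquisition", "post_reversal")) {
  segment <- match.arg(segment)
  sessions <- as_session_list(sessions)
  labels <- resolve_labels(sessions, labels)
  per <- do.call(rbind, lapply(seq_along(sessions), function(k) {
    s <- sessions[[k]]
    ch <- s$trials$choice
    tn <- length(ch)
    rev <- s$schedule$reversal_trial
    if (segment == "acquisition") {
      s0 <- 1L; s1 <- if (is.na(rev)) tn else rev
    } else {
      if (is.na(rev)) {
        return(cbind(session_meta(s),
                     data.frame(criterion_trial = NA_integer_,
                                reached = FALSE)))
      }
      s0 <- rev + 1L; s1 <- tn
    }
    hit <- as.integer(ch == labels[[k]])
    crit <- NA_integer_
    if (s1 - s0 + 1L >= window) {
      cs <- cumsum(hit[s0:s1])
      for (t in window:(s1 - s0 + 1L)) {
        prop <- (cs[t] - if (t > window) cs[t - window] else 0) / window
        if (prop >= threshold) { crit <- t; break }
      }
    }
    cbind(session_meta(s),
          data.frame(criterion_trial = crit, reached = !is.na(crit)))
  }))
  rownames(per) <- NULL
  vals <- ifelse(per$reached, per$criterion_trial, Inf)
  med <- stats::aggregate(vals, by = per[, c("subject_id", "group", "phase")],
                          FUN = stats::median)
  names(med)[names(med) == "x"] <- "median_trials"
  structure(list(per_session = per, per_subject = med),
            class = "criterion_result")
}

#' Best-option choice proportions per session
#'
#' Proportion of trials on which the labelled best option was chosen, over
#' the whole session and (optionally) per half, split at the reversal trial
#' when the schedule has one and at the midpoint otherwise. Optionally also
#' reports perseveration after the reversal: the proportion of choices of
#' the pre-reversal best option (its modal label over the first half) during
#' the `reversal_window` trials immediately after the reversal.
#'
#' @param sessions A `bandit_session` or list of them.
#' @param labels As in [trials_to_criterion()].
#' @param halves Include per-half proportions (default `TRUE`).
#' @param reversal_window If positive, report the ex-best-option proportion
#'   over this many post-reversal trials (`NA` for fixed schedules);
#'   default 0 (omitted).
#' @return Data frame, one row per session.
#' @export
v1_choice_summary <- function(sessions, labels = NULL, halves = TRUE,
                              reversal_window = 0L) {
  sessions <- as_session_list(sessions)
  labels <- resolve_labels(sessions, labels)
  out <- do.call(rbind, lapply(seq_along(sessions), function(k) {
    s <- sessions[[k]]
    ch <- s$trials$choice
    lab <- labels[[k]]
    tn <- length(ch)
    split <- if (!is.na(s$schedule$reversal_trial)) {
      s$schedule$reversal_trial
    } else tn %/% 2L
    row <- cbind(session_meta(s),
                 data.frame(p_v1 = mean(ch == lab)))
    if (halves) {
      row$p_v1_first_half <- mean(ch[1:split] == lab[1:split])
      row$p_v1_second_half <-
        mean(ch[(split + 1):tn] == lab[(split + 1):tn])
    }
    if (reversal_window > 0L) {
      rev <- s$schedule$reversal_trial
      row$p_exv1_post <- if (is.na(rev)) NA_real_ else {
        exv1 <- as.integer(names(which.max(table(lab[1:rev]))))
        idx <- (rev + 1L):min(tn, rev + reversal_window)
        mean(ch[idx] == exv1)
      }
    }
    row
  }))
  rownames(out) <- NULL
  out
}

#' Latency summaries: stay/switch log-latency and a binned histogram
#'
#' Latencies are natural-log transformed. Trials are classed as stay or
#' switch exactly as in [switch_stay_table()] (the first trial of a session,
#' having no predecessor, is excluded). Missing latencies are dropped and
#' counted in `n_dropped`.
#'
#' @param sessions A `bandit_session` or list of them.
#' @param bin_ms Histogram bin width in ms (default 100; edges 0, 100, ...).
#' @return A list with `by_subject` (mean log-latency on stay and switch
#'   trials per subject x phase), `histogram` (counts and proportions per
#'   bin) and `n_dropped`.
#' @export
latency_summary <- function(sessions, bin_ms = 100) {
  sessions <- as_session_list(sessions)
  rows <- lapply(sessions, function(s) {
    ch <- s$trials$choice; lat <- s$trials$latency_ms
    tn <- length(ch)
    if (tn < 2L) return(NULL)
    n <- 2:tn
    cbind(session_meta(s)[rep(1L, length(n)), , drop = FALSE],
          data.frame(latency_ms = lat[n],
                     kind = ifelse(ch[n] != ch[n - 1L], "switch", "stay")))
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) stop("no session has at least 2 trials")
  n_dropped <- sum(is.na(ev$latency_ms))
  ev <- ev[!is.na(ev$latency_ms), , drop = FALSE]
  if (!nrow(ev)) stop("no usable latencies")
  ev$log_lat <- log(ev$latency_ms)
  agg <- stats::aggregate(log_lat ~ subject_id + group + phase + kind,
                          data = ev,
                          FUN = function(x) c(m = mean(x), n = length(x)))
  by_subject <- data.frame(agg[, c("subject_id", "group", "phase", "kind")],
                           mean_log_latency = agg$log_lat[, "m"],
                           n = agg$log_lat[, "n"])
  wide <- stats::reshape(by_subject, direction = "wide", idvar =
                           c("subject_id", "group", "phase"),
                         timevar = "kind")
  rownames(wide) <- NULL
  edges <- seq(0, (max(ev$latency_ms) %/% bin_ms + 1) * bin_ms, by = bin_ms)
  cnt <- as.integer(table(cut(ev$latency_ms, edges, right = FALSE)))
  histogram <- data.frame(bin_lo = edges[-length(edges)],
                          bin_hi = edges[-1], count = cnt,
                          proportion = cnt / sum(cnt))
  list(by_subject = wide, histogram = histogram, n_dropped = n_dropped)
}

#' Early/late performance classification for fixed schedules
#'
#' Classifies each session by its proportion of best-option choices over the
#' first `window` trials: at most `low` is "EARLY_LOW", at least `high` is
#' "EARLY_HIGH", anything between is "neither" (thresholds inclusive). The
#' endpoint is the proportion over the last `window` trials. Group medians
#' of the endpoint are reported per class, and where both groups contribute
#' sessions to a class their endpoint distributions are compared with a
#' two-sample Kolmogorov-Smirnov test, treating sessions as independent
#' samples.
#'
#' @param sessions A `bandit_session` or list of them (>= 2*`window` trials
#'   each).
#' @param labels As in [trials_to_criterion()].
#' @param low,high Class thresholds (defaults 0.25 and 0.75).
#' @param window Number of trials at each end (default 20).
#' @return A list with `per_session`, `group_summary` and `ks_tests`.
#' @export
fixed_early_late <- function(sessions, labels = NULL, low = 0.25,
                             high = 0.75, window = 20L) {
  sessions <- as_session_list(sessions)
  labels <- resolve_labels(sessions, labels)
  per <- do.call(rbind, lapply(seq_along(sessions), function(k) {
    s <- sessions[[k]]
    ch <- s$trials$choice; lab <- labels[[k]]
    tn <- length(ch)
    if (tn < 2L * window) stop("sessions must have at least 2*window trials")
    early <- mean(ch[1:window] == lab[1:window])
    late <- mean(ch[(tn - window + 1L):tn] == lab[(tn - window + 1L):tn])
    cls <- if (early <= low) "EARLY_LOW" else if (early >= high)
      "EARLY_HIGH" else "neither"
    cbind(session_meta(s),
          data.frame(p_v1_early = early, p_v1_late = late, class = cls))
  }))
  rownames(per) <- NULL
  grp <- stats::aggregate(p_v1_late ~ group + class, data = per,
                          FUN = function(x) c(median = stats::median(x),
                                              n = length(x)))
  group_summary <- data.frame(grp[, c("group", "class")],
                              median_late = grp$p_v1_late[, "median"],
                              n_sessions = grp$p_v1_late[, "n"])
  ks_tests <- list()
  for (cls in unique(per$class)) {
    a <- per$p_v1_late[per$class == cls & per$group == "control"]
    b <- per$p_v1_late[per$class == cls & per$group == "mdmc"]
    if (length(a) && length(b)) {
      ks_tests[[cls]] <- suppressWarnings(stats::ks.test(a, b))
    }
  }
  list(per_session = per, group_summary = group_summary, ks_tests = ks_tests)
}
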