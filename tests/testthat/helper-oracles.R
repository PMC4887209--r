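# Independent brute-force oracles used to cross-check the vectorised
# implementations, plus small fixture builders. Everything here is written
# as plain trial-by-trial scanning, deliberately naive.

# A session with arbitrary choice/reward/latency content on a flat dummy
# schedule (probabilities are irrelevant for analyses that only read the
# behaviour).
toy_session <- function(choices, rewards = NULL, latencies = NULL,
                        subject_id = "toy", group = "control",
                        phase = "pre", session_id = 1L, kind = "stable") {
  tn <- length(choices)
  if (is.null(rewards)) rewards <- rep(0L, tn)
  if (is.null(latencies)) latencies <- rep(400, tn)
  sched <- reward_schedule(kind, matrix(1 / 3, tn, 3))
  bandit_session(subject_id, group, phase, sched,
                 data.frame(trial = seq_len(tn),
                            config_id = rep(1L, tn),
                            choice = as.integer(choices),
                            reward = as.integer(rewards),
                            latency_ms = latencies),
                 session_id = session_id)
}

random_toy_session <- function(n, seed, ...) {
  set.seed(seed)
  toy_session(sample(0:2, n, replace = TRUE),
              rewards = stats::rbinom(n, 1, 0.5),
              latencies = stats::runif(n, 100, 900), ...)
}

# Brute-force design matrix: one explicit loop per row and per lag pair.
oracle_design_matrix <- function(session, target) {
  ch <- session$trials$choice
  rw <- session$trials$reward
  tn <- length(ch)
  rows <- list(); y <- integer(0)
  for (n in 7:tn) {
    x <- numeric(0)
    for (i in 1:6) for (j in 1:6) {
      v <- if (rw[n - j] == 0) 0 else if (ch[n - i] == target) 1 else -1
      x <- c(x, v)
    }
    rows[[length(rows) + 1L]] <- x
    y <- c(y, as.integer(ch[n] == target))
  }
  X <- do.call(rbind, rows)
  storage.mode(X) <- "integer"
  list(X = X, y = y)
}

# Brute-force switch/stay scanner.
oracle_switch_table <- function(session, split_reversal = FALSE) {
  ch <- session$trials$choice
  rw <- session$trials$reward
  rev <- session$schedule$reversal_trial
  recs <- data.frame()
  for (n in 2:length(ch)) {
    seg <- if (split_reversal && !is.na(rev)) {
      if (n <= rev) "pre" else "post"
    } else "all"
    recs <- rbind(recs, data.frame(
      segment = seg,
      prev_outcome = if (rw[n - 1] == 1) "reward" else "no_reward",
      switch = as.integer(ch[n] != ch[n - 1])))
  }
  recs
}

# Brute-force A_kB scanner (maximal, pooled mode).
oracle_akb_events <- function(session) {
  ch <- session$trials$choice
  rw <- session$trials$reward
  recs <- data.frame()
  for (n in 3:length(ch)) {
    b <- ch[n - 1]; a <- ch[n - 2]
    if (a == b) next
    k <- 0
    m <- n - 2
    while (m >= 1 && m >= n - 8 && ch[m] == a) { k <- k + 1; m <- m - 1 }
    # run extending beyond the window is capped (pooled mode)
    extended <- (m == n - 9) && m >= 1 && ch[m] == a
    if (!extended) {
      # maximality/cleanliness: no further a within the window before run
      clean <- TRUE
      while (m >= 1 && m >= n - 8) {
        if (ch[m] == a) clean <- FALSE
        m <- m - 1
      }
      if (!clean) next
    }
    nxt <- if (ch[n] == b) "B" else if (ch[n] == a) "A" else "C"
    recs <- rbind(recs, data.frame(
      condition = if (k >= 4) "4-7" else as.character(k),
      prior_outcome = if (rw[n - 1] == 1) "reward" else "no_reward",
      nxt = nxt))
  }
  recs
}

# Brute-force choice-frequency scanner.
oracle_freq_events <- function(session) {
  ch <- session$trials$choice
  rw <- session$trials$reward
  recs <- data.frame()
  for (n in 7:length(ch)) {
    b <- ch[n - 1]
    cnt <- 0
    for (m in (n - 6):(n - 2)) if (ch[m] == b) cnt <- cnt + 1
    recs <- rbind(recs, data.frame(
      condition = cnt,
      prior_outcome = if (rw[n - 1] == 1) "reward" else "no_reward",
      rep = as.integer(ch[n] == b)))
  }
  recs
}

aggregate_binary <- function(events, value_col) {
  out <- stats::aggregate(events[[value_col]],
                          by = events[c("condition", "prior_outcome")],
                          FUN = function(x) c(n = length(x), m = mean(x)))
  data.frame(condition = out$condition, prior_outcome = out$prior_outcome,
             n = out$x[, "n"], p = out$x[, "m"])
}
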