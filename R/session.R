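# Session objects and the trial loop of the task.

#' Construct a session object
#'
#' A session bundles an ordered trial table with subject/group/phase metadata
#' and the schedule it was run on. Options are coded 0-2, rewards 0/1, and
#' trials are numbered contiguously from 1.
#'
#' @param subject_id Character subject identifier.
#' @param group `"control"` or `"mdmc"`.
#' @param phase `"pre"` or `"post"` (relative to surgery).
#' @param schedule The `reward_schedule` the session was run on.
#' @param trials Data frame with columns `trial`, `config_id`, `choice`,
#'   `reward`, `latency_ms` (and optionally `pos_opt0..2`, the screen slot of
#'   each option).
#' @param session_id Integer session number within subject x schedule x phase.
#' @return An object of class `bandit_session`.
#' @export
bandit_session <- function(subject_id, group, phase, schedule, trials,
                           session_id = 1L) {
  group <- match.arg(group, c("control", "mdmc"))
  phase <- match.arg(phase, c("pre", "post"))
  stopifnot(inherits(schedule, "reward_schedule"), is.data.frame(trials))
  needed <- c("trial", "config_id", "choice", "reward", "latency_ms")
  miss <- setdiff(needed, names(trials))
  if (length(miss)) stop("trials missing columns: ", paste(miss, collapse = ", "))
  if (nrow(trials) != n_trials(schedule)) {
    stop("trial count does not match schedule length")
  }
  if (!identical(as.integer(trials$trial), seq_len(nrow(trials)))) {
    stop("trial indices must be contiguous from 1")
  }
  if (!all(trials$choice %in% 0:2)) stop("choice must be in {0, 1, 2}")
  if (!all(trials$reward %in% 0:1)) stop("reward must be 0 or 1")
  lat <- trials$latency_ms
  if (any(!is.na(lat) & lat <= 0)) stop("latency_ms must be positive")
  structure(
    list(subject_id = as.character(subject_id), group = group, phase = phase,
         schedule = schedule, trials = trials,
         session_id = as.integer(session_id)),
    class = "bandit_session"
  )
}

#' @export
print.bandit_session <- function(x, ...) {
  cat(sprintf("<bandit_session: %s %s/%s %s #%d, %d trials>\n",
              x$subject_id, x$group, x$phase, x$schedule$kind, x$session_id,
              nrow(x$trials)))
  invisible(x)
}

#' Run one session of the bandit task
#'
#' Plays the trial loop: on each trial the spatial configuration and option
#' positions are drawn uniformly, the policy supplies a choice distribution
#' over the three options, a choice is sampled, and reward is drawn as an
#' independent Bernoulli from the chosen option's scheduled probability for
#' that trial. Rewards on unchosen options are never held over. The whole
#' session is deterministic given `seed`.
#'
#' @param schedule A `reward_schedule`.
#' @param policy A policy as returned by [rw_agent()], [lesion_agent()],
#'   [kernel_agent()] or [fixed_choice_policy()].
#' @param seed Integer seed.
#' @param subject_id,group,phase,session_id Metadata stored on the session.
#' @return A `bandit_session`.
#' @export
play_session <- function(schedule, policy, seed, subject_id = "sim",
                         group = "control", phase = "pre", session_id = 1L) {
  stopifnot(inherits(schedule, "reward_schedule"))
  if (!inherits(policy, "bandit_policy")) stop("`policy` must be a bandit_policy")
  set.seed(as.integer(seed))
  policy$reset()
  tn <- n_trials(schedule)
  choice <- integer(tn); reward <- integer(tn)
  config_id <- integer(tn); latency <- numeric(tn)
  pos <- matrix(NA_integer_, tn, 3)
  prev_choice <- NA_integer_
  for (t in seq_len(tn)) {
    config_id[t] <- sample.int(4L, 1L)
    pos[t, ] <- sample.int(3L) - 1L
    p <- policy$action_probs()
    if (length(p) != 3L || any(!is.finite(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8) {
      stop("policy returned an invalid choice distribution")
    }
    ch <- sample.int(3L, 1L, prob = p) - 1L
    rw <- stats::rbinom(1L, 1L, schedule$probs[t, ch + 1L])
    is_switch <- !is.na(prev_choice) && ch != prev_choice
    latency[t] <- policy$draw_latency(is_switch)
    policy$update(ch, rw)
    choice[t] <- ch; reward[t] <- rw; prev_choice <- ch
  }
  trials <- data.frame(
    trial = seq_len(tn), config_id = config_id, choice = choice,
    reward = reward, latency_ms = latency,
    pos_opt0 = pos[, 1], pos_opt1 = pos[, 2], pos_opt2 = pos[, 3]
  )
  bandit_session(subject_id, group, phase, schedule, trials, session_id)
}

#' Deterministic single-option policy
#'
#' Always chooses the given option; useful for degenerate-case checks.
#'
#' @param option Option index 0-2.
#' @param latency_ms Constant latency to report.
#' @return A `bandit_policy`.
#' @export
fixed_choice_policy <- function(option, latency_ms = 400) {
  stopifnot(option %in% 0:2)
  p <- c(0, 0, 0); p[option + 1L] <- 1
  structure(list(
    reset = function() invisible(NULL),
    action_probs = function() p,
    update = function(choice, reward) invisible(NULL),
    draw_latency = function(is_switch) latency_ms
  ), class = "bandit_policy")
}

#' Uniform random policy
#'
#' Chooses among the three options uniformly on every trial.
#'
#' @param latency_ms Constant latency to report.
#' @return A `bandit_policy`.
#' @export
uniform_policy <- function(latency_ms = 400) {
  structure(list(
    reset = function() invisible(NULL),
    action_probs = function() rep(1 / 3, 3),
    update = function(choice, reward) invisible(NULL),
    draw_latency = function(is_switch) latency_ms
  ), class = "bandit_policy")
}
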