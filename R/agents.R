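# Synthetic behaving agents: a control Rescorla-Wagner value learner, a
# lesion-mechanism variant in which outcome credit for recently sampled
# options is attenuated (an eligibility-trace account of the MDmc lesion),
# and a planted-kernel agent that provides ground truth for the lagged
# regression. All are policies usable with play_session().

#' Agent parameter set
#'
#' Parameters of the simulated value-learning agents. The trace parameters
#' operationalise an eligibility-trace mechanism: each outcome's value update
#' is scaled by `trace_atten` whenever the chosen option was selected fewer
#' than `trace_threshold` times over the previous `trace_span` trials, while
#' updates for frequently chosen options are left intact. `trace_atten = 1`
#' (the control setting) disables the mechanism. Latencies are lognormal:
#' `log latency ~ N(log(latency_base_ms + latency_switch_add_ms * switch),
#' latency_sigma)`, so switch trials are slower by a constant log offset;
#' the lesion phenotype sets the switch addition to 0 and lowers the base.
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta_sm Softmax inverse temperature, >= 0.
#' @param init_value Initial option value.
#' @param trace_span Number of recent trials considered by the trace
#'   mechanism (default 5).
#' @param trace_atten Multiplier in \[0, 1\] on value updates for options
#'   below the recent-choice threshold; 1 = intact.
#' @param trace_threshold Minimum selection count over the previous
#'   `trace_span` trials for an update to escape attenuation (default 3).
#' @param latency_base_ms Median stay-trial latency in ms.
#' @param latency_switch_add_ms Addition to the median latency on switch
#'   trials, in ms.
#' @param latency_sigma Lognormal sigma (log-ms scale).
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.3, beta_sm = 5, init_value = 1 / 3,
                         trace_span = 5L, trace_atten = 1,
                         trace_threshold = 3L,
                         latency_base_ms = 400, latency_switch_add_ms = 150,
                         latency_sigma = 0.35) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (beta_sm < 0) stop("`beta_sm` must be >= 0")
  if (trace_atten < 0 || trace_atten > 1) stop("`trace_atten` must lie in [0, 1]")
  if (trace_span < 1) stop("`trace_span` must be >= 1")
  if (latency_base_ms <= 0 || latency_sigma < 0 || latency_switch_add_ms < 0) {
    stop("latency parameters must be non-negative (base strictly positive)")
  }
  structure(list(
    alpha = alpha, beta_sm = beta_sm, init_value = init_value,
    trace_span = as.integer(trace_span), trace_atten = trace_atten,
    trace_threshold = as.integer(trace_threshold),
    latency_base_ms = latency_base_ms,
    latency_switch_add_ms = latency_switch_add_ms,
    latency_sigma = latency_sigma
  ), class = "agent_params")
}

latency_drawer <- function(params) {
  function(is_switch) {
    mu <- log(params$latency_base_ms +
                if (is_switch) params$latency_switch_add_ms else 0)
    stats::rlnorm(1L, meanlog = mu, sdlog = params$latency_sigma)
  }
}

#' Rescorla-Wagner softmax agent
#'
#' A policy maintaining three option values, updating only the chosen
#' option's value by the delta rule after each outcome and choosing by the
#' Boltzmann rule.
#'
#' @param params An [agent_params()] object.
#' @return A `bandit_policy` for [play_session()].
#' @export
rw_agent <- function(params = agent_params()) {
  stopifnot(inherits(params, "agent_params"))
  p <- unclass(params)
  p$trace_atten <- 1
  lesion_agent(do.call(agent_params, p))
}

#' Eligibility-trace-attenuated agent (lesion mechanism)
#'
#' Identical to [rw_agent()] except that the value update following each
#' outcome is multiplied by `trace_atten` whenever the chosen option was
#' selected fewer than `trace_threshold` times over the previous
#' `trace_span` trials. Options with a long recent choice history are
#' updated at full strength, so long-run choice trends are learned normally;
#' what is degraded is the rapid crediting of outcomes to recently sampled
#' alternatives. With `trace_atten = 1` the policy is behaviourally
#' identical to the control agent.
#'
#' @param params An [agent_params()] object; `trace_atten < 1` engages the
#'   mechanism.
#' @return A `bandit_policy` for [play_session()].
#' @export
lesion_agent <- function(params = agent_params(trace_atten = 0.2)) {
  stopifnot(inherits(params, "agent_params"))
  env <- new.env(parent = emptyenv())
  reset <- function() {
    env$v <- rep(params$init_value, 3L)
    env$recent <- integer(0)  # previous choices, most recent last
  }
  reset()
  draw_lat <- latency_drawer(params)
  structure(list(
    reset = reset,
    action_probs = function() softmax_probs(env$v, params$beta_sm),
    update = function(choice, reward) {
      k <- min(length(env$recent), params$trace_span)
      cnt <- if (k > 0) {
        sum(utils::tail(env$recent, k) == choice)
      } else 0L
      scale <- if (cnt < params$trace_threshold) params$trace_atten else 1
      i <- choice + 1L
      env$v[i] <- env$v[i] + scale * params$alpha * (reward - env$v[i])
      env$recent <- c(env$recent, choice)
      if (length(env$recent) > params$trace_span) {
        env$recent <- utils::tail(env$recent, params$trace_span)
      }
      invisible(NULL)
    },
    draw_latency = draw_lat,
    params = params
  ), class = "bandit_policy")
}

#' Planted choice-by-outcome kernel
#'
#' Ground-truth weights for the lagged logistic-regression kernel: a 5 x 5
#' grid of interest weights indexed (choice lag, outcome lag), an intercept,
#' and the 11 lag-6 confound weights (choice lag 6 crossed with outcome lags
#' 1-6, and outcome lag 6 crossed with choice lags 1-5).
#'
#' @param grid Numeric 5 x 5 matrix, rows = choice lags 1-5, columns =
#'   outcome lags 1-5.
#' @param intercept Scalar intercept.
#' @param lag6_choice Length-6 vector: weights for (choice lag 6, outcome
#'   lag j), j = 1..6.
#' @param lag6_outcome Length-5 vector: weights for (choice lag i, outcome
#'   lag 6), i = 1..5.
#' @return A list of class `planted_kernel` carrying the full 6 x 6 weight
#'   matrix in `w`.
#' @export
planted_kernel <- function(grid, intercept = 0, lag6_choice = numeric(6),
                           lag6_outcome = numeric(5)) {
  grid <- as.matrix(grid)
  if (!identical(dim(grid), c(5L, 5L))) stop("`grid` must be 5 x 5")
  if (any(!is.finite(grid)) || !is.finite(intercept) ||
      any(!is.finite(lag6_choice)) || any(!is.finite(lag6_outcome))) {
    stop("kernel weights must be finite")
  }
  if (length(lag6_choice) != 6L || length(lag6_outcome) != 5L) {
    stop("lag-6 confound weights must have lengths 6 and 5")
  }
  w <- matrix(0, 6, 6)
  w[1:5, 1:5] <- grid
  w[6, ] <- lag6_choice
  w[1:5, 6] <- lag6_outcome
  structure(list(grid = grid, intercept = intercept, w = w),
            class = "planted_kernel")
}

#' Agent choosing from a planted history kernel
#'
#' At each trial with at least 6 predecessors the agent scores each option
#' `s` as `intercept + sum_{i,j} w[i,j] * c_i(s) * r_j`, where `c_i(s)` is
#' +1 if the choice at lag `i` was `s` and -1 otherwise, and `r_j` is the
#' 0/1 outcome at lag `j` -- exactly the explanatory-variable coding the
#' lagged regression uses -- and chooses by a multinomial logistic rule over
#' the three scores. During the warm-up (history shorter than 6 trials) it
#' chooses uniformly.
#'
#' @param kernel A [planted_kernel()].
#' @param latency_params An [agent_params()] used only for latencies.
#' @return A `bandit_policy` for [play_session()].
#' @export
kernel_agent <- function(kernel, latency_params = agent_params()) {
  stopifnot(inherits(kernel, "planted_kernel"))
  env <- new.env(parent = emptyenv())
  reset <- function() {
    env$choices <- integer(0)
    env$rewards <- integer(0)
  }
  reset()
  draw_lat <- latency_drawer(latency_params)
  structure(list(
    reset = reset,
    action_probs = function() {
      n <- length(env$choices)
      if (n < 6L) return(rep(1 / 3, 3))
      ch <- env$choices[n:(n - 5L)]  # lags 1..6
      r <- env$rewards[n:(n - 5L)]
      scores <- vapply(0:2, function(s) {
        cs <- ifelse(ch == s, 1, -1)
        kernel$intercept + drop(cs %*% kernel$w %*% r)
      }, numeric(1))
      e <- exp(scores - max(scores))
      e / sum(e)
    },
    update = function(choice, reward) {
      env$choices <- c(env$choices, choice)
      env$rewards <- c(env$rewards, reward)
      invisible(NULL)
    },
    draw_latency = draw_lat
  ), class = "bandit_policy")
}

#' Cohort configuration
#'
#' Describes a simulated study cohort: subjects and groups, schedules,
#' sessions per schedule, phases, per-group agent parameters and the master
#' seed. The default mirrors the study design this package emulates: 7
#' control and 3 lesion subjects, two varying schedules (stable, variable),
#' 5 sessions per schedule, pre and post phases, with the lesion agent
#' parameters applied only to the lesion group post-surgery.
#'
#' @param n_control,n_lesion Numbers of subjects per group.
#' @param schedule_kinds Character vector of varying schedule kinds.
#' @param fixed_levels Integer vector of fixed-schedule levels to run
#'   post-surgery (empty by default).
#' @param n_sessions Sessions per subject x schedule x phase.
#' @param phases Phases to simulate.
#' @param seed Master seed; everything downstream is derived from it.
#' @param control_params,lesion_params [agent_params()] for the control
#'   behaviour and for the lesion group's post phase.
#' @param fixed_base_probs Base probabilities for fixed schedules.
#' @param subject_ids Optional explicit subject ids (controls first).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 7L, n_lesion = 3L,
                          schedule_kinds = c("stable", "variable"),
                          fixed_levels = integer(0),
                          n_sessions = 5L,
                          phases = c("pre", "post"),
                          seed = 1L,
                          control_params = agent_params(),
                          lesion_params = agent_params(
                            trace_atten = 0.2, latency_base_ms = 300,
                            latency_switch_add_ms = 0),
                          fixed_base_probs = c(0.8, 0.5, 0.2),
                          subject_ids = NULL) {
  stopifnot(all(schedule_kinds %in% VARYING_KINDS),
            all(fixed_levels %in% 1:3),
            all(phases %in% c("pre", "post")),
            inherits(control_params, "agent_params"),
            inherits(lesion_params, "agent_params"))
  if (is.null(subject_ids)) {
    subject_ids <- c(if (n_control > 0) paste0("C", seq_len(n_control)),
                     if (n_lesion > 0) paste0("MD", seq_len(n_lesion)))
  }
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids")
  if (length(subject_ids) != n_control + n_lesion) {
    stop("`subject_ids` must have length n_control + n_lesion")
  }
  subjects <- data.frame(
    subject_id = subject_ids,
    group = rep(c("control", "mdmc"), c(n_control, n_lesion)),
    stringsAsFactors = FALSE
  )
  structure(list(
    subjects = subjects, schedule_kinds = schedule_kinds,
    fixed_levels = as.integer(fixed_levels),
    n_sessions = as.integer(n_sessions), phases = phases,
    seed = as.integer(seed),
    control_params = control_params, lesion_params = lesion_params,
    fixed_base_probs = fixed_base_probs
  ), class = "cohort_config")
}

# Deterministic per-session seed from the cohort seed and session keys.
session_seed <- function(seed, subject_id, phase, kind, session_id) {
  key <- paste(subject_id, phase, kind, session_id, sep = "|")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  substream_seed(seed, h)
}

#' Simulate a cohort of sessions
#'
#' Runs the full study design described by a [cohort_config()]: every
#' subject plays `n_sessions` sessions of each varying schedule in each
#' phase (and of each fixed level, post phase only, if requested). Schedules
#' are predetermined per (kind, phase, session number) and shared across
#' subjects, as in the task the package emulates; lesion-group subjects use
#' `lesion_params` in the post phase and `control_params` otherwise. The
#' output is a pure function of the config.
#'
#' @param config A [cohort_config()].
#' @return A list of `bandit_session` objects.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  sessions <- list()
  specs <- list()
  for (kind in config$schedule_kinds) {
    for (phase in config$phases) {
      specs[[length(specs) + 1L]] <- list(kind = kind, phase = phase,
                                          fixed = FALSE)
    }
  }
  for (lev in config$fixed_levels) {
    specs[[length(specs) + 1L]] <- list(kind = paste0("fixed", lev),
                                        phase = "post", fixed = TRUE,
                                        level = lev)
  }
  for (sp in specs) {
    for (sess in seq_len(config$n_sessions)) {
      sched <- if (sp$fixed) {
        generate_fixed_schedule(sp$level, config$fixed_base_probs)
      } else {
        generate_varying_schedule(
          sp$kind,
          seed = session_seed(config$seed, "schedule", sp$phase, sp$kind, sess)
        )
      }
      for (k in seq_len(nrow(config$subjects))) {
        sid <- config$subjects$subject_id[k]
        grp <- config$subjects$group[k]
        par <- if (grp == "mdmc" && sp$phase == "post") {
          config$lesion_params
        } else {
          config$control_params
        }
        pol <- lesion_agent(par)
        sessions[[length(sessions) + 1L]] <- play_session(
          sched, pol,
          seed = session_seed(config$seed, sid, sp$phase, sp$kind, sess),
          subject_id = sid, group = grp, phase = sp$phase, session_id = sess
        )
      }
    }
  }
  sessions
}

#' Filter a list of sessions by metadata
#'
#' @param sessions List of `bandit_session` objects.
#' @param group,phase,subject_id,kind Optional filters; `NULL` means keep
#'   all.
#' @return The matching subset, still a list.
#' @export
filter_sessions <- function(sessions, group = NULL, phase = NULL,
                            subject_id = NULL, kind = NULL) {
  keep <- vapply(sessions, function(s) {
    (is.null(group) || s$group %in% group) &&
      (is.null(phase) || s$phase %in% phase) &&
      (is.null(subject_id) || s$subject_id %in% subject_id) &&
      (is.null(kind) || s$schedule$kind %in% kind)
  }, logical(1))
  sessions[keep]
}
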