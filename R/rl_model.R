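# Rescorla-Wagner value learning with Boltzmann choice: the update rule,
# softmax, session likelihood, maximum-likelihood fitting of the learning
# rate, and subjective best-option labelling.

#' Rescorla-Wagner value update
#'
#' Applies the delta rule `V' = V + alpha * (r - V)` to the chosen option's
#' value. Only the chosen option is updated on a trial.
#'
#' @param value Current value.
#' @param reward Outcome, 0 or 1.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value.
#' @export
rw_update <- function(value, reward, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must lie in [0, 1]")
  value + alpha * (reward - value)
}

#' Boltzmann (softmax) choice probabilities
#'
#' Choice probabilities proportional to `exp(beta_sm * V)`, computed with
#' max-subtraction for numerical stability.
#'
#' @param values Numeric 3-vector of option values.
#' @param beta_sm Inverse temperature, >= 0.
#' @return Probability 3-vector summing to 1.
#' @export
softmax_probs <- function(values, beta_sm) {
  if (beta_sm < 0) stop("`beta_sm` must be >= 0")
  if (any(!is.finite(values))) stop("`values` must be finite")
  z <- beta_sm * values
  e <- exp(z - max(z))
  e / sum(e)
}

# Flatten a list of sessions into parallel choice/reward/session-id vectors.
flatten_sessions <- function(sessions) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  if (!length(sessions)) stop("`sessions` must be non-empty")
  ch <- integer(0); rw <- integer(0); sid <- integer(0)
  for (k in seq_along(sessions)) {
    s <- sessions[[k]]
    stopifnot(inherits(s, "bandit_session"))
    if (!nrow(s$trials)) stop("session with no trials")
    ch <- c(ch, as.integer(s$trials$choice))
    rw <- c(rw, as.integer(s$trials$reward))
    sid <- c(sid, rep.int(k, nrow(s$trials)))
  }
  list(choices = ch, rewards = rw, session_index = sid)
}

#' Negative log-likelihood of sessions under the Rescorla-Wagner model
#'
#' Sums `-log P(choice_t)` over all trials, forward-simulating option values
#' from the actual choices and rewards, with values reset to `init_value` at
#' the start of each session (every session uses novel stimuli). Degenerate
#' parameter settings that assign a chosen option probability zero yield
#' `+Inf` rather than an error.
#'
#' @param sessions A `bandit_session` or list of them.
#' @param alpha Learning rate in \[0, 1\].
#' @param beta_sm Softmax inverse temperature, >= 0.
#' @param init_value Initial option value (default 1/3).
#' @return The negative log-likelihood (a non-negative scalar, possibly
#'   `Inf`).
#' @export
session_nll <- function(sessions, alpha, beta_sm, init_value = 1 / 3) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  if (beta_sm < 0) stop("`beta_sm` must be >= 0")
  d <- flatten_sessions(sessions)
  .rw_nll_cpp(d$choices, d$rewards, d$session_index, alpha, beta_sm,
              init_value)
}

#' Fit the Rescorla-Wagner learning rate by maximum likelihood
#'
#' Minimises [session_nll()] over the learning rate (and, by default, jointly
#' over the softmax inverse temperature) using bounded quasi-Newton
#' optimisation from a grid of starting points. Intended for a single
#' subject's pre-surgery sessions; the fitted rate is then reused for that
#' subject's post-surgery analyses.
#'
#' @param sessions A `bandit_session` or list of them (one subject).
#' @param fit_beta If `TRUE` (default) fit `beta_sm` jointly; otherwise hold
#'   it at `beta_fixed`.
#' @param beta_fixed Inverse temperature used when `fit_beta = FALSE`.
#' @param init_value Initial option value.
#' @param alpha_starts,beta_starts Multi-start grids.
#' @return A list of class `rw_fit` with `alpha_hat`, `beta_sm_hat`,
#'   `neg_log_likelihood`, `n_trials`, `converged`, `at_boundary` and the
#'   per-start diagnostics in `starts`.
#' @export
fit_learning_rate <- function(sessions, fit_beta = TRUE, beta_fixed = 5,
                              init_value = 1 / 3,
                              alpha_starts = c(0.05, 0.2, 0.4, 0.6, 0.9),
                              beta_starts = c(1, 3, 8, 20)) {
  d <- flatten_sessions(sessions)
  lower_a <- 1e-4; upper_a <- 1
  lower_b <- 1e-3; upper_b <- 50
  obj <- if (fit_beta) {
    function(par) .rw_nll_cpp(d$choices, d$rewards, d$session_index,
                              par[1], par[2], init_value)
  } else {
    function(par) .rw_nll_cpp(d$choices, d$rewards, d$session_index,
                              par[1], beta_fixed, init_value)
  }
  starts <- if (fit_beta) {
    as.matrix(expand.grid(alpha = alpha_starts, beta = beta_starts))
  } else {
    matrix(alpha_starts, ncol = 1, dimnames = list(NULL, "alpha"))
  }
  lower <- if (fit_beta) c(lower_a, lower_b) else lower_a
  upper <- if (fit_beta) c(upper_a, upper_b) else upper_a
  best <- NULL
  diag_rows <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      diag_rows[[i]] <- data.frame(start = i, value = NA_real_,
                                   convergence = NA_integer_)
      next
    }
    diag_rows[[i]] <- data.frame(start = i, value = fit$value,
                                 convergence = fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimisation failed from every start")
  alpha_hat <- unname(best$par[1])
  beta_hat <- if (fit_beta) unname(best$par[2]) else beta_fixed
  structure(list(
    alpha_hat = alpha_hat,
    beta_sm_hat = beta_hat,
    neg_log_likelihood = best$value,
    n_trials = length(d$choices),
    converged = best$convergence == 0,
    at_boundary = alpha_hat <= lower_a + 1e-6 || alpha_hat >= upper_a - 1e-6,
    fit_beta = fit_beta,
    init_value = init_value,
    starts = do.call(rbind, diag_rows)
  ), class = "rw_fit")
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf(
    "<rw_fit: alpha = %.3f, beta_sm = %.2f, NLL = %.1f over %d trials%s%s>\n",
    x$alpha_hat, x$beta_sm_hat, x$neg_log_likelihood, x$n_trials,
    if (!x$converged) ", NOT converged" else "",
    if (x$at_boundary) ", alpha at boundary" else ""))
  invisible(x)
}

#' Forward-simulated value traces for a session
#'
#' Values each choice was based on (i.e. before that trial's update), given
#' the subject's actual choices and rewards.
#'
#' @param session A `bandit_session`.
#' @param alpha Learning rate.
#' @param init_value Initial option value.
#' @return T x 3 numeric matrix of option values.
#' @export
rw_value_trace <- function(session, alpha, init_value = 1 / 3) {
  stopifnot(inherits(session, "bandit_session"))
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]")
  v <- .rw_values_cpp(as.integer(session$trials$choice),
                      as.integer(session$trials$reward), alpha, init_value)
  colnames(v) <- paste0("v_opt", 0:2)
  v
}

#' Per-trial subjectively-best-option labels
#'
#' Labels each trial with the option of highest forward-simulated
#' Rescorla-Wagner value given the subject's actual choices and rewards (the
#' subjectively highest-value stimulus, V1_RL). Ties break towards the
#' lowest option index.
#'
#' @param session A `bandit_session`.
#' @param alpha Learning rate (typically from [fit_learning_rate()]).
#' @param init_value Initial option value.
#' @return Integer vector of option indices (0-2), one per trial.
#' @export
v1_rl_labels <- function(session, alpha, init_value = 1 / 3) {
  v <- rw_value_trace(session, alpha, init_value)
  as.integer(max.col(v, ties.method = "first") - 1L)
}
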