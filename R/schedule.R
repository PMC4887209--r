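# Reward schedules for the three-option bandit task.
#
# Two families are supported: "varying" schedules (stable, variable) of 300
# trials whose per-option reward probabilities drift continuously and whose
# best option reverses identity after trial 150, and "fixed" schedules
# (fixed1..fixed3) of 150 trials with constant probabilities sharing a common
# option ratio but scaled yield.

VARYING_KINDS <- c("stable", "variable")
FIXED_KINDS <- c("fixed1", "fixed2", "fixed3")

#' Construct a reward schedule object
#'
#' Low-level constructor; most users will call [generate_varying_schedule()]
#' or [generate_fixed_schedule()].
#'
#' @param kind One of `"stable"`, `"variable"`, `"fixed1"`, `"fixed2"`,
#'   `"fixed3"`.
#' @param probs Numeric T x 3 matrix of per-trial Bernoulli reward
#'   probabilities, one column per option (options are coded 0-2).
#' @param reversal_trial Trial after which the best-option identity changes
#'   (varying kinds only; `NA` for fixed kinds).
#' @param seed Integer seed used to generate the schedule (`NA` if loaded
#'   from file).
#' @return An object of class `reward_schedule`.
#' @export
reward_schedule <- function(kind, probs, reversal_trial = NA_integer_,
                            seed = NA_integer_) {
  kind <- match.arg(kind, c(VARYING_KINDS, FIXED_KINDS))
  probs <- as.matrix(probs)
  if (ncol(probs) != 3L) stop("`probs` must have exactly 3 columns")
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all reward probabilities must lie in [0, 1]")
  }
  colnames(probs) <- paste0("p_opt", 0:2)
  structure(
    list(kind = kind, probs = probs,
         reversal_trial = as.integer(reversal_trial),
         seed = as.integer(seed)),
    class = "reward_schedule"
  )
}

#' @export
print.reward_schedule <- function(x, ...) {
  cat(sprintf("<reward_schedule: %s, %d trials%s>\n", x$kind, nrow(x$probs),
              if (!is.na(x$reversal_trial))
                sprintf(", reversal after trial %d", x$reversal_trial)
              else ""))
  invisible(x)
}

#' Number of trials in a schedule
#' @param schedule A `reward_schedule`.
#' @return Integer trial count.
#' @export
n_trials <- function(schedule) nrow(schedule$probs)

# Derive a 32-bit sub-seed for an independent RNG stream.  Separate streams
# per option and per session segment are what lets the stable and variable
# kinds share every trace except the pre-reversal best option's.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset * 7919) %% 2147483647)
}

# Bounded smoothed random walk on [lo, hi]: Gaussian increments, reflecting
# boundaries, then a short moving-average smooth confined to the segment.
bounded_walk <- function(n, lo, hi, sigma, seed, start = (lo + hi) / 2) {
  set.seed(seed)
  x <- numeric(n)
  cur <- start
  for (t in seq_len(n)) {
    cur <- cur + stats::rnorm(1L, 0, sigma)
    # reflect into [lo, hi]
    while (cur < lo || cur > hi) {
      if (cur < lo) cur <- 2 * lo - cur
      if (cur > hi) cur <- 2 * hi - cur
    }
    x[t] <- cur
  }
  if (n >= 5L) {
    sm <- stats::filter(x, rep(1 / 5, 5), sides = 2)
    x <- ifelse(is.na(sm), x, as.numeric(sm))
  }
  pmin(pmax(x, lo), hi)
}

#' Generate a varying (reversing) reward schedule
#'
#' Produces a 300-trial schedule in which one option (the pre-reversal best,
#' option 0) carries a clearly higher reward probability over trials 1-150,
#' after which the best-option identity swaps to option 1 for trials 151-300.
#' Per-option probabilities fluctuate continuously as bounded smoothed random
#' walks. The `"stable"` and `"variable"` kinds generated from the same seed
#' differ only in the pre-reversal trace of the best option: under
#' `"variable"` it wanders over a wider band with larger increments, so the
#' initial learning period is noisier while everything else is identical.
#'
#' @param kind `"stable"` or `"variable"`.
#' @param seed Integer seed; the schedule is deterministic given `seed`.
#' @param params Optional list overriding schedule-shape parameters:
#'   `high_band` (2-vector, default `c(0.60, 0.90)`), `low_band` (default
#'   `c(0.10, 0.45)`), `stable_band` (default `c(0.65, 0.85)`),
#'   `variable_band` (default `c(0.50, 0.90)`), `sigma_low`, `sigma_stable`,
#'   `sigma_variable` (walk increment SDs).
#' @return A `reward_schedule` of 300 trials with `reversal_trial = 150`.
#' @export
generate_varying_schedule <- function(kind = c("stable", "variable"),
                                      seed = 1L, params = list()) {
  kind <- match.arg(kind)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  p <- utils::modifyList(list(
    high_band = c(0.60, 0.90),
    low_band = c(0.10, 0.45),
    stable_band = c(0.65, 0.85),
    variable_band = c(0.50, 0.90),
    sigma_low = 0.03,
    sigma_stable = 0.015,
    sigma_variable = 0.06
  ), params)
  for (b in c("high_band", "low_band", "stable_band", "variable_band")) {
    bb <- p[[b]]
    if (length(bb) != 2L || any(bb < 0) || any(bb > 1) || bb[1] >= bb[2]) {
      stop(sprintf("`%s` must be an increasing 2-vector within [0, 1]", b))
    }
  }
  if (max(p$low_band) >= min(p$stable_band) ||
      max(p$low_band) >= min(p$variable_band) ||
      max(p$low_band) >= min(p$high_band)) {
    stop("low band must lie strictly below every best-option band")
  }
  n_half <- 150L
  # Pre-reversal: option 0 is best; its trace is the only kind-dependent piece.
  v1_pre <- if (kind == "stable") {
    bounded_walk(n_half, p$stable_band[1], p$stable_band[2], p$sigma_stable,
                 substream_seed(seed, 6))
  } else {
    bounded_walk(n_half, p$variable_band[1], p$variable_band[2],
                 p$sigma_variable, substream_seed(seed, 7))
  }
  pre <- cbind(
    v1_pre,
    bounded_walk(n_half, p$low_band[1], p$low_band[2], p$sigma_low,
                 substream_seed(seed, 1)),
    bounded_walk(n_half, p$low_band[1], p$low_band[2], p$sigma_low,
                 substream_seed(seed, 2))
  )
  # Post-reversal: option 1 becomes best; all three post traces are shared
  # between kinds (independent substreams, so they do not depend on the pre
  # segment).
  post <- cbind(
    bounded_walk(n_half, p$low_band[1], p$low_band[2], p$sigma_low,
                 substream_seed(seed, 3)),
    bounded_walk(n_half, p$high_band[1], p$high_band[2], p$sigma_low,
                 substream_seed(seed, 4)),
    bounded_walk(n_half, p$low_band[1], p$low_band[2], p$sigma_low,
                 substream_seed(seed, 5))
  )
  reward_schedule(kind, rbind(pre, post), reversal_trial = 150L, seed = seed)
}

#' Generate a fixed (non-reversing) reward schedule
#'
#' Fixed schedules hold each option's reward probability constant over 150
#' trials. The three levels share the same option ratio but scale the
#' absolute yield: level 2 multiplies every probability by 0.75 and level 3
#' by 0.5 relative to level 1.
#'
#' @param level Integer 1, 2 or 3.
#' @param base_probs Strictly decreasing 3-vector of level-1 probabilities in
#'   (0, 1]; option 0 is the best option.
#' @return A `reward_schedule` of 150 constant-probability trials.
#' @export
generate_fixed_schedule <- function(level, base_probs = c(0.8, 0.5, 0.2)) {
  if (!level %in% 1:3) stop("`level` must be 1, 2 or 3")
  if (length(base_probs) != 3L || any(base_probs <= 0) ||
      any(base_probs > 1) || any(diff(base_probs) >= 0)) {
    stop("`base_probs` must be a strictly decreasing 3-vector in (0, 1]")
  }
  scale <- c(1, 0.75, 0.5)[level]
  probs <- base_probs * scale
  if (any(probs > 1)) stop("scaled probability exceeds 1")
  reward_schedule(paste0("fixed", level),
                  matrix(rep(probs, each = 150L), nrow = 150L))
}

#' Centred moving-window mean
#'
#' Smooths a per-trial series with a centred window of `window` trials
#' (+/- `window/2` around each trial), truncating the window at the session
#' edges rather than padding, so the output has the same length as the input.
#'
#' @param values Numeric per-trial series.
#' @param window Even window width in trials (default 20, i.e. +/-10).
#' @param align `"center"` (default) or `"trailing"`; trailing uses the
#'   window of `window` trials ending at each trial, truncated at the start.
#' @return Numeric vector of smoothed values, same length as `values`.
#' @export
moving_window_prob <- function(values, window = 20L,
                               align = c("center", "trailing")) {
  align <- match.arg(align)
  if (length(values) == 0L) stop("`values` must be non-empty")
  if (window < 2L || window %% 2L != 0L) stop("`window` must be even and >= 2")
  n <- length(values)
  half <- window %/% 2L
  vapply(seq_len(n), function(t) {
    idx <- if (align == "center") {
      max(1L, t - half):min(n, t + half)
    } else {
      max(1L, t - window + 1L):t
    }
    mean(values[idx])
  }, numeric(1))
}

#' Per-trial objectively-best-option labels
#'
#' Labels each trial with the option whose moving-window-smoothed scheduled
#' reward probability is highest (the objectively highest-value stimulus,
#' V1_sch). Ties are broken towards the lowest option index.
#'
#' @param schedule A `reward_schedule`.
#' @param window Moving-window width passed to [moving_window_prob()].
#' @param align Window alignment, see [moving_window_prob()].
#' @return Integer vector of option indices (0-2), one per trial.
#' @export
v1_sch_labels <- function(schedule, window = 20L,
                          align = c("center", "trailing")) {
  align <- match.arg(align)
  stopifnot(inherits(schedule, "reward_schedule"))
  sm <- apply(schedule$probs, 2, moving_window_prob, window = window,
              align = align)
  as.integer(max.col(sm, ties.method = "first") - 1L)
}
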