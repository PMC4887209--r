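# Lagged choice-by-outcome logistic-regression kernel.
#
# For each of the three stimuli a logistic regression predicts "chose this
# stimulus" from 36 explanatory variables (EVs), one per combination of
# choice lag i and outcome lag j over the previous 6 trials: 25 EVs of
# interest (i <= 5 and j <= 5) and 11 confound EVs capturing longer-term
# trends (i = 6 or j = 6). The EV for (i, j) is 0 when the outcome at lag j
# was no reward, +1 when it was a reward and the choice at lag i was the
# target stimulus, and -1 when it was a reward and the choice at lag i was
# one of the other stimuli. The three per-stimulus weight vectors are then
# combined by the inverse-covariance (variance-weighted) mean, and the 5 x 5
# interest grid is partitioned into contingent (i = j) and spread-of-effect
# (i != j) components.

KERNEL_LAGS <- 6L

kernel_column_map <- function() {
  cm <- expand.grid(outcome_lag = 1:KERNEL_LAGS, choice_lag = 1:KERNEL_LAGS)
  cm <- cm[, c("choice_lag", "outcome_lag")]
  cm <- cm[order(cm$choice_lag, cm$outcome_lag), ]
  rownames(cm) <- NULL
  cm$role <- ifelse(cm$choice_lag <= 5L & cm$outcome_lag <= 5L,
                    "interest", "confound")
  cm$name <- sprintf("c%d_o%d", cm$choice_lag, cm$outcome_lag)
  cm
}

#' Build the lagged choice-by-outcome design matrix for one stimulus
#'
#' One row per trial with at least 6 predecessors within the same session
#' (histories never span session boundaries, since each session uses novel
#' stimuli). Column (i, j) codes the interaction of the choice at trial
#' n-i with the outcome at trial n-j: 0 if that outcome was no reward, +1 if
#' it was a reward and the lag-i choice was `target`, -1 if it was a reward
#' and the lag-i choice was another stimulus. The response is 1 when the
#' current choice is `target`.
#'
#' @param sessions A `bandit_session` or list of them.
#' @param target Target option index (0-2).
#' @return A list of class `kernel_design` with `X` (N x 36 matrix of
#'   values in \{-1, 0, +1\}), `y` (0/1 response), `column_map` (choice lag,
#'   outcome lag, interest/confound role per column) and `target`.
#' @export
build_design_matrix <- function(sessions, target) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  if (!length(sessions)) stop("`sessions` must be non-empty")
  stopifnot(target %in% 0:2)
  cm <- kernel_column_map()
  xs <- list(); ys <- list()
  for (s in sessions) {
    stopifnot(inherits(s, "bandit_session"))
    ch <- as.integer(s$trials$choice)
    rw <- as.integer(s$trials$reward)
    tn <- length(ch)
    if (tn < KERNEL_LAGS + 1L) next  # too short to contribute rows
    n <- (KERNEL_LAGS + 1L):tn
    X <- matrix(0L, length(n), nrow(cm))
    for (k in seq_len(nrow(cm))) {
      i <- cm$choice_lag[k]; j <- cm$outcome_lag[k]
      sign_i <- ifelse(ch[n - i] == target, 1L, -1L)
      X[, k] <- rw[n - j] * sign_i
    }
    xs[[length(xs) + 1L]] <- X
    ys[[length(ys) + 1L]] <- as.integer(ch[n] == target)
  }
  if (!length(xs)) stop("no session long enough to contribute rows")
  X <- do.call(rbind, xs)
  colnames(X) <- cm$name
  structure(list(X = X, y = unlist(ys), column_map = cm,
                 target = as.integer(target)),
            class = "kernel_design")
}

# Penalised (ridge) logistic regression by Newton iterations; the intercept
# is never penalised. Returns coefficients and the inverse penalised
# Hessian as covariance.
ridge_logistic <- function(Xi, y, lambda) {
  p <- ncol(Xi)
  pen <- c(0, rep(lambda, p - 1L))
  b <- rep(0, p)
  for (it in 1:100) {
    eta <- drop(Xi %*% b)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xi, y - mu)) - 2 * pen * b
    H <- crossprod(Xi, Xi * w) + 2 * diag(pen, p)
    step <- solve(H, grad)
    b <- b + step
    if (max(abs(step)) < 1e-9) break
  }
  list(coef = b, cov = solve(H))
}

#' Fit the per-stimulus logistic regression
#'
#' Maximum-likelihood logistic regression of the response on the 36 EVs plus
#' an intercept. The covariance of the slope estimates is the inverse
#' observed information by default, or a robust (sandwich) estimate. Should
#' the fit separate (some fitted probabilities numerically 0/1, divergent
#' coefficients), the fit is repeated with a small ridge penalty on the
#' slopes and flagged; aliased (rank-deficient) columns are reported, their
#' coefficients set to 0 and their covariance rows/columns zeroed.
#'
#' @param dm A [build_design_matrix()] result.
#' @param vcov_type `"model"` (inverse observed information, default) or
#'   `"robust"` (sandwich).
#' @param ridge_lambda Ridge penalty used only in the separation fallback.
#' @return A list of class `kernel_fit` with `beta` (named 36-vector),
#'   `cov` (36 x 36), `intercept`, `separation`, `dropped` (aliased column
#'   names), `vcov_type`, `n`.
#' @export
fit_stimulus_regression <- function(dm, vcov_type = c("model", "robust"),
                                    ridge_lambda = 1e-2) {
  stopifnot(inherits(dm, "kernel_design"))
  vcov_type <- match.arg(vcov_type)
  X <- dm$X; y <- dm$y
  p <- ncol(X)
  dat <- data.frame(y = y, X, check.names = FALSE)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- stats::coef(fit)
  dropped <- names(co)[-1][is.na(co[-1])]
  separation <- sep_warn || !fit$converged ||
    any(abs(co[!is.na(co)]) > 15)
  beta <- numeric(p); names(beta) <- colnames(X)
  covm <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  if (separation) {
    rf <- ridge_logistic(cbind(1, X), y, ridge_lambda)
    intercept <- rf$coef[1]
    beta[] <- rf$coef[-1]
    covm[, ] <- rf$cov[-1, -1]
  } else {
    intercept <- co[1]
    keep <- !is.na(co[-1])
    beta[keep] <- co[-1][keep]
    V <- if (vcov_type == "model") stats::vcov(fit) else sandwich::sandwich(fit)
    covm[keep, keep] <- V[-1, -1, drop = FALSE]
  }
  structure(list(beta = beta, cov = covm, intercept = unname(intercept),
                 separation = separation, dropped = dropped,
                 vcov_type = vcov_type, n = length(y),
                 column_map = dm$column_map, target = dm$target),
            class = "kernel_fit")
}

#' Inverse-covariance-weighted combination of per-stimulus weights
#'
#' Combines the three per-stimulus weight vectors by the variance-weighted
#' mean `(C_A^-1 + C_B^-1 + C_C^-1)^-1 (C_A^-1 b_A + C_B^-1 b_B +
#' C_C^-1 b_C)`. With identical covariances this reduces to the arithmetic
#' mean. Singular covariances fall back to the Moore-Penrose pseudo-inverse,
#' flagged via the `"pseudo_inverse"` attribute.
#'
#' @param betas List of coefficient vectors (equal lengths).
#' @param covs List of covariance matrices (or scalar variances in the
#'   1-dimensional case), same length as `betas`.
#' @return Combined coefficient vector, with attribute `pseudo_inverse`.
#' @export
combine_weights <- function(betas, covs) {
  if (length(betas) != length(covs) || !length(betas)) {
    stop("`betas` and `covs` must be non-empty lists of equal length")
  }
  p <- length(betas[[1]])
  used_pinv <- FALSE
  inv_of <- function(C) {
    C <- as.matrix(C)
    if (!identical(dim(C), c(p, p))) stop("covariance dimension mismatch")
    out <- tryCatch(solve(C), error = function(e) NULL)
    if (is.null(out)) {
      used_pinv <<- TRUE
      out <- MASS::ginv(C)
    }
    out
  }
  acc_w <- matrix(0, p, p)
  acc_b <- numeric(p)
  for (k in seq_along(betas)) {
    b <- as.numeric(betas[[k]])
    if (length(b) != p) stop("beta dimension mismatch")
    Wi <- inv_of(covs[[k]])
    acc_w <- acc_w + Wi
    acc_b <- acc_b + drop(Wi %*% b)
  }
  inv_acc <- tryCatch(solve(acc_w), error = function(e) {
    used_pinv <<- TRUE
    MASS::ginv(acc_w)
  })
  out <- drop(inv_acc %*% acc_b)
  names(out) <- names(betas[[1]])
  attr(out, "pseudo_inverse") <- used_pinv
  out
}

#' Extract the 5 x 5 interest grid from a combined weight vector
#'
#' @param beta Named 36-vector in [kernel_column_map()] order.
#' @return 5 x 5 matrix, rows = choice lags 1-5, columns = outcome lags 1-5.
#' @export
kernel_grid <- function(beta) {
  cm <- kernel_column_map()
  g <- matrix(NA_real_, 5, 5,
              dimnames = list(paste0("choice_lag", 1:5),
                              paste0("outcome_lag", 1:5)))
  keep <- cm$role == "interest"
  g[cbind(cm$choice_lag[keep], cm$outcome_lag[keep])] <-
    as.numeric(beta)[keep]
  g
}

#' Partition the interest grid into contingent and spread components
#'
#' The diagonal (choice lag = outcome lag) measures contingent credit
#' assignment: each outcome paired with the choice that produced it. Cells
#' above the diagonal (choice lag < outcome lag: a recent choice paired with
#' an unrelated earlier outcome) measure a past outcome spreading forward;
#' cells below (choice lag > outcome lag) measure a recent outcome spreading
#' backward onto earlier choices. Per-lag summaries average the off-diagonal
#' cells in the corresponding row or column of the triangle (undefined, and
#' `NA`, at lag 5, which has no unrelated partner lags).
#'
#' @param grid 5 x 5 interest grid from [kernel_grid()].
#' @return A list with `contingent` (5 weights by lag), `choice_spread_cells`
#'   and `outcome_spread_cells` (10 each), by-lag means
#'   `choice_spread_by_lag`, `outcome_spread_by_lag`, and overall means.
#' @export
partition_kernel <- function(grid) {
  grid <- as.matrix(grid)
  if (!identical(dim(grid), c(5L, 5L))) stop("`grid` must be 5 x 5")
  idx <- which(upper.tri(grid), arr.ind = TRUE)   # i < j
  idx_lo <- which(lower.tri(grid), arr.ind = TRUE) # i > j
  choice_by_lag <- vapply(1:5, function(i) {
    if (i == 5L) NA_real_ else mean(grid[i, (i + 1):5])
  }, numeric(1))
  outcome_by_lag <- vapply(1:5, function(j) {
    if (j == 5L) NA_real_ else mean(grid[(j + 1):5, j])
  }, numeric(1))
  list(
    contingent = diag(grid),
    choice_spread_cells = grid[idx],
    outcome_spread_cells = grid[idx_lo],
    choice_spread_by_lag = choice_by_lag,
    outcome_spread_by_lag = outcome_by_lag,
    contingent_mean = mean(diag(grid)),
    choice_spread_mean = mean(grid[idx]),
    outcome_spread_mean = mean(grid[idx_lo])
  )
}

#' Recent-versus-distant contrast on the last outcome's influence
#'
#' Contrasts how strongly the most recent outcome (outcome lag 1) interacts
#' with recent versus distant past choices: recent = choice lags \{1, 2\}
#' (or \{2, 3\} when restricted to non-contingent choices, avoiding the
#' lag-1 cell that conflates contingent learning with spread), distant =
#' choice lags \{4, 5\}.
#'
#' @param grid 5 x 5 interest grid.
#' @param mode `"with_n1"` or `"noncontingent_only"`.
#' @return Named numeric vector `c(recent, distant)`.
#' @export
recency_contrast <- function(grid, mode = c("with_n1", "noncontingent_only")) {
  mode <- match.arg(mode)
  grid <- as.matrix(grid)
  if (!identical(dim(grid), c(5L, 5L))) stop("`grid` must be 5 x 5")
  v <- grid[, 1]
  recent_idx <- if (mode == "with_n1") 1:2 else 2:3
  c(recent = mean(v[recent_idx]), distant = mean(v[4:5]))
}

#' Fit the full history kernel for a set of sessions
#'
#' Convenience wrapper running [build_design_matrix()] and
#' [fit_stimulus_regression()] for each of the three stimuli and combining
#' the weights with [combine_weights()]. The intended fitting unit is one
#' subject and phase, pooling that subject's sessions.
#'
#' @param sessions A `bandit_session` or list of them.
#' @param vcov_type Passed to [fit_stimulus_regression()].
#' @return A list of class `kernel_result` with `per_stimulus` (three
#'   `kernel_fit`s), `beta_combined`, `grid`, `partition` and
#'   `any_separation`.
#' @export
fit_history_kernel <- function(sessions, vcov_type = c("model", "robust")) {
  vcov_type <- match.arg(vcov_type)
  fits <- lapply(0:2, function(s) {
    fit_stimulus_regression(build_design_matrix(sessions, s),
                            vcov_type = vcov_type)
  })
  comb <- combine_weights(lapply(fits, `[[`, "beta"),
                          lapply(fits, `[[`, "cov"))
  grid <- kernel_grid(comb)
  structure(list(
    per_stimulus = fits,
    beta_combined = comb,
    grid = grid,
    partition = partition_kernel(grid),
    any_separation = any(vapply(fits, `[[`, logical(1), "separation")),
    column_map = kernel_column_map()
  ), class = "kernel_result")
}

#' @export
print.kernel_result <- function(x, ...) {
  cat(sprintf("<kernel_result: %d rows/stimulus, contingent mean %.3f%s>\n",
              x$per_stimulus[[1]]$n, x$partition$contingent_mean,
              if (x$any_separation) ", separation fallback used" else ""))
  invisible(x)
}
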