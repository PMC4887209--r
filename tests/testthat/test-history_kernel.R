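# Lagged choice-by-outcome design matrix, per-stimulus fits,
# inverse-covariance combination and grid partition.

test_that("the design matrix has 36 EVs (25 interest + 11 confound) valued in {-1,0,+1}", {
  s <- random_toy_session(60, seed = 1)
  dm <- build_design_matrix(s, target = 0)
  expect_identical(ncol(dm$X), 36L)
  expect_identical(sum(dm$column_map$role == "interest"), 25L)
  expect_identical(sum(dm$column_map$role == "confound"), 11L)
  expect_true(all(dm$column_map$role[dm$column_map$choice_lag <= 5 &
                                       dm$column_map$outcome_lag <= 5] ==
                    "interest"))
  expect_true(all(dm$X %in% c(-1, 0, 1)))
  expect_identical(nrow(dm$X), 60L - 6L)
  expect_true(all(dm$y %in% 0:1))
})

test_that("EV coding follows the choice/outcome interaction rule", {
  # trial n = 8; choice at n-2 is A (0), outcome at n-3 is reward
  ch <- c(1L, 1L, 2L, 1L, 1L, 0L, 2L, 0L)
  rw <- c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L)
  dm <- build_design_matrix(toy_session(ch, rw), target = 0)
  row <- dm$X[2, ]  # trial n = 8
  expect_equal(unname(row["c2_o3"]), 1)   # chose A at n-2, reward at n-3
  # same history, but the n-2 choice was another stimulus
  ch2 <- ch; ch2[6] <- 1L
  dm2 <- build_design_matrix(toy_session(ch2, rw), target = 0)
  expect_equal(unname(dm2$X[2, "c2_o3"]), -1)
  # no reward at lag j zeroes the whole outcome-lag column regardless of i
  expect_true(all(dm$X[2, paste0("c", 1:6, "_o1")] == 0))  # n-1 unrewarded
  expect_true(all(dm$X[2, paste0("c", 1:6, "_o2")] == 0))
})

test_that("rows never span session boundaries and short sessions contribute none", {
  s_short <- random_toy_session(6, seed = 2)
  expect_error(build_design_matrix(s_short, 0), "long enough")
  s_long <- random_toy_session(40, seed = 3)
  dm <- build_design_matrix(list(s_short, s_long), 0)
  expect_identical(nrow(dm$X), 34L)
  # pooled sessions stack row blocks per session
  dm2 <- build_design_matrix(list(s_long, s_long), 0)
  expect_identical(nrow(dm2$X), 68L)
  expect_identical(dm2$X[1:34, ], dm2$X[35:68, ])
})

test_that("design matrix equals the brute-force oracle on random sessions", {
  for (seed in 1:25) {
    s <- random_toy_session(sample(20:60, 1), seed = seed)
    for (target in 0:2) {
      dm <- build_design_matrix(s, target)
      orc <- oracle_design_matrix(s, target)
      expect_identical(unname(dm$X), unname(orc$X))
      expect_identical(dm$y, orc$y)
    }
  }
})

test_that("the logistic fit recovers planted weights with nominal-like coverage", {
  set.seed(11)
  n <- 20000
  truth <- rnorm(36, 0, 0.3)
  X <- matrix(sample(c(-1L, 0L, 1L), n * 36, replace = TRUE,
                     prob = c(0.25, 0.5, 0.25)), n, 36)
  colnames(X) <- kernel_design_colnames <- sprintf(
    "c%d_o%d", rep(1:6, each = 6), rep(1:6, 6))
  eta <- -0.2 + X %*% truth
  y <- rbinom(n, 1, plogis(eta))
  dm <- structure(list(X = X, y = y,
                       column_map = data.frame(
                         choice_lag = rep(1:6, each = 6),
                         outcome_lag = rep(1:6, 6),
                         role = "interest", name = colnames(X)),
                       target = 0L),
                  class = "kernel_design")
  fit <- fit_stimulus_regression(dm)
  expect_false(fit$separation)
  se <- sqrt(diag(fit$cov))
  covered <- abs(fit$beta - truth) <= 1.96 * se
  expect_gte(mean(covered), 0.85)
  expect_gt(cor(fit$beta, truth), 0.95)
})

test_that("an all-zero design yields zero slopes and the marginal intercept", {
  s <- random_toy_session(50, seed = 4)
  s$trials$reward[] <- 0L  # no rewards -> every EV is 0
  dm <- build_design_matrix(s, 1)
  expect_true(all(dm$X == 0))
  fit <- fit_stimulus_regression(dm)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, qlogis(mean(dm$y)), tolerance = 1e-8)
  expect_identical(length(fit$dropped), 36L)
})

test_that("duplicating every row halves the model-based covariance", {
  sch <- generate_varying_schedule("stable", seed = 6)
  sess <- lapply(1:4, function(k) {
    play_session(sch, rw_agent(agent_params()), seed = 600 + k)
  })
  dm <- build_design_matrix(sess, 0)
  fit1 <- fit_stimulus_regression(dm)
  dm2 <- dm
  dm2$X <- rbind(dm$X, dm$X)
  dm2$y <- c(dm$y, dm$y)
  fit2 <- fit_stimulus_regression(dm2)
  expect_false(fit1$separation)
  expect_false(fit2$separation)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-6)
  expect_equal(fit2$cov, fit1$cov / 2, tolerance = 1e-4)
})

test_that("combine_weights implements the inverse-covariance-weighted mean", {
  # scalar inverse-variance case by hand
  comb <- combine_weights(list(1, 1, 4), list(1, 1, 0.5))
  expect_equal(as.numeric(comb), 2.5)
  # equal covariances reduce to the arithmetic mean
  set.seed(7)
  b <- lapply(1:3, function(i) rnorm(36))
  S <- crossprod(matrix(rnorm(36 * 40), 40, 36)) / 40 + diag(0.1, 36)
  comb <- combine_weights(b, list(S, S, S))
  expect_equal(as.numeric(comb), as.numeric((b[[1]] + b[[2]] + b[[3]]) / 3),
               tolerance = 1e-12)
  # an (effectively) infinite variance removes that stimulus's contribution
  comb3 <- combine_weights(list(1, 1, 100), list(1, 1, 1e12))
  expect_equal(as.numeric(comb3), 1, tolerance = 1e-6)
  expect_error(combine_weights(list(1, 1), list(1, 1, 1)), "equal length")
  expect_error(combine_weights(list(rep(1, 3), rep(1, 2), rep(1, 3)),
                               list(diag(3), diag(3), diag(3))),
               "dimension mismatch")
})

test_that("the interest grid partitions into 5 contingent and 10+10 spread cells", {
  ident <- diag(5)
  part <- partition_kernel(ident)
  expect_equal(part$contingent, rep(1, 5))
  expect_equal(part$choice_spread_cells, rep(0, 10))
  expect_equal(part$outcome_spread_cells, rep(0, 10))
  ones <- matrix(1, 5, 5)
  p1 <- partition_kernel(ones)
  expect_equal(p1$contingent_mean, 1)
  expect_equal(p1$choice_spread_mean, 1)
  expect_equal(p1$outcome_spread_mean, 1)
  expect_length(p1$choice_spread_cells, 10)
  expect_length(p1$outcome_spread_cells, 10)
  # by-lag means average the off-diagonal triangle cells of that lag
  g <- matrix(seq_len(25), 5, 5)
  p <- partition_kernel(g)
  expect_equal(p$choice_spread_by_lag[1], mean(g[1, 2:5]))
  expect_equal(p$outcome_spread_by_lag[2], mean(g[3:5, 2]))
  expect_true(is.na(p$choice_spread_by_lag[5]))
})

test_that("the recency contrast summarises the last outcome's interaction row", {
  g <- matrix(0, 5, 5)
  g[, 1] <- c(4, 2, 0, 1, 1)
  expect_equal(recency_contrast(g, "with_n1"),
               c(recent = 3, distant = 1))
  expect_equal(recency_contrast(g, "noncontingent_only"),
               c(recent = 1, distant = 1))
  gs <- matrix(0, 5, 5); gs[, 1] <- c(2, 1, 0, 1, 2)
  rc <- recency_contrast(gs, "with_n1")
  expect_equal(unname(rc["recent"]), unname(rc["distant"]))
})

test_that("grid extraction maps combined weights back to (choice lag, outcome lag)", {
  beta <- seq_len(36)
  cm <- bandit3arm:::kernel_column_map()
  names(beta) <- cm$name
  g <- kernel_grid(beta)
  expect_equal(g[2, 3], beta[cm$name == "c2_o3"][[1]])
  expect_equal(dim(g), c(5L, 5L))
})
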