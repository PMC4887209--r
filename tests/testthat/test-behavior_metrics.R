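# Switch/stay, choice-history (A_kB), choice-frequency, criterion,
# performance, latency and early/late analyses.

test_that("switch probabilities come from simple transition counts", {
  s <- toy_session(c(0L, 0L, 1L, 2L), rewards = c(1L, 1L, 1L, 0L))
  tab <- switch_stay_table(s)
  expect_equal(sum(tab$n_switch) / sum(tab$n), 2 / 3)

  stay <- toy_session(rep(1L, 30), rewards = rep(c(0L, 1L), 15))
  tab <- switch_stay_table(stay)
  expect_true(all(tab$p_switch == 0))
  expect_setequal(tab$prev_outcome, c("reward", "no_reward"))

  set.seed(8)
  big <- toy_session(sample(0:2, 6000, replace = TRUE),
                     rewards = rbinom(6000, 1, 0.5))
  tab <- switch_stay_table(big)
  expect_equal(sum(tab$n_switch) / sum(tab$n), 2 / 3, tolerance = 0.03)
})

test_that("switch/stay splits at the reversal and matches the oracle scanner", {
  for (seed in 1:20) {
    s <- random_toy_session(sample(c(20, 150, 300), 1), seed = 100 + seed)
    if (seed %% 2 == 0) s$schedule$reversal_trial <- 150L
    split <- !is.na(s$schedule$reversal_trial)
    got <- switch_stay_table(s, split_reversal = split)
    orc <- oracle_switch_table(s, split_reversal = split)
    agg <- stats::aggregate(switch ~ segment + prev_outcome, orc, FUN = mean)
    m <- merge(got, agg, by = c("segment", "prev_outcome"))
    expect_equal(m$p_switch, m$switch)
    expect_equal(sum(got$n), nrow(s$trials) - 1L)
  }
})

test_that("A_kB events follow the run-history definition", {
  # three A choices then rewarded B: one event in bin 3
  s <- toy_session(c(2L, 0L, 0L, 0L, 1L, 2L),
                   rewards = c(0L, 0L, 0L, 0L, 1L, 0L))
  tab <- akb_table(s)
  r3 <- tab[tab$condition == "3", ]
  expect_identical(nrow(r3), 1L)
  expect_identical(r3$prior_outcome, "reward")
  expect_equal(r3$n_events, 1L)
  expect_equal(r3$p_next_C, 1)  # moved to the third stimulus
  expect_equal(tab$p_next_B + tab$p_next_A + tab$p_next_C, rep(1, nrow(tab)))

  # five A choices then B: pooled into "4-7"
  s2 <- toy_session(c(0L, 0L, 0L, 0L, 0L, 1L, 1L))
  expect_identical(akb_table(s2)$condition, "4-7")

  # mixed-identity history (..., C, A, C, B) is not an A_kB condition: the
  # only rewarded candidate trial is the excluded one, so no reward row
  # appears
  s3 <- toy_session(c(2L, 2L, 0L, 2L, 1L, 1L),
                    rewards = c(0L, 0L, 0L, 0L, 1L, 0L))
  tab3 <- akb_table(s3)
  expect_false("reward" %in% tab3$prior_outcome)
  expect_equal(sum(tab3$n_events), 2L)
})

test_that("A_kB and choice-frequency tables match brute-force scanners", {
  for (seed in 1:30) {
    s <- random_toy_session(sample(25:80, 1), seed = 200 + seed)
    orc <- oracle_akb_events(s)
    if (nrow(orc)) {
      got <- akb_table(s)
      ref <- aggregate_binary(transform(orc, hit = as.integer(nxt == "B")),
                              "hit")
      m <- merge(got, ref, by = c("condition", "prior_outcome"))
      expect_identical(nrow(m), nrow(got))
      expect_equal(m$n_events, m$n)
      expect_equal(m$p_next_B, m$p)
    }
    gotf <- choice_frequency_table(s)
    reff <- aggregate_binary(oracle_freq_events(s), "rep")
    mf <- merge(gotf, reff, by = c("condition", "prior_outcome"))
    expect_identical(nrow(mf), nrow(gotf))
    expect_equal(mf$n_events, mf$n)
    expect_equal(mf$p_repeat, mf$p)
  }
})

test_that("choice-frequency counts span 0-5 and reflect win-stay structure", {
  # B at n-1 and at all of n-2..n-6 -> count 5; B only at n-1 -> count 0
  s <- toy_session(c(1L, 1L, 1L, 1L, 1L, 1L, 1L))
  expect_identical(choice_frequency_table(s)$condition, 5L)
  s0 <- toy_session(c(0L, 0L, 0L, 0L, 0L, 1L, 2L))
  expect_identical(choice_frequency_table(s0)$condition, 0L)

  winstay <- matrix(0, 5, 5); winstay[1, 1] <- 3
  sch <- generate_varying_schedule("stable", seed = 9)
  sess <- lapply(1:6, function(k) {
    play_session(sch, kernel_agent(planted_kernel(winstay)), seed = 900 + k)
  })
  tab <- choice_frequency_table(sess)
  for (cnt in unique(tab$condition)) {
    pr <- tab$p_repeat[tab$condition == cnt & tab$prior_outcome == "reward"]
    pn <- tab$p_repeat[tab$condition == cnt & tab$prior_outcome == "no_reward"]
    if (length(pr) && length(pn)) expect_gt(pr, pn)
  }
})

test_that("the learning criterion uses a trailing inclusive window", {
  lab <- rep(0L, 150)
  all_v1 <- toy_session(rep(0L, 150))
  res <- trials_to_criterion(all_v1, labels = lab)
  expect_identical(res$per_session$criterion_trial, 20L)

  none <- toy_session(rep(1L, 150))
  res <- trials_to_criterion(none, labels = lab)
  expect_false(res$per_session$reached)
  expect_true(is.na(res$per_session$criterion_trial))

  # exactly 13/20 = 0.65 in the first window meets the inclusive threshold
  ch <- c(rep(0L, 13), rep(1L, 7), rep(2L, 130))
  res <- trials_to_criterion(toy_session(ch), labels = lab)
  expect_identical(res$per_session$criterion_trial, 20L)

  # post-reversal counting restarts at the reversal
  s <- toy_session(c(rep(1L, 150), rep(0L, 150)))
  s$schedule$reversal_trial <- 150L
  res <- trials_to_criterion(s, labels = rep(0L, 300),
                             segment = "post_reversal")
  expect_identical(res$per_session$criterion_trial, 20L)

  # segment shorter than the window can never reach criterion
  short <- toy_session(rep(0L, 10))
  res <- trials_to_criterion(short, labels = rep(0L, 10))
  expect_false(res$per_session$reached)
})

test_that("best-option summaries split at the reversal", {
  lab <- c(rep(0L, 150), rep(1L, 150))
  s <- toy_session(c(rep(0L, 150), rep(2L, 150)))
  s$schedule$reversal_trial <- 150L
  out <- v1_choice_summary(s, labels = lab, reversal_window = 50)
  expect_equal(out$p_v1, 0.5)
  expect_equal(out$p_v1_first_half, 1)
  expect_equal(out$p_v1_second_half, 0)
  expect_equal(out$p_exv1_post, 0)  # never went back to the ex-best option

  persev <- toy_session(rep(0L, 300))
  persev$schedule$reversal_trial <- 150L
  out <- v1_choice_summary(persev, labels = lab, reversal_window = 50)
  expect_equal(out$p_exv1_post, 1)

  set.seed(10)
  rand <- toy_session(sample(0:2, 3000, replace = TRUE))
  out <- v1_choice_summary(rand, labels = rep(0L, 3000), halves = FALSE)
  expect_equal(out$p_v1, 1 / 3, tolerance = 0.03)
})

test_that("latency summaries log-transform and bin at 100 ms", {
  s <- toy_session(c(0L, 0L, 1L), latencies = c(100, 100, 100))
  out <- latency_summary(s)
  expect_equal(out$by_subject$mean_log_latency.stay, log(100))
  expect_equal(out$by_subject$mean_log_latency.switch, log(100))

  s2 <- toy_session(c(0L, 1L, 1L), latencies = c(999, 50, 150))
  h <- latency_summary(s2)$histogram
  expect_equal(h$count[h$bin_lo == 0], 1L)
  expect_equal(h$count[h$bin_lo == 100], 1L)
  expect_equal(sum(h$count), 2L)  # first trial excluded (no predecessor)

  s3 <- toy_session(c(0L, 1L, 2L), latencies = c(400, NA, 500))
  out3 <- latency_summary(s3)
  expect_identical(out3$n_dropped, 1L)
})

test_that("fixed-schedule sessions classify by inclusive early thresholds", {
  lab <- rep(0L, 150)
  mk <- function(n_early, late_all = TRUE, group = "control", id = "x") {
    ch <- c(rep(0L, n_early), rep(1L, 20 - n_early),
            rep(if (late_all) 0L else 1L, 130))
    toy_session(ch, subject_id = id, group = group, kind = "fixed1")
  }
  res <- fixed_early_late(list(mk(5), mk(16), mk(10)), labels = lab)
  expect_identical(res$per_session$class,
                   c("EARLY_LOW", "EARLY_HIGH", "neither"))
  expect_equal(res$per_session$p_v1_early, c(0.25, 0.8, 0.5))
  expect_equal(res$per_session$p_v1_late[2], 1.0)

  # group comparison runs a two-sample KS test when both groups contribute
  ctrl <- lapply(1:4, function(k) mk(4, TRUE, "control", paste0("c", k)))
  les <- lapply(1:4, function(k) mk(4, FALSE, "mdmc", paste0("m", k)))
  res2 <- fixed_early_late(c(ctrl, les), labels = lab)
  expect_true("EARLY_LOW" %in% names(res2$ks_tests))
  expect_s3_class(res2$ks_tests$EARLY_LOW, "htest")
  expect_error(fixed_early_late(toy_session(rep(0L, 30)), labels = rep(0L, 30)),
               "2\\*window")
})
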