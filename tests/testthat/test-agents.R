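# Synthetic agents: value learner, trace-attenuated (lesion) variant,
# planted-kernel agent, cohort simulation.

test_that("degenerate agent parameters produce the forced behaviours", {
  pol <- rw_agent(agent_params(alpha = 0, beta_sm = 5))
  p0 <- pol$action_probs()
  pol$update(0L, 1L); pol$update(0L, 1L)
  expect_equal(pol$action_probs(), p0)  # values frozen at alpha = 0

  pol <- rw_agent(agent_params(alpha = 0.5, beta_sm = 0))
  pol$update(0L, 1L); pol$update(0L, 1L)
  expect_equal(pol$action_probs(), rep(1 / 3, 3))  # beta = 0 ignores values
})

test_that("a value learner comes to prefer the best option on a fixed schedule", {
  f1 <- generate_fixed_schedule(1)
  lab <- v1_sch_labels(f1)
  hits <- vapply(1:100, function(seed) {
    s <- play_session(f1, rw_agent(agent_params(alpha = 0.3, beta_sm = 5)),
                      seed = seed)
    mean(s$trials$choice[131:150] == lab[131:150]) >= 0.65
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("trace attenuation of 1 reproduces the control agent exactly", {
  sch <- generate_varying_schedule("stable", seed = 4)
  a <- play_session(sch, rw_agent(agent_params()), seed = 77)
  b <- play_session(sch, lesion_agent(agent_params(trace_atten = 1)),
                    seed = 77)
  expect_identical(a$trials, b$trials)
})

test_that("full attenuation blocks credit to a just-switched-to option", {
  pol <- lesion_agent(agent_params(alpha = 0.5, beta_sm = 5,
                                   trace_atten = 0, trace_threshold = 3))
  for (i in 1:5) pol$update(1L, 1L)   # history on option 1 only
  before <- pol$action_probs()
  pol$update(0L, 1L)                  # switch to option 0, rewarded
  expect_equal(pol$action_probs(), before)  # no increment for option 0
  # but the frequently chosen option still updates at full strength
  pol2 <- lesion_agent(agent_params(alpha = 0.5, beta_sm = 5,
                                    trace_atten = 0, trace_threshold = 3))
  for (i in 1:5) pol2$update(1L, 1L)
  p_before <- pol2$action_probs()[2]
  pol2$update(1L, 0L)
  expect_false(isTRUE(all.equal(pol2$action_probs()[2], p_before)))
})

test_that("latency generator recovers the configured switch offset", {
  par <- agent_params(latency_base_ms = 400, latency_switch_add_ms = 150,
                      latency_sigma = 0.3)
  sch <- generate_varying_schedule("stable", seed = 5)
  sess <- lapply(1:10, function(k) {
    play_session(sch, rw_agent(par), seed = 200 + k)
  })
  lat <- latency_summary(sess)$by_subject
  gap <- lat$mean_log_latency.switch - lat$mean_log_latency.stay
  expect_equal(gap, log(550 / 400), tolerance = 0.05)

  par0 <- agent_params(latency_base_ms = 300, latency_switch_add_ms = 0,
                       latency_sigma = 0.3)
  sess0 <- lapply(1:10, function(k) {
    play_session(sch, rw_agent(par0), seed = 300 + k)
  })
  lat0 <- latency_summary(sess0)$by_subject
  gap0 <- lat0$mean_log_latency.switch - lat0$mean_log_latency.stay
  expect_lt(abs(gap0), 0.05)
})

test_that("the planted-kernel agent behaves as its weights dictate", {
  zero <- planted_kernel(matrix(0, 5, 5))
  pol <- kernel_agent(zero)
  expect_equal(pol$action_probs(), rep(1 / 3, 3))  # warm-up
  for (i in 1:10) pol$update(sample(0:2, 1), rbinom(1, 1, 0.5))
  expect_equal(pol$action_probs(), rep(1 / 3, 3))  # zero kernel stays uniform

  winstay <- matrix(0, 5, 5); winstay[1, 1] <- 8
  pol <- kernel_agent(planted_kernel(winstay))
  for (i in 1:6) pol$update(1L, 0L)
  pol$update(2L, 1L)   # last choice option 2, rewarded
  p <- pol$action_probs()
  expect_gt(p[3], 0.99)  # near-deterministic win-stay in the large-weight limit
})

test_that("cohort simulation emulates the study design deterministically", {
  cfg <- cohort_config(n_control = 7, n_lesion = 3, n_sessions = 5,
                       schedule_kinds = c("stable", "variable"),
                       phases = c("pre", "post"), seed = 1)
  expect_error(cohort_config(subject_ids = c("A", "A"), n_control = 1,
                             n_lesion = 1), "duplicate")

  small <- cohort_config(n_control = 1, n_lesion = 0, n_sessions = 1,
                         schedule_kinds = "stable", phases = "pre", seed = 2)
  one <- simulate_cohort(small)
  expect_length(one, 1)
  expect_identical(one[[1]]$group, "control")

  two_a <- simulate_cohort(small)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_sessions(one, f1); write_sessions(two_a, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical reruns
})

test_that("comparable sessions share one predetermined schedule across subjects", {
  cfg <- cohort_config(n_control = 2, n_lesion = 1, n_sessions = 1,
                       schedule_kinds = "stable", phases = "pre", seed = 3)
  ses <- simulate_cohort(cfg)
  expect_length(ses, 3)
  expect_identical(ses[[1]]$schedule$probs, ses[[2]]$schedule$probs)
  expect_identical(ses[[1]]$schedule$probs, ses[[3]]$schedule$probs)
  # but different subjects behave differently (independent seeds)
  expect_false(identical(ses[[1]]$trials$choice, ses[[2]]$trials$choice))
})
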