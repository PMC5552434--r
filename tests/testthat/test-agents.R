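test_that("trial records are internally consistent", {
  rec <- small_monkey_cohort()
  expect_true(all(rec$chosen == rec$item_lo | rec$chosen == rec$item_hi))
  expect_identical(rec$correct, as.integer(rec$chosen == rec$item_lo))
  expect_true(all(rec$rt_seconds > 0))
})

test_that("zero inverse temperature gives chance-level choice", {
  s <- build_schedule(species_profile("human"), seed = 5)
  rec <- simulate_associative(s, associative_config(beta = 0), seed = 6)
  # 380 fair coin flips: mean within 4 binomial sds of 0.5
  expect_lt(abs(mean(rec$correct) - 0.5), 4 * 0.5 / sqrt(nrow(rec)))
})

test_that("infinite position noise gives chance-level choice", {
  s <- build_schedule(species_profile("human"), seed = 5)
  cfg <- representational_config(position_noise = 1e6, learn_rate = 0.3)
  rec <- simulate_representational(s, cfg, seed = 6)
  expect_lt(abs(mean(rec$correct) - 0.5), 4 * 0.5 / sqrt(nrow(rec)))
})

test_that("massed training biases the associative agent toward the massed item", {
  prof <- species_profile("monkey")
  outcomes <- vapply(1:150, function(i) {
    s <- truncated_schedule(prof, seed = 9000 + i)
    rec <- simulate_associative(s, associative_config(alpha = 0.2, beta = 5,
                                                      theta = 0),
                                seed = 100 + i)
    first_xf_correct(rec)
  }, 1L)
  # picking the novel item over F is the *correct* choice; the associative
  # agent should do it on fewer than half of first encounters
  expect_lt(mean(outcomes, na.rm = TRUE), 0.5)
})

test_that("the massed prior makes the representational agent avoid the massed item", {
  prof <- species_profile("monkey")
  cfg <- default_agent_config("monkey")
  outcomes <- vapply(1:150, function(i) {
    s <- truncated_schedule(prof, seed = 9000 + i)
    first_xf_correct(simulate_representational(s, cfg, seed = 100 + i))
  }, 1L)
  expect_gt(mean(outcomes, na.rm = TRUE), 0.5)
})

test_that("the naive fast learner reverses its massed-item preference quickly", {
  tr <- transition_profile(small_human_cohort())
  xf <- tr[tr$segment == "xf", ]
  expect_lt(xf$accuracy[xf$presentation == 1], 0.5)   # initial F preference
  expect_gt(xf$accuracy[xf$presentation == 4], 0.5)   # reversed by 4th
})

test_that("representational cohorts show a monotone distance effect in phase 3", {
  rec <- small_monkey_cohort()
  p3 <- rec[rec$phase == 3 & rec$distance <= 5, ]
  acc <- tapply(p3$correct, p3$distance, mean)
  expect_gt(cor(as.numeric(names(acc)), acc, method = "spearman"), 0)
})

test_that("log-RT means follow the configured linear predictor", {
  # large-n check against the generating model
  base <- data.frame(distance = rep(c(1, 5), each = 10000),
                     trial_index = rep(1:100, 200))
  cfg <- rt_config(mu0 = -1, distance_slope = -0.05, practice_slope = 1e-3,
                   sigma = 0.3)
  out <- simulate_rt(base, cfg, seed = 99)
  pred <- cfg$mu0 + cfg$distance_slope * base$distance +
    cfg$practice_slope * base$trial_index
  res <- log(out$rt_seconds) - pred
  expect_lt(abs(mean(res)), 0.02)
  expect_lt(abs(sd(res) - cfg$sigma), 0.02)
  m <- tapply(log(out$rt_seconds), base$distance, mean)
  expect_lt(m[["5"]], m[["1"]])
})

test_that("median RT matches the species back-transforms", {
  base <- data.frame(distance = 1, trial_index = 1)[rep(1, 2001), ]
  fast <- simulate_rt(base, rt_config(mu0 = -1.35, sigma = 1e-6), seed = 1)
  slow <- simulate_rt(base, rt_config(mu0 = 0.5, sigma = 1e-6), seed = 1)
  expect_equal(round(median(fast$rt_seconds), 2), 0.26)
  expect_equal(round(median(slow$rt_seconds), 2), 1.65)
})

test_that("cohorts have the expected size and are seed-deterministic", {
  prof <- species_profile("human")
  cfg <- default_agent_config("human")
  a <- generate_cohort(prof, cfg, rt_config(species = "human"),
                       n_subjects = 2, seed = 77)
  b <- generate_cohort(prof, cfg, rt_config(species = "human"),
                       n_subjects = 2, seed = 77)
  expect_equal(nrow(a), 2L * 380L)
  expect_identical(a, b)
  expect_error(generate_cohort(prof, cfg, n_subjects = 0, seed = 1),
               "n_subjects")
  m <- species_profile("monkey", sessions_per_subject = 2)
  d <- generate_cohort(m, cfg, rt_cfg = NULL, n_subjects = 3, seed = 5)
  expect_equal(nrow(d), 3L * 2L * 760L)
})

test_that("agent and RT configs validate their parameters", {
  expect_error(associative_config(alpha = 0), "alpha")
  expect_error(associative_config(theta = 2), "theta")
  expect_error(representational_config(position_noise = -1))
  expect_error(rt_config(sigma = 0), "sigma")
})

test_that("parametric simulation hits its target probabilities", {
  s <- build_schedule(species_profile("human"), seed = 2)
  cfg <- parametric_config(function(sched)
    ifelse(sched$phase == 3, 0.9, 0.4))
  recs <- do.call(rbind, lapply(1:30, function(i)
    simulate_parametric(s, cfg, seed = i)))
  expect_lt(abs(mean(recs$correct[recs$phase == 3]) - 0.9), 0.02)
  expect_lt(abs(mean(recs$correct[recs$phase != 3]) - 0.4), 0.03)
  d <- simulate_binomial_curve(50, 200, -1, 0.1, seed = 4)
  expect_true(all(d$k >= 0 & d$k <= d$m))
  # by trial 50 the curve is near saturation
  expect_gt(mean(d$k[40:50] / d$m[40:50]), 0.9)
})
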