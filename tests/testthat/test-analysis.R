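test_that("binomial aggregation counts sessions per trial index", {
  rec <- data.frame(subject = 1, session = c(1, 2, 1, 2), trial_index = c(41, 41, 42, 42),
                    phase = 2, item_lo = "E", item_hi = "F",
                    chosen = c("E", "E", "E", "F"),
                    correct = c(1L, 1L, 1L, 0L), rt_seconds = 0.3,
                    distance = 1, joint_rank = 11, pair = "EF")
  s <- aggregate_counts(rec, "EF", 2)
  expect_equal(s$trial_index, c(41L, 42L))
  expect_equal(s$k, c(2L, 1L))
  expect_equal(s$m, c(2L, 2L))
  # order invariance
  s2 <- aggregate_counts(rec[sample(4), ], "EF", 2)
  expect_equal(s, s2)
  # empty selection is an explicit zero-row series
  expect_equal(nrow(aggregate_counts(rec, "AB", 2)), 0L)
})

test_that("massed-phase totals equal the session count at each index", {
  rec <- small_monkey_cohort()
  s <- aggregate_counts(rec, "FG", 1)
  n_sessions <- nrow(unique(rec[, c("subject", "session")]))
  expect_equal(nrow(s), 40L)  # one massed trial per index
  expect_true(all(s$m == n_sessions))
  expect_equal(sum(s$m), sum(rec$phase == 1))
})

test_that("massed-pair accuracy rises in phase 1 then steps down at phase 2", {
  rec <- small_monkey_cohort()
  c1 <- accuracy_timeseries(rec, "FG", 1, optimize = FALSE)
  expect_s3_class(c1, "tigp_curve")
  expect_equal(c1$trial_index, 1:40)
  expect_gt(c1$mean[40], c1$mean[1])      # learning across the massed block
  c2 <- accuracy_timeseries(rec, "FG", 2, optimize = FALSE)
  expect_lt(c2$mean[1], c1$mean[40])      # step drop at the boundary
  expect_error(accuracy_timeseries(rec, "AB", 1), "empty series")
})

test_that("a chance-level cohort is recovered as flat at one half", {
  rec <- constant_p_cohort(p = 0.5)
  cu <- accuracy_timeseries(rec, "FG", 2, optimize = FALSE)
  expect_true(all(abs(cu$mean - 0.5) < 0.15))
  expect_true(all(cu$lo99 < 0.5 & cu$hi99 > 0.5))
})

test_that("duplicating every session narrows the bands but keeps the curve", {
  rec <- small_monkey_cohort()
  dup <- rec
  dup$session <- dup$session + 1000L
  both <- rbind(rec, dup)
  p <- kernel_params(1, 10)
  c1 <- accuracy_timeseries(rec, "FG", 1, optimize = FALSE, params = p)
  c2 <- accuracy_timeseries(both, "FG", 1, optimize = FALSE, params = p)
  expect_equal(c2$mean, c1$mean, tolerance = 0.05)
  expect_true(all(c2$hi99 - c2$lo99 < c1$hi99 - c1$lo99))
})

test_that("log-RT series recover constant, trending and baseline structure", {
  rec <- small_monkey_cohort()
  # constant RT: flat curve at its log
  flat <- rec
  flat$rt_seconds <- 0.26
  cf <- rt_timeseries(flat, "FG", 1, optimize = FALSE)
  expect_true(all(abs(cf$mean - log(0.26)) < 1e-6))
  # monkey-like generator: fitted grand mean near the configured baseline
  cm <- rt_timeseries(rec, "FG", 1, optimize = FALSE)
  expect_lt(abs(mean(cm$mean) - (-1.35)), 0.05)
  # human-like practice trend: later trials faster
  h <- small_human_cohort()
  ch <- rt_timeseries(h, "FG", 2, optimize = FALSE)
  expect_lt(ch$mean[nrow(ch)], ch$mean[1])
  bad <- rec
  bad$rt_seconds[3] <- -1
  expect_error(rt_timeseries(bad, "FG", 1), "positive")
})

test_that("transition profile applies a uniform Beta prior to pooled counts", {
  rec <- constant_p_cohort(p = 1, n_sessions = 5)  # all-correct toy data
  tr <- transition_profile(rec)
  expect_true(all(tr$accuracy == (tr$m + 1) / (tr$m + 2)))
  expect_true(all(tr$k == tr$m))
  segs <- unique(tr$segment)
  expect_setequal(segs, c("fg_phase1", "fg", "xf", "xg"))
  expect_equal(max(tr$presentation[tr$segment == "fg_phase1"]), 4L)
  expect_equal(max(tr$presentation[tr$segment == "xf"]), 6L)
  # intervals nested
  expect_true(all(tr$acc_lo99 <= tr$acc_lo80 & tr$acc_hi80 <= tr$acc_hi99))
})

test_that("choice-of-massed-item and accuracy are complementary off the massed pair", {
  tr <- transition_profile(small_monkey_cohort())
  xf <- tr[tr$segment == "xf", ]
  # chose-F count is m - k, so under Beta(1,1) the means are complementary
  expect_equal(xf$choice, 1 - xf$accuracy, tolerance = 1e-12)
  fg <- tr[tr$segment == "fg", ]
  expect_equal(fg$choice, fg$accuracy)  # choosing F *is* correct for FG
})

test_that("truncated transition profiles are reported and flagged", {
  rec <- constant_p_cohort(p = 0.8, n_sessions = 3)
  # keep only the first two phase-2 massed-pair instances per session
  drop <- unlist(lapply(split(seq_len(nrow(rec)),
                              paste(rec$subject, rec$session)),
                        function(ix) {
    r <- rec[ix, ]
    fg2 <- which(r$phase == 2 & r$pair == "FG")
    ix[fg2[order(r$trial_index[fg2])][-(1:2)]]
  }))
  rec2 <- rec[-drop, ]
  expect_warning(tr <- transition_profile(rec2), "reporting what exists")
  expect_true(attr(tr, "truncated"))
  expect_lte(max(tr$presentation[tr$segment == "fg"]), 2L)
})

test_that("learning rates are zero for static cohorts and sorted canonically", {
  rec <- constant_p_cohort(p = 0.6, n_sessions = 10)
  lr <- learning_rates(rec, 2, optimize = FALSE)
  expect_true(all(lr$lo99 < 0 & lr$hi99 > 0))
  ord <- order(lr$distance, lr$joint_rank)
  expect_equal(ord, seq_len(nrow(lr)))
  expect_equal(nrow(lr), 15L)
  expect_error(learning_rates(rec, 1), "phase 2 or 3")
})

test_that("a ten-fold learning-speed difference is recovered within two-fold", {
  prof <- species_profile("human")
  slope_cohort <- function(b, seed) {
    cfg <- parametric_config(function(s) {
      t2 <- pmax(s$trial_index - 20, 0)
      ifelse(s$phase == 2, plogis(-0.5 + b * t2), 0.6)
    })
    generate_cohort(prof, cfg, rt_cfg = NULL, n_subjects = 60, seed = seed)
  }
  # shared smoothing scale: edge shrinkage then cancels in the ratio
  p <- kernel_params(1, 130)
  slow <- learning_rates(slope_cohort(0.005, 51), 2, optimize = FALSE,
                         params = p)
  fast <- learning_rates(slope_cohort(0.050, 52), 2, optimize = FALSE,
                         params = p)
  ratio <- mean(fast$rate) / mean(slow$rate)
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("effect statistics handle flat and monotone tables", {
  flat <- data.frame(distance = 1:5, mean = rep(0.7, 5))
  expect_equal(effect_stats(flat)$estimate[1], 0)
  mono <- data.frame(distance = 1:5, mean = c(0.5, 0.6, 0.7, 0.8, 0.9))
  expect_equal(effect_stats(mono)$estimate[1], 1)
  expect_error(effect_stats(data.frame(distance = c(1, 1, 2),
                                       mean = c(0, 0, 1))),
               "undefined trend")
})
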