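test_that("all_pairs enumerates every unordered pair with coordinates", {
  expect_equal(nrow(all_pairs(7)), 21L)
  expect_equal(nrow(all_pairs(5)), 10L)
  expect_equal(nrow(all_pairs(2)), 1L)
  expect_error(all_pairs(1), "invalid design")
  p <- all_pairs(7)
  expect_true(all(p$distance >= 1 & p$distance <= 6))
  expect_true(all(p$joint_rank >= 3 & p$joint_rank <= 13))
})

test_that("pair coordinates match the worked examples and error on bad pairs", {
  expect_equal(unname(pair_coordinates("BD")), c(2, 6))
  expect_equal(unname(pair_coordinates("FG")[2]), 13)
  expect_equal(unname(pair_coordinates("AB")[2]), 3)
  expect_equal(unname(pair_coordinates(c("D", "B"))), c(2, 6))
  expect_error(pair_coordinates("BB"), "must differ")
  expect_error(pair_coordinates("BZ", n_items = 7), "unknown item")
})

test_that("the pair -> (distance, joint rank) map is a bijection with parity", {
  p <- all_pairs(7)
  key <- paste(p$distance, p$joint_rank)
  expect_equal(length(unique(key)), 21L)
  # same parity: distance and joint rank are both sums/differences of ranks
  expect_true(all((p$distance %% 2) == (p$joint_rank %% 2)))
  # joint rank varies at fixed distance (orthogonality):
  d1 <- p[p$distance == 1, ]
  expect_true(all(c(3, 13) %in% d1$joint_rank))
})

test_that("phase pair sets follow the massed design", {
  expect_equal(phase_pairs(1, 7)$pair, "FG")
  p2 <- phase_pairs(2, 7)
  expect_equal(nrow(p2), 15L)
  expect_true(all(p2$distance == 1 | p2$item_hi %in% c("F", "G")))
  expect_true(all(all_pairs(7)$pair[all_pairs(7)$distance == 1] %in% p2$pair))
  expect_equal(nrow(phase_pairs(3, 7)), 21L)
  expect_error(phase_pairs(4, 7), "unknown phase")
})

test_that("species profiles reproduce the printed session structure", {
  m <- species_profile("monkey")
  expect_equal(unname(m$phase_trials), c(40L, 300L, 420L))
  expect_equal(m$session_trials, 760L)
  h <- species_profile("human")
  expect_equal(unname(h$phase_trials), c(20L, 150L, 210L))
  expect_equal(h$session_trials, 380L)
  expect_equal(h$session_trials * 2L, m$session_trials)
})

test_that("schedules are phase-ordered permutations with exact counterbalance", {
  prof <- species_profile("monkey")
  s <- build_schedule(prof, seed = 42)
  expect_equal(nrow(s), 760L)
  expect_equal(s$trial_index, 1:760)
  expect_equal(as.integer(table(s$phase)), c(40L, 300L, 420L))
  # phase 2 starts at trial 41
  expect_equal(min(s$trial_index[s$phase == 2]), 41L)
  # multiset equality: every pair occurs exactly its presentation count
  for (ph in 1:3) {
    counts <- table(s$pair[s$phase == ph])
    expect_true(all(counts == prof$presentations[[ph]]))
    expect_equal(sort(names(counts)), sort(phase_pairs(ph)$pair))
  }
  # exact side counterbalance per pair per phase
  tab <- table(s$pair, s$correct_side, s$phase)
  expect_true(all(tab[, "left", ] == tab[, "right", ]))
})

test_that("seeds give reproducible schedules that permute the same multiset", {
  prof <- species_profile("human")
  s1 <- build_schedule(prof, seed = 7)
  s2 <- build_schedule(prof, seed = 7)
  s3 <- build_schedule(prof, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1$pair, s3$pair))
  for (ph in 1:3)
    expect_equal(sort(paste(s1$pair, s1$correct_side)[s1$phase == ph]),
                 sort(paste(s3$pair, s3$correct_side)[s3$phase == ph]))
})

test_that("odd presentation counts are rejected", {
  prof <- species_profile("monkey")
  prof$presentations[2] <- 21L
  expect_error(build_schedule(prof, seed = 1), "counterbalance")
})

test_that("schedules export to CSV with the documented columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  s <- build_schedule(species_profile("human"), seed = 3)
  write_schedule(s, f, session = 2L)
  d <- read.csv(f)
  expect_equal(names(d), c("session", "trial_index", "phase", "item_lo",
                           "item_hi", "distance", "joint_rank",
                           "correct_side"))
  expect_equal(nrow(d), 380L)
  expect_true(all(d$session == 2L))
})
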