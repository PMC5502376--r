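test_that("reciprocal-interval rate is 1000/ISI inside intervals and zero
           outside", {
  grid <- 0:20
  r <- reciprocal_interval_rate(c(0, 10), grid)
  expect_equal(r[grid > 0 & grid < 10], rep(100, 9))
  expect_equal(r[grid > 10], rep(0, 10))
  expect_equal(reciprocal_interval_rate(5, grid), rep(0, 21))  # single spike
  expect_equal(reciprocal_interval_rate(numeric(0), grid), rep(0, 21))
  expect_error(reciprocal_interval_rate(c(3, 3, 5), grid), "increasing")
})

test_that("regular spiking gives the count-based rate in interior windows", {
  spikes <- seq(0, 1000, by = 20)       # 50 spikes/s
  grid <- 0:1000
  r <- reciprocal_interval_rate(spikes, grid)
  inner <- grid >= 100 & grid <= 900
  expect_true(all(r[inner] == 50))
  expect_equal(mean(r[grid >= 200 & grid <= 350]), 50)
})

test_that("window mean uses the closed [-100, +50] interval and nothing
           later", {
  times <- 0:400
  expect_equal(window_mean(rep(7, 401), times, onset = 200), 7)
  step <- ifelse(times >= 200, 10, 0)
  expect_equal(window_mean(step, times, onset = 200), 10 * 51 / 151)
  # poisoning samples after +50 ms must not change the mean
  poisoned <- step
  poisoned[times > 250] <- 1e9
  expect_equal(window_mean(poisoned, times, onset = 200),
               window_mean(step, times, onset = 200))
  expect_error(window_mean(step, times, onset = 20), "window")
})

test_that("trial pairing slides, filters by direction, and conserves
           interior trials", {
  s_off <- quick_session("repeated", n_trials = 5, seed = 1)
  p <- pair_trials(s_off)
  expect_equal(nrow(p), 4)
  expect_equal(p$test_index, p$instruction_index + 1)
  s_alt <- quick_session("alternating", n_trials = 6, seed = 1)
  p_off <- pair_trials(s_alt, "off")
  expect_equal(p_off$instruction_index, c(1, 3))  # 0-based odd trials
  p_all <- pair_trials(s_alt, "both")
  counts <- table(c(p_all$instruction_index, p_all$test_index))
  interior <- as.character(1:4)
  expect_true(all(counts[interior] == 2))
  # all pairs carry the instruction trial's CS contingency
  s1 <- quick_session("repeated", n_trials = 30, seed = 2,
                      cs_probability = 1)
  expect_true(all(pair_trials(s1)$cs))
})

test_that("trial-over-trial change is test minus instruction with a
           window-mean scalar", {
  s <- quick_session("repeated", n_trials = 4, seed = 3)
  # identical eye traces differ by zero
  s$eye_velocity[2, ] <- s$eye_velocity[1, ]
  ch <- trial_over_trial_change(s, 0, what = "eye")
  expect_true(all(ch$difference == 0))
  expect_equal(ch$change, 0)
  # constant offset passes straight through
  s$eye_velocity[3, ] <- s$eye_velocity[2, ] + 3
  expect_equal(trial_over_trial_change(s, 1, what = "eye")$change, 3)
  # vectorized pair_changes agrees with the single-pair path
  pairs <- pair_trials(s, "both")
  pc <- pair_changes(s, pairs, what = "eye")
  expect_equal(pc$tot_change[1], 0)
  expect_equal(pc$tot_change[2], 3)
})

test_that("CS probability curves count trials with >= 1 CS per bin", {
  s0 <- quick_session("repeated", n_trials = 50, seed = 4,
                      cs_probability = 0)
  expect_true(all(cs_probability_curve(s0)$probability == 0))
  s1 <- quick_session("repeated", n_trials = 200, seed = 5,
                      cs_probability = 1)
  curve <- cs_probability_curve(s1)
  covering <- curve$bin_start < 175 & curve$bin_end > 75
  expect_equal(sum(curve$probability[covering]), 1)
  expect_true(all(curve$probability[!covering] == 0))
  # default session: the bins tiling the CS window sum to the generating
  # probability (each trial carries at most one CS)
  s <- quick_session("random", n_trials = 2000, seed = 6)
  cv <- cs_probability_curve(s)
  cover <- cv$bin_start < 175 & cv$bin_end > 75
  tot <- sum(cv$probability[cover])
  n_off <- sum(s$trials$direction == "off")
  expect_lt(abs(tot - 0.36), 3 * sqrt(0.36 * 0.64 / n_off))
})

test_that("CS-frequent classification is a strict 0.3 threshold", {
  expect_true(classify_cs_frequent(0.4))
  expect_false(classify_cs_frequent(0.3))
  expect_false(classify_cs_frequent(0))
  expect_error(classify_cs_frequent(1.2))
})

test_that("binning groups pairs in tens and drops the remainder", {
  pairs <- data.frame(cs = rep(c(TRUE, FALSE), 100),
                      cs_duration = rep(c(8, NA), 100),
                      tot_change = rep(2, 200))
  b <- bin_groups(pairs)
  expect_equal(nrow(b), 20)
  expect_true(all(b$n_pairs == 10))
  expect_true(all(b$mean_tot_change == 2))
  expect_true(all(b$cs_probability == 0.5))
  expect_true(all(b$mean_cs_duration == 8))
  b205 <- bin_groups(pairs[c(1:200, 1:5), ])
  expect_equal(nrow(b205), 20)          # remainder of 5 dropped
  # a bin with zero CSs has undefined duration
  nocs <- data.frame(cs = rep(FALSE, 10), cs_duration = NA_real_,
                     tot_change = 0)
  expect_true(is.na(bin_groups(nocs)$mean_cs_duration))
})

test_that("history-contingent CS probability is flat when CSs are
           history-independent", {
  s <- quick_session("random", n_trials = 8000, seed = 7)
  for (pat in c("repeated", "alternating")) {
    h <- history_contingent_cs_probability(s, pat)
    expect_equal(h$depth, 1:4)
    se <- sqrt(0.36 * 0.64 / h$n_trials)
    expect_true(all(abs(h$probability - 0.36) < 3.5 * se))
  }
  # depth-1 repeated equals the direct conditional estimate
  tr <- s$trials
  prev_off <- c(FALSE, tr$direction[-nrow(tr)] == "off")
  sel <- tr$direction == "off" & prev_off
  h1 <- history_contingent_cs_probability(s, "repeated", depths = 1)
  expect_equal(h1$probability, mean(tr$cs[sel]))
  expect_equal(h1$n_trials, sum(sel))
  # absent histories give NA, not zero
  s_small <- quick_session("random", n_trials = 3, seed = 8)
  h4 <- history_contingent_cs_probability(s_small, "repeated", depths = 4)
  expect_true(is.na(h4$probability))
})
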