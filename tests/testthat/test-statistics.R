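test_that("binned duration-probability correlation handles exact linearity
           and degenerate bins", {
  bins <- data.frame(cs_probability = seq(0.1, 0.5, by = 0.1),
                     mean_cs_duration = 2 * seq(0.1, 0.5, by = 0.1) + 7,
                     mean_tot_change = 0)
  expect_equal(binned_duration_probability_correlation(bins)$r, 1)
  bins$mean_cs_duration[c(1, 2, 4)] <- NA   # only 2 usable bins
  res <- binned_duration_probability_correlation(bins)
  expect_true(is.na(res$r))
  expect_equal(res$n, 2)
})

test_that("temporal correlation of consecutive CS durations matches its
           definition and error contract", {
  # strictly alternating long/short durations -> r = -1
  dur <- rep(c(10, 6), 20)
  res <- temporal_correlation_consecutive(dur)
  expect_equal(res$r, -1)
  expect_equal(res$n_pairs, 39)
  expect_length(res$control, 10)
  # constant durations: zero variance, flagged undefined
  expect_true(is.na(temporal_correlation_consecutive(rep(8, 40))$r))
  # fewer than 10 consecutive pairs: does not qualify
  sparse <- rep(NA_real_, 40); sparse[c(1, 5, 9, 13)] <- 8:11
  expect_true(is.na(temporal_correlation_consecutive(sparse)$r))
  # interleaved NAs only pair trials that both bear a CS
  d2 <- c(1, 2, NA, 3, 4, NA, 5, 6)
  expect_equal(temporal_correlation_consecutive(d2, min_pairs = 3)$n_pairs, 3)
})

test_that("shuffling consecutive durations destroys a strong temporal
           correlation", {
  m <- cs_model(duration_corr = 1, n_cells = 60, n_trials = 200)
  mean_tc <- function(dec, seed) {
    mm <- m; mm$temporal_decorrelation <- dec
    pop <- simulate(mm, seed = seed)
    r <- vapply(split(as.data.frame(pop), pop$cell), function(tr) {
      temporal_correlation_consecutive(ifelse(tr$cs, tr$d, NA),
                                       min_pairs = 3)$r
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }
  set.seed(71)
  r_sorted <- mean_tc(0, 100)
  r_shuffled <- mean_tc(0.8, 200)
  expect_gt(r_sorted, 0.5)              # sorted trials: strong correlation
  expect_lt(abs(r_shuffled), 0.15)      # 0.8 swaps/trial: near zero
  expect_gt(r_sorted - r_shuffled, 0.4)
})

test_that("partial correlations satisfy the regression-residual identity
           to 1e-10", {
  set.seed(81)
  for (case in 1:8) {
    n <- sample(6:20, 1)
    bins <- data.frame(mean_tot_change = rnorm(n),
                       cs_probability = runif(n),
                       mean_cs_duration = rnorm(n, 8))
    pr <- partial_correlations(bins)
    expect_equal(pr[["prob"]],
                 partial_cor_oracle(bins$mean_tot_change,
                                    bins$cs_probability,
                                    bins$mean_cs_duration),
                 tolerance = 1e-10)
    expect_equal(pr[["dur"]],
                 partial_cor_oracle(bins$mean_tot_change,
                                    bins$mean_cs_duration,
                                    bins$cs_probability),
                 tolerance = 1e-10)
  }
})

test_that("partial correlations separate a duration-driven effect from an
           independent probability", {
  set.seed(82)
  n <- 4000
  dur <- rnorm(n, 8, 1)
  prob <- runif(n)
  change <- -2 * dur + rnorm(n, 0, 2)
  bins <- data.frame(mean_tot_change = change, cs_probability = prob,
                     mean_cs_duration = dur)
  pr <- partial_correlations(bins)
  expect_lt(pr[["dur"]], -0.5)
  expect_lt(abs(pr[["prob"]]), 0.05)
  # change independent of both: both partials near zero
  bins$mean_tot_change <- rnorm(n)
  pr0 <- partial_correlations(bins)
  expect_lt(max(abs(pr0)), 0.05)
  # degenerate inputs are flagged
  bins$mean_cs_duration <- 8
  expect_true(all(is.na(partial_correlations(bins))))
  expect_true(all(is.na(partial_correlations(bins[1:3, ]))))
})

test_that("population partial-correlation cloud has negative means", {
  pop <- simulate(cs_model(n_cells = 200), seed = 83)
  pc <- population_partial_correlations(pop)
  s <- summary(pc)
  expect_gt(s$n_defined, 150)
  expect_lt(s$mean_prob, 0)
  expect_lt(s$mean_dur, 0)
})

test_that("the measured-correlation sweep exposes the underlying relation
           only at high temporal correlation", {
  m <- cs_model()
  sw <- sweep_measured_correlation(m, r_values = c(0, 0.5),
                                   temporal_corr_values = c(0, 1),
                                   replicates = 25, seed = 91)
  # no underlying relation: measured stays near zero everywhere
  expect_true(all(abs(sw$grid["0", ]) < 3 * sw$se["0", ] + 0.05))
  # r = 0.5: sorted trials reveal the relation, full shuffling hides it
  expect_gt(sw$grid["0.5", "1"], 0.25)
  expect_lt(abs(sw$grid["0.5", "0"]), 0.2)
  expect_gt(sw$grid["0.5", "1"] - sw$grid["0.5", "0"], 0.15)
})

test_that("the binned-correlation distributions at decorrelation 0.8 cannot
           separate underlying correlations 0.5 and 1", {
  percell <- function(r, seed) {
    pop <- simulate(cs_model(duration_corr = r, n_cells = 80), seed = seed)
    vapply(split(as.data.frame(pop), pop$cell), function(tr) {
      binned_duration_probability_correlation(model_bins(tr))$r
    }, numeric(1))
  }
  r1 <- percell(1, 101)
  r05 <- percell(0.5, 102)
  expect_lt(abs(mean(r1, na.rm = TRUE)), 0.15)   # concentrates near zero
  expect_lt(abs(mean(r05, na.rm = TRUE)), 0.15)
  # overlapping distributions: the difference in means is small relative
  # to the spread of either
  expect_lt(abs(mean(r1, na.rm = TRUE) - mean(r05, na.rm = TRUE)),
            sd(r1, na.rm = TRUE))
})

test_that("noise-corrupted curve correlations follow the closed-form
           attenuation", {
  set.seed(111)
  curve <- rnorm(20, 0, 1)
  expect_true(all(noise_corrupted_curve_correlation(curve, curve, 0,
                                                    reps = 5) == 1))
  # attenuation oracle: E[r] ~ sqrt(V / (V + noise)); choose the curve
  # variance so the expected r is 0.13 with noise variance 20
  V <- 20 * 0.13^2 / (1 - 0.13^2)
  curve13 <- as.numeric(scale(rnorm(20))) * sqrt(V)
  r <- noise_corrupted_curve_correlation(curve13, curve13, 20, reps = 4000)
  expect_lt(abs(mean(r) - 0.13), 3 * sd(r) / sqrt(length(r)) + 0.01)
  # infinite-noise limit: mean correlation vanishes
  r_inf <- noise_corrupted_curve_correlation(curve13, curve13, 1e8,
                                             reps = 2000)
  expect_lt(abs(mean(r_inf)), 0.03)
})

test_that("paired comparisons apply the Bonferroni cap and handle
           degenerate differences", {
  x <- rnorm(12)
  same <- paired_comparison(x, x)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)
  expect_equal(same$p_adjusted, 1)
  shifted <- paired_comparison(x + 2, x)
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_value, 0)
  set.seed(121)
  res <- paired_comparison(rnorm(30, 1), rnorm(30, 0), n_comparisons = 3)
  expect_false(res$degenerate)
  expect_equal(res$p_adjusted, min(1, res$p_value * 3))
  # agreement with the standard paired t test
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(paired_comparison(a, b)$p_value,
               t.test(a, b, paired = TRUE)$p.value)
})

test_that("the paired test holds its type-I error rate under the null", {
  set.seed(131)
  reps <- 4000
  hits <- 0L
  for (i in seq_len(reps)) {
    a <- rnorm(15); b <- rnorm(15)
    if (paired_comparison(a, b, n_comparisons = 1)$p_value < 0.05)
      hits <- hits + 1L
  }
  rate <- hits / reps
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("plasticity regression recovers generator constants from a
           modest session", {
  s <- quick_session("random", n_trials = 5000, seed = 141)
  est <- estimate_plasticity(s)
  expect_lt(abs(est$depression$estimate - 5.5), 3 * est$depression$se)
  expect_lt(abs(est$potentiation$estimate - 1.7), 3 * est$potentiation$se)
})
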