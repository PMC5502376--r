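#' Correlation between binned CS duration and CS probability
#'
#' Pearson (or Spearman) correlation, across 10-trial bins, between the CS
#' probability and the mean CS duration. Bins without any CS have no defined
#' duration and are excluded; at least 3 usable bins are required, otherwise
#' the result is flagged undefined (\code{r = NA}).
#'
#' @param bins Data.frame from \code{\link{bin_groups}} or
#'   \code{\link{model_bins}}.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Object of class \code{"cs_cor"}: list with \code{r}, \code{n}
#'   (usable bins) and \code{method}.
#' @export
binned_duration_probability_correlation <- function(bins,
                                                    method = c("pearson",
                                                               "spearman")) {
  method <- match.arg(method)
  use <- !is.na(bins$mean_cs_duration)
  n <- sum(use)
  r <- if (n < 3 ||
           stats::sd(bins$cs_probability[use]) == 0 ||
           stats::sd(bins$mean_cs_duration[use]) == 0) NA_real_
       else stats::cor(bins$cs_probability[use], bins$mean_cs_duration[use],
                       method = method)
  structure(list(r = r, n = n, method = method), class = "cs_cor")
}

#' @export
print.cs_cor <- function(x, ...) {
  if (is.na(x$r))
    cat(sprintf("correlation undefined (%d usable observations)\n", x$n))
  else
    cat(sprintf("r = %.4f (%s, n = %d)\n", x$r, x$method, x$n))
  invisible(x)
}

#' Temporal correlation of CS duration across consecutive trials
#'
#' Extracts all pairs of consecutive trials that both bear a CS and
#' correlates their durations. Cells qualify with more than 9 such pairs
#' (i.e. at least 10); otherwise the result is flagged undefined. A control
#' distribution is obtained by pairing the same number of randomly chosen CS
#' trials, repeated \code{n_control} times.
#'
#' @param durations Per-trial CS durations in trial order, \code{NA} on
#'   trials without a CS.
#' @param n_control Number of random-pair control repetitions (default 10).
#' @param min_pairs Minimum consecutive-CS pairs to qualify (default 10).
#' @return List of class \code{"cs_tempcor"}: \code{r}, \code{n_pairs},
#'   \code{control} (numeric vector of control correlations, length
#'   \code{n_control} when defined).
#' @export
temporal_correlation_consecutive <- function(durations, n_control = 10L,
                                             min_pairs = 10L) {
  has <- is.finite(durations)
  i <- which(has[-length(durations)] & has[-1])
  n_pairs <- length(i)
  if (n_pairs < min_pairs ||
      stats::sd(durations[i]) == 0 || stats::sd(durations[i + 1]) == 0) {
    return(structure(list(r = NA_real_, n_pairs = n_pairs,
                          control = numeric(0)), class = "cs_tempcor"))
  }
  r <- stats::cor(durations[i], durations[i + 1])
  cs_idx <- which(has)
  control <- vapply(seq_len(n_control), function(rep) {
    a <- sample(cs_idx, n_pairs, replace = TRUE)
    b <- sample(cs_idx, n_pairs, replace = TRUE)
    if (stats::sd(durations[a]) == 0 || stats::sd(durations[b]) == 0)
      return(NA_real_)
    stats::cor(durations[a], durations[b])
  }, numeric(1))
  structure(list(r = r, n_pairs = n_pairs, control = control),
            class = "cs_tempcor")
}

#' @export
print.cs_tempcor <- function(x, ...) {
  if (is.na(x$r))
    cat(sprintf("temporal correlation undefined (%d consecutive-CS pairs)\n",
                x$n_pairs))
  else
    cat(sprintf(
      "consecutive-CS duration r = %.4f (n = %d pairs); control mean %.4f\n",
      x$r, x$n_pairs, mean(x$control, na.rm = TRUE)))
  invisible(x)
}

#' First-order partial correlations of plasticity with CS properties
#'
#' Partial Pearson correlation, across bins, between the trial-over-trial
#' simple-spike change and each CS property (probability or duration) while
#' controlling for the other. Computed through the residualization identity
#' \deqn{r_{xy\cdot z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'       {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' rather than covariance-matrix inversion, for numerical transparency on
#' small numbers of bins. Bins without a defined mean CS duration are
#' excluded; at least 4 usable bins are required and a degenerate covariance
#' (zero variance or |r| = 1 between controls) yields NA.
#'
#' @param bins Data.frame with \code{mean_tot_change}, \code{cs_probability},
#'   \code{mean_cs_duration} (as from \code{\link{bin_groups}}).
#' @return Named numeric vector:
#'   \code{prob} = partial r(change, probability | duration),
#'   \code{dur} = partial r(change, duration | probability).
#' @export
partial_correlations <- function(bins) {
  use <- stats::complete.cases(bins[, c("mean_tot_change", "cs_probability",
                                        "mean_cs_duration")])
  x <- bins$mean_tot_change[use]
  p <- bins$cs_probability[use]
  d <- bins$mean_cs_duration[use]
  bad <- c(prob = NA_real_, dur = NA_real_)
  if (length(x) < 4) return(bad)
  if (stats::sd(x) == 0 || stats::sd(p) == 0 || stats::sd(d) == 0) return(bad)
  r_xp <- stats::cor(x, p); r_xd <- stats::cor(x, d); r_pd <- stats::cor(p, d)
  if (abs(r_pd) >= 1) return(bad)
  c(prob = (r_xp - r_xd * r_pd) / sqrt((1 - r_xd^2) * (1 - r_pd^2)),
    dur  = (r_xd - r_xp * r_pd) / sqrt((1 - r_xp^2) * (1 - r_pd^2)))
}

#' Per-cell partial correlations across a model population
#'
#' Bins every cell's trials in groups of \code{group_size} and computes, per
#' cell, the partial correlations of the trial-over-trial change with CS
#' probability and with CS duration (each controlling for the other).
#'
#' @param population A \code{"cs_population"} from
#'   \code{\link{simulate.cs_model}}.
#' @param group_size Trials per bin (default 10).
#' @return Data.frame of class \code{"cs_partials"}: \code{cell},
#'   \code{partial_prob}, \code{partial_dur} (NA where undefined).
#' @export
population_partial_correlations <- function(population, group_size = 10L) {
  cells <- split(as.data.frame(population), population$cell)
  res <- t(vapply(cells, function(tr) {
    partial_correlations(model_bins(tr, group_size))
  }, numeric(2)))
  out <- data.frame(cell = as.integer(names(cells)),
                    partial_prob = res[, "prob"],
                    partial_dur = res[, "dur"])
  out <- out[order(out$cell), ]
  rownames(out) <- NULL
  class(out) <- c("cs_partials", "data.frame")
  out
}

#' @export
summary.cs_partials <- function(object, ...) {
  ok <- stats::complete.cases(object[, c("partial_prob", "partial_dur")])
  out <- list(
    n_cells = nrow(object),
    n_defined = sum(ok),
    mean_prob = mean(object$partial_prob[ok]),
    mean_dur = mean(object$partial_dur[ok]),
    quadrant_I_fraction = mean(object$partial_prob[ok] > 0 &
                               object$partial_dur[ok] > 0)
  )
  class(out) <- "summary.cs_partials"
  out
}

#' @export
print.summary.cs_partials <- function(x, ...) {
  cat(sprintf("partial correlations for %d cells (%d defined)\n",
              x$n_cells, x$n_defined))
  cat(sprintf("  mean partial r(change, probability | duration): %+.4f\n",
              x$mean_prob))
  cat(sprintf("  mean partial r(change, duration | probability): %+.4f\n",
              x$mean_dur))
  cat(sprintf("  fraction of cells in quadrant I (both > 0):     %.4f\n",
              x$quadrant_I_fraction))
  invisible(x)
}

#' @export
plot.cs_partials <- function(x, ...) {
  graphics::plot(x$partial_prob, x$partial_dur,
                 xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = "partial r (change vs CS probability | duration)",
                 ylab = "partial r (change vs CS duration | probability)",
                 pch = 1, col = "grey40", ...)
  graphics::abline(h = 0, v = 0, lty = 2)
  ok <- stats::complete.cases(x[, c("partial_prob", "partial_dur")])
  graphics::points(mean(x$partial_prob[ok]), mean(x$partial_dur[ok]),
                   pch = 19, col = "red", cex = 1.5)
  invisible(x)
}

#' Sweep of the measured binned correlation over model parameters
#'
#' For every combination of underlying duration-probability correlation
#' \code{r} and imposed temporal correlation (\code{= 1 - decorrelation}),
#' simulates \code{replicates} independent model cells, measures each cell's
#' 10-trial-bin duration-probability correlation, and stores the replicate
#' mean and its standard error. The iso-contour where the measured
#' correlation equals \code{contour_level} is extracted per column by linear
#' interpolation along the \code{r} axis.
#'
#' @param model Base \code{\link{cs_model}} (its \code{duration_corr} and
#'   \code{temporal_decorrelation} are overridden cell by cell).
#' @param r_values Underlying correlations to sweep (rows).
#' @param temporal_corr_values Temporal correlations to sweep (columns).
#' @param replicates Cells simulated per grid point (default 20).
#' @param seed Base RNG seed.
#' @param group_size Trials per bin (default 10).
#' @param contour_level Level of the extracted iso-contour (default 0.1).
#' @return Object of class \code{"cs_sweep"}: list with \code{grid} (mean
#'   measured correlation, r x temporal corr), \code{se} (replicate SE),
#'   \code{r_values}, \code{temporal_corr_values}, \code{contour}
#'   (data.frame \code{temporal_corr}, \code{r}: interpolated \code{r} at
#'   which the measured correlation crosses \code{contour_level}; NA when
#'   the column never crosses).
#' @export
sweep_measured_correlation <- function(model,
                                       r_values = seq(0, 1, by = 0.1),
                                       temporal_corr_values = seq(0, 1,
                                                                  by = 0.1),
                                       replicates = 20L,
                                       seed = model$rng_seed,
                                       group_size = 10L,
                                       contour_level = 0.1) {
  stopifnot(all(r_values >= 0 & r_values <= 1),
            all(temporal_corr_values >= 0 & temporal_corr_values <= 1))
  nr <- length(r_values); nc <- length(temporal_corr_values)
  grid <- se <- matrix(NA_real_, nr, nc,
                       dimnames = list(r = r_values,
                                       temporal_corr = temporal_corr_values))
  cell_seed <- as.integer(seed)
  for (ci in seq_len(nc)) {
    for (ri in seq_len(nr)) {
      m <- model
      m$duration_corr <- r_values[ri]
      m$temporal_decorrelation <- 1 - temporal_corr_values[ci]
      vals <- numeric(replicates)
      for (k in seq_len(replicates)) {
        cell_seed <- cell_seed + 1L
        tr <- simulate_cell(m, seed = cell_seed)
        vals[k] <- binned_duration_probability_correlation(
          model_bins(tr, group_size))$r
      }
      vals <- vals[is.finite(vals)]
      grid[ri, ci] <- mean(vals)
      se[ri, ci] <- stats::sd(vals) / sqrt(length(vals))
    }
  }
  contour <- data.frame(temporal_corr = temporal_corr_values, r = NA_real_)
  for (ci in seq_len(nc)) {
    col <- grid[, ci]
    cross <- which(diff(col >= contour_level) != 0)
    if (col[1] >= contour_level) {
      contour$r[ci] <- r_values[1]
    } else if (length(cross)) {
      j <- cross[1]
      f <- (contour_level - col[j]) / (col[j + 1] - col[j])
      contour$r[ci] <- r_values[j] + f * (r_values[j + 1] - r_values[j])
    }
  }
  structure(list(grid = grid, se = se, r_values = r_values,
                 temporal_corr_values = temporal_corr_values,
                 replicates = replicates, contour_level = contour_level,
                 contour = contour),
            class = "cs_sweep")
}

#' @export
print.cs_sweep <- function(x, ...) {
  cat(sprintf(
    "measured binned correlation: %d x %d grid, %d replicates per cell\n",
    length(x$r_values), length(x$temporal_corr_values), x$replicates))
  print(round(x$grid, 3))
  invisible(x)
}

#' @export
plot.cs_sweep <- function(x, ...) {
  graphics::image(x$temporal_corr_values, x$r_values, t(x$grid),
                  xlab = "temporal correlation (1 - decorrelation)",
                  ylab = "underlying correlation r",
                  main = "measured duration-probability correlation", ...)
  ok <- !is.na(x$contour$r)
  if (any(ok))
    graphics::lines(x$contour$temporal_corr[ok], x$contour$r[ok], lwd = 2)
  invisible(x)
}

#' Correlation between a noise-corrupted curve and a reference curve
#'
#' Adds independent normal noise of the given variance to \code{curve_a} and
#' correlates the corrupted curve with \code{curve_b}, repeated \code{reps}
#' times. Used to judge how much measurement noise attenuates the
#' correlation between binned learning curves.
#'
#' @param curve_a,curve_b Equal-length numeric curves.
#' @param noise_variance Variance of the added noise (same units squared).
#' @param reps Replicates (default 1000).
#' @return Numeric vector of \code{reps} correlation coefficients.
#' @export
noise_corrupted_curve_correlation <- function(curve_a, curve_b,
                                              noise_variance, reps = 1000L) {
  stopifnot(length(curve_a) == length(curve_b), noise_variance >= 0)
  sd_n <- sqrt(noise_variance)
  vapply(seq_len(reps), function(i) {
    stats::cor(curve_a + stats::rnorm(length(curve_a), 0, sd_n), curve_b)
  }, numeric(1))
}

#' Paired comparison with Bonferroni adjustment
#'
#' Two-sided paired t test with the p value multiplied by the number of
#' comparisons in the family (capped at 1). Zero-variance differences are a
#' degenerate case: the p value is 1 when the mean difference is 0 and 0
#' otherwise, flagged via \code{degenerate = TRUE}.
#'
#' @param values_a,values_b Equal-length paired samples (one entry per cell).
#' @param n_comparisons Bonferroni multiplier (default 3: the three pairwise
#'   paradigm comparisons).
#' @return List: \code{statistic}, \code{p_value}, \code{p_adjusted},
#'   \code{mean_difference}, \code{degenerate}.
#' @export
paired_comparison <- function(values_a, values_b, n_comparisons = 3L) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    p <- if (mean(d) == 0) 1 else 0
    return(list(statistic = NA_real_, p_value = p,
                p_adjusted = min(1, p * n_comparisons),
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       p_adjusted = min(1, tt$p.value * n_comparisons),
       mean_difference = mean(d), degenerate = FALSE)
}

#' Recover plasticity constants from a synthetic session by regression
#'
#' Estimates the depression and potentiation magnitudes generating a session
#' by regressing the per-pair trial-over-trial change in window-mean firing
#' rate on indicator variables for the instruction trial's outcome (CS /
#' CS-less off-direction) and for the previous trial's outcome. With
#' one-trial memory the change on pair \eqn{i} is the learning injected by
#' trial \eqn{i} minus the learning injected by trial \eqn{i-1}, so both
#' sets of indicators are needed for an unbiased estimate; the raw
#' conditional mean of the change is biased by the plasticity carried into
#' the instruction trial.
#'
#' @param session A \code{"cs_session"}.
#' @param windows An \code{\link{analysis_windows}}.
#' @return List: \code{depression} and \code{potentiation} (each a list with
#'   \code{estimate} and \code{se}, spikes/s, positive magnitudes), and the
#'   underlying \code{fit} (an \code{lm}).
#' @export
estimate_plasticity <- function(session, windows = analysis_windows()) {
  pairs <- pair_trials(session, direction = "both", windows = windows)
  pairs <- pair_changes(session, pairs, what = "rate", windows = windows)
  tr <- session$trials
  csw <- csin_window(tr, windows)$cs
  offnc <- tr$direction == "off" & !csw
  i <- match(pairs$instruction_index, tr$trial)
  df <- data.frame(
    change = pairs$tot_change,
    cs_instr = as.numeric(csw[i]),
    offnc_instr = as.numeric(offnc[i]),
    cs_prev = as.numeric(ifelse(i > 1, csw[pmax(i - 1, 1)], 0)),
    offnc_prev = as.numeric(ifelse(i > 1, offnc[pmax(i - 1, 1)], 0))
  )
  fit <- stats::lm(change ~ 0 + cs_instr + offnc_instr + cs_prev + offnc_prev,
                   data = df)
  cf <- stats::coef(summary(fit))
  list(depression = list(estimate = -unname(cf["cs_instr", "Estimate"]),
                         se = unname(cf["cs_instr", "Std. Error"])),
       potentiation = list(estimate = unname(cf["offnc_instr", "Estimate"]),
                           se = unname(cf["offnc_instr", "Std. Error"])),
       fit = fit)
}
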