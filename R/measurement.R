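#' Analysis-window conventions
#'
#' Bundles the windowing constants of the learning analyses. The learning
#' window is the closed interval \code{[-100, +50]} ms around instruction
#' onset (151 samples on a 1-ms grid): ending 50 ms after the instructive
#' change ensures the learning measure precedes any visual feedback. CS
#' responses are counted in the 75-175 ms window after instruction onset;
#' CS-probability curves use 100-ms bins; pair-level metrics are aggregated
#' in sequential groups of 10.
#'
#' @param learning_window Length-2 ms interval relative to instruction onset
#'   (default \code{c(-100, 50)}); the upper end must not exceed +50 ms.
#' @param cs_window Length-2 ms interval for CS counting (default
#'   \code{c(75, 175)}).
#' @param cs_bin_width CS-probability bin width, ms (default 100).
#' @param group_size Pairs per bin (default 10).
#' @return Object of class \code{"analysis_windows"}.
#' @export
analysis_windows <- function(learning_window = c(-100, 50),
                             cs_window = c(75, 175),
                             cs_bin_width = 100,
                             group_size = 10L) {
  stopifnot(length(learning_window) == 2,
            learning_window[1] < learning_window[2],
            learning_window[2] <= 50,
            length(cs_window) == 2, cs_window[1] < cs_window[2],
            cs_bin_width > 0, group_size >= 1)
  structure(list(learning_window = as.numeric(learning_window),
                 cs_window = as.numeric(cs_window),
                 cs_bin_width = as.numeric(cs_bin_width),
                 group_size = as.integer(group_size)),
            class = "analysis_windows")
}

#' Reciprocal-interval firing-rate estimate
#'
#' At each grid time falling inside an inter-spike interval of length
#' \eqn{\Delta} ms the instantaneous rate is \eqn{1000/\Delta} spikes/s;
#' before the first and after the last spike the rate is 0. A grid time equal
#' to a spike time is assigned to the interval that starts there. With fewer
#' than two spikes the rate is 0 everywhere.
#'
#' @param spike_times Strictly increasing spike times, ms.
#' @param t_grid Times at which to evaluate the rate, ms.
#' @return Numeric vector of rates, spikes/s, same length as \code{t_grid}.
#' @export
reciprocal_interval_rate <- function(spike_times, t_grid) {
  if (length(spike_times) > 1 && any(diff(spike_times) <= 0))
    stop("spike times must be strictly increasing", call. = FALSE)
  n <- length(spike_times)
  rate <- numeric(length(t_grid))
  if (n < 2) return(rate)
  isi <- diff(spike_times)                 # ms
  idx <- findInterval(t_grid, spike_times)
  inside <- idx >= 1 & idx < n & t_grid < spike_times[n]
  rate[inside] <- 1000 / isi[idx[inside]]
  rate
}

#' Mean of a trace over the learning window
#'
#' Arithmetic mean of the trace samples whose times lie in the closed
#' interval \code{[onset + window[1], onset + window[2]]}.
#'
#' @param trace Numeric trace sampled at \code{times}.
#' @param times Sample times, ms.
#' @param onset Alignment time (instruction onset), ms.
#' @param window Length-2 interval relative to \code{onset}
#'   (default \code{c(-100, 50)}).
#' @return Scalar mean.
#' @export
window_mean <- function(trace, times, onset, window = c(-100, 50)) {
  stopifnot(length(trace) == length(times))
  lo <- onset + window[1]
  hi <- onset + window[2]
  if (lo < min(times) || hi > max(times))
    stop("analysis window extends beyond the trace", call. = FALSE)
  sel <- times >= lo & times <= hi
  mean(trace[sel])
}

#' Assemble consecutive-trial pairs from a session
#'
#' Slides over consecutive trials: pair \eqn{i} has instruction trial
#' \eqn{i} and test trial \eqn{i+1} (overlapping, so every interior trial is
#' the test of one pair and the instruction of the next). Pairs are filtered
#' to those whose instruction trial has the requested direction. CS
#' contingency and duration are attached from the instruction trial's CS
#' events within the CS window (first CS if several).
#'
#' @param session A \code{"cs_session"}.
#' @param direction Instruction direction to keep: \code{"off"} (default),
#'   \code{"on"}, or \code{"both"}.
#' @param windows An \code{\link{analysis_windows}}.
#' @return Data.frame: \code{pair}, \code{instruction_index},
#'   \code{test_index} (0-based trial ordinals), \code{direction}, \code{cs},
#'   \code{cs_duration} (NA without a CS).
#' @export
pair_trials <- function(session, direction = c("off", "on", "both"),
                        windows = analysis_windows()) {
  direction <- match.arg(direction)
  tr <- session$trials
  n <- nrow(tr)
  if (n < 2) stop("need at least 2 trials to form pairs", call. = FALSE)
  instr <- seq_len(n - 1)
  cs_in_win <- csin_window(tr, windows)
  pairs <- data.frame(pair = seq_along(instr),
                      instruction_index = tr$trial[instr],
                      test_index = tr$trial[instr + 1],
                      direction = tr$direction[instr],
                      cs = cs_in_win$cs[instr],
                      cs_duration = cs_in_win$duration[instr])
  if (direction != "both")
    pairs <- pairs[pairs$direction == direction, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# does each trial have a CS inside the cs_window, and with what duration
csin_window <- function(tr, windows) {
  rel <- tr$cs_time - tr$instruction_onset
  ok <- !is.na(rel) & rel >= windows$cs_window[1] & rel <= windows$cs_window[2]
  list(cs = ok, duration = ifelse(ok, tr$cs_duration, NA_real_))
}

#' Per-trial rate traces for a session
#'
#' Reciprocal-interval rate estimates for every trial on the session's 1-ms
#' time grid.
#'
#' @param session A \code{"cs_session"}.
#' @return Matrix, trials x time samples.
#' @export
session_rate_traces <- function(session) {
  t(vapply(session$spike_times,
           reciprocal_interval_rate,
           numeric(length(session$times)),
           t_grid = session$times))
}

#' Trial-over-trial change for one pair of trials
#'
#' Millisecond-by-millisecond difference (test minus instruction) of the
#' firing-rate or eye-velocity traces of a consecutive-trial pair, plus its
#' mean over the learning window.
#'
#' @param session A \code{"cs_session"}.
#' @param instruction_index 0-based ordinal of the instruction trial.
#' @param what \code{"rate"} or \code{"eye"}.
#' @param windows An \code{\link{analysis_windows}}.
#' @param traces Optional precomputed trace matrix (trials x samples), e.g.
#'   from \code{\link{session_rate_traces}}; avoids re-estimating rates.
#' @return List: \code{times} (ms relative to instruction onset),
#'   \code{difference} (per-ms trace), \code{change} (window-mean scalar).
#' @export
trial_over_trial_change <- function(session, instruction_index,
                                    what = c("rate", "eye"),
                                    windows = analysis_windows(),
                                    traces = NULL) {
  what <- match.arg(what)
  i <- match(instruction_index, session$trials$trial)
  if (is.na(i) || i + 1 > nrow(session$trials))
    stop("no such consecutive pair in session", call. = FALSE)
  if (is.null(traces))
    traces <- if (what == "rate") session_rate_traces(session)
              else session$eye_velocity
  diff_trace <- traces[i + 1, ] - traces[i, ]
  onset <- session$trials$instruction_onset[i]
  list(times = session$times - onset,
       difference = diff_trace,
       change = window_mean(diff_trace, session$times, onset,
                            windows$learning_window))
}

#' Window-mean trial-over-trial changes for a pairs table
#'
#' Vectorized companion of \code{\link{trial_over_trial_change}}: appends a
#' \code{tot_change} column (test-minus-instruction window mean) to a
#' \code{\link{pair_trials}} table.
#'
#' @inheritParams trial_over_trial_change
#' @param pairs Data.frame from \code{\link{pair_trials}}.
#' @return \code{pairs} with an added \code{tot_change} column (spikes/s for
#'   \code{"rate"}, deg/s for \code{"eye"}).
#' @export
pair_changes <- function(session, pairs, what = c("rate", "eye"),
                         windows = analysis_windows()) {
  what <- match.arg(what)
  traces <- if (what == "rate") session_rate_traces(session)
            else session$eye_velocity
  onset <- session$trials$instruction_onset[1]
  sel <- session$times >= onset + windows$learning_window[1] &
         session$times <= onset + windows$learning_window[2]
  wmean <- rowMeans(traces[, sel, drop = FALSE])
  i <- match(pairs$instruction_index, session$trials$trial)
  pairs$tot_change <- wmean[i + 1] - wmean[i]
  pairs
}

#' CS-probability curve in fixed-width bins
#'
#' Counts, per time bin, the trials with at least one CS event in the bin and
#' converts counts to probabilities. Bins tile the trial in
#' \code{bin_width}-ms steps starting at the alignment origin (instruction
#' onset by default). Multiple CSs in one bin count once.
#'
#' @param session A \code{"cs_session"}.
#' @param bin_width Bin width, ms (default 100).
#' @param origin \code{"instruction"} (default) or \code{"target"}: alignment
#'   zero for the bins.
#' @param direction Which trials to include (default \code{"off"}).
#' @return Data.frame: \code{bin_start}, \code{bin_end} (ms from origin),
#'   \code{probability}.
#' @export
cs_probability_curve <- function(session, bin_width = 100,
                                 origin = c("instruction", "target"),
                                 direction = c("off", "on", "both")) {
  origin <- match.arg(origin)
  direction <- match.arg(direction)
  tr <- session$trials
  if (direction != "both") tr <- tr[tr$direction == direction, , drop = FALSE]
  if (nrow(tr) == 0) stop("no trials with requested direction", call. = FALSE)
  t0 <- if (origin == "instruction") tr$instruction_onset else 0
  rel <- tr$cs_time - t0
  t_max <- max(session$times) - (if (origin == "instruction")
    tr$instruction_onset[1] else 0)
  edges <- seq(0, t_max + bin_width, by = bin_width)
  nbin <- length(edges) - 1L
  prob <- numeric(nbin)
  for (b in seq_len(nbin)) {
    inbin <- !is.na(rel) & rel >= edges[b] & rel < edges[b + 1]
    prob[b] <- mean(inbin)
  }
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             probability = prob)
}

#' Classify a Purkinje cell as CS-frequent
#'
#' A cell is CS-frequent when its CS probability in the analysis window is
#' strictly greater than 0.3; only such cells are analysed.
#'
#' @param cs_probability_in_window Fraction in \eqn{[0, 1]}.
#' @return Logical.
#' @export
classify_cs_frequent <- function(cs_probability_in_window) {
  stopifnot(all(cs_probability_in_window >= 0),
            all(cs_probability_in_window <= 1))
  cs_probability_in_window > 0.3
}

#' Aggregate pair-level metrics in sequential groups
#'
#' Splits an ordered pairs table into consecutive non-overlapping groups of
#' \code{group_size}; a trailing remainder smaller than \code{group_size} is
#' dropped so every bin has equal size. Per bin: number of pairs, mean
#' trial-over-trial change, CS probability (fraction of pairs with a CS on
#' the instruction trial), and mean CS duration over CS pairs (NA when the
#' bin has no CS).
#'
#' @param pairs Data.frame with columns \code{cs}, \code{cs_duration} and
#'   (optionally) \code{tot_change}, in trial order.
#' @param group_size Pairs per bin (default 10).
#' @return Data.frame: \code{bin}, \code{n_pairs}, \code{mean_tot_change},
#'   \code{cs_probability}, \code{mean_cs_duration}.
#' @export
bin_groups <- function(pairs, group_size = 10L) {
  n <- nrow(pairs)
  nbin <- n %/% group_size
  if (nbin == 0)
    return(data.frame(bin = integer(0), n_pairs = integer(0),
                      mean_tot_change = numeric(0),
                      cs_probability = numeric(0),
                      mean_cs_duration = numeric(0)))
  idx <- rep(seq_len(nbin), each = group_size)
  pairs <- pairs[seq_len(nbin * group_size), , drop = FALSE]
  has_change <- "tot_change" %in% names(pairs)
  out <- data.frame(bin = seq_len(nbin), n_pairs = as.integer(group_size))
  out$mean_tot_change <- if (has_change)
    as.numeric(tapply(pairs$tot_change, idx, mean)) else NA_real_
  out$cs_probability <- as.numeric(tapply(pairs$cs, idx, mean))
  dur <- tapply(seq_len(nrow(pairs)), idx, function(j) {
    d <- pairs$cs_duration[j][pairs$cs[j]]
    if (length(d) == 0) NA_real_ else mean(d)
  })
  out$mean_cs_duration <- as.numeric(dur)
  out
}

#' Bin the trials of a simulated model cell
#'
#' Model-side counterpart of \code{\link{bin_groups}}: converts one cell's
#' trial table from \code{\link{simulate_cell}} into 10-trial-bin summaries.
#' The last trial is dropped first (its \code{delta_ss} describes a pair that
#' leaves the block), then trials are grouped consecutively. Mean CS duration
#' uses the raw durations \code{d} of the CS trials in the bin, i.e. only the
#' durations an experimenter could observe.
#'
#' @param trials Data.frame from \code{\link{simulate_cell}} (one cell).
#' @param group_size Trials per bin (default 10).
#' @return Same columns as \code{\link{bin_groups}}.
#' @export
model_bins <- function(trials, group_size = 10L) {
  use <- trials[-nrow(trials), , drop = FALSE]  # pairs fully inside block
  pairs <- data.frame(cs = use$cs, cs_duration = ifelse(use$cs, use$d, NA),
                      tot_change = use$delta_ss)
  bin_groups(pairs, group_size)
}

#' History-contingent CS probability in the random paradigm
#'
#' For each history depth \code{k}, finds off-direction trials whose
#' preceding \code{k} instruction directions follow the requested pattern
#' (\code{"repeated"}: all off; \code{"alternating"}: on, off, on, ... going
#' backwards) and returns the fraction of those trials bearing a CS in the
#' CS window. Depths with no qualifying trials yield NA (absent), not 0.
#'
#' @param session A \code{"cs_session"} (random paradigm).
#' @param pattern \code{"repeated"} or \code{"alternating"}.
#' @param depths Integer history depths (default \code{1:4}).
#' @param windows An \code{\link{analysis_windows}}.
#' @return Data.frame: \code{depth}, \code{n_trials}, \code{probability}.
#' @export
history_contingent_cs_probability <- function(session,
                                              pattern = c("repeated",
                                                          "alternating"),
                                              depths = 1:4,
                                              windows = analysis_windows()) {
  pattern <- match.arg(pattern)
  tr <- session$trials
  dirs <- tr$direction
  csw <- csin_window(tr, windows)$cs
  n <- nrow(tr)
  res <- data.frame(depth = depths, n_trials = NA_integer_,
                    probability = NA_real_)
  for (di in seq_along(depths)) {
    k <- depths[di]
    want <- if (pattern == "repeated") rep("off", k)
            else rep_len(c("on", "off"), k)  # lag 1 = on, lag 2 = off, ...
    ok <- logical(n)
    for (i in seq_len(n)) {
      if (i <= k || dirs[i] != "off") next
      hist_dirs <- dirs[i - seq_len(k)]     # lags 1..k
      ok[i] <- all(hist_dirs == want)
    }
    res$n_trials[di] <- sum(ok)
    if (any(ok)) res$probability[di] <- mean(csw[ok])
  }
  res
}
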