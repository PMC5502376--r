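#' Specify the generative model of CS-linked single-trial plasticity
#'
#' Constructs the parameter object for the stochastic model of complex-spike
#' (CS) occurrence, CS duration and CS-contingent trial-over-trial change in
#' simple-spike firing of a cerebellar Purkinje cell during off-direction
#' learning trials.
#'
#' On every trial a latent seed \eqn{p \sim N(0, \sigma_p)} is drawn together
#' with a threshold \eqn{t = s \cdot U(0,1)}; a CS occurs iff \eqn{p > t}.
#' Every trial also carries a latent raw duration
#' \deqn{d = c \left[ r p + (1 - r^2)\,\epsilon + 1 \right], \quad
#'       \epsilon \sim N(0, \sigma_d),}
#' normalized to \eqn{D = d/4 - 1} so that \eqn{E[D] = 1}. The underlying
#' correlation between CS propensity and duration is set by \code{r}
#' (\code{duration_corr}). Temporal correlation of duration across trials is
#' imposed afterwards by sorting trials by \code{d} and undoing the sort with
#' \code{floor(temporal_decorrelation * n)} random pairwise swaps
#' (\code{\link{apply_temporal_structure}}). The trial-over-trial change in
#' simple-spike rate from trial \eqn{i} to \eqn{i+1} is
#' \deqn{\Delta SS = -g\,D + N(0, \sigma_n) \textrm{ after a CS trial,}
#'       \qquad \Delta SS = m + N(0, \sigma_n) \textrm{ otherwise,}}
#' with depression gain \eqn{g}, potentiation mean \eqn{m} and noise SD
#' \eqn{\sigma_n}. The model has no memory beyond one trial and simulates
#' off-direction learning trials only.
#'
#' @param prob_seed_sd SD \eqn{\sigma_p} of the CS seed distribution
#'   (dimensionless, default 0.2).
#' @param threshold_scale Upper bound \eqn{s} of the uniform CS threshold
#'   (dimensionless, default 0.8).
#' @param duration_corr Underlying correlation parameter \eqn{r} linking
#'   duration to the CS seed, in \eqn{[-1, 1]} (default 0.5).
#' @param duration_noise_sd SD \eqn{\sigma_d} of the duration noise
#'   (dimensionless, default 0.2).
#' @param duration_scale Duration scale \eqn{c} in ms (default 8), chosen so
#'   simulated durations match the empirical CS-duration distribution.
#' @param depression_gain Depression slope \eqn{g} in spikes/s per unit
#'   normalized duration (default 5.5).
#' @param potentiation_mean Potentiation \eqn{m} after a CS-less trial,
#'   spikes/s (default 1.7).
#' @param plasticity_noise_sd SD \eqn{\sigma_n} of the trial-over-trial noise,
#'   spikes/s (default 14).
#' @param n_trials Number of off-direction learning trials per cell
#'   (default 200).
#' @param n_cells Number of model Purkinje cells in a population
#'   (default 1000).
#' @param temporal_decorrelation Swaps per trial in \eqn{[0, 1]} applied after
#'   sorting by duration (default 0.8); the imposed temporal correlation is
#'   \code{1 - temporal_decorrelation}.
#' @param rng_seed Integer seed for reproducible simulation.
#'
#' @return An object of class \code{"cs_model"}: a validated parameter list.
#' @seealso \code{\link{simulate.cs_model}}, \code{\link{simulate_cell}}
#' @examples
#' m <- cs_model(duration_corr = 0.8, n_cells = 10)
#' pop <- simulate(m, seed = 1)
#' summary(pop)
#' @export
cs_model <- function(prob_seed_sd = 0.2,
                     threshold_scale = 0.8,
                     duration_corr = 0.5,
                     duration_noise_sd = 0.2,
                     duration_scale = 8,
                     depression_gain = 5.5,
                     potentiation_mean = 1.7,
                     plasticity_noise_sd = 14,
                     n_trials = 200L,
                     n_cells = 1000L,
                     temporal_decorrelation = 0.8,
                     rng_seed = 1L) {
  m <- list(
    prob_seed_sd = as.numeric(prob_seed_sd),
    threshold_scale = as.numeric(threshold_scale),
    duration_corr = as.numeric(duration_corr),
    duration_noise_sd = as.numeric(duration_noise_sd),
    duration_scale = as.numeric(duration_scale),
    depression_gain = as.numeric(depression_gain),
    potentiation_mean = as.numeric(potentiation_mean),
    plasticity_noise_sd = as.numeric(plasticity_noise_sd),
    n_trials = as.integer(n_trials),
    n_cells = as.integer(n_cells),
    temporal_decorrelation = as.numeric(temporal_decorrelation),
    rng_seed = as.integer(rng_seed)
  )
  validate_cs_model(m)
  class(m) <- "cs_model"
  m
}

validate_cs_model <- function(m) {
  stop_if <- function(bad, msg) if (bad) stop(msg, call. = FALSE)
  for (f in names(m)) {
    stop_if(length(m[[f]]) != 1L || is.na(m[[f]]),
            sprintf("parameter '%s' must be a single non-missing value", f))
  }
  stop_if(m$prob_seed_sd <= 0, "'prob_seed_sd' must be > 0")
  stop_if(m$threshold_scale < 0, "'threshold_scale' must be >= 0")
  stop_if(abs(m$duration_corr) > 1, "'duration_corr' must lie in [-1, 1]")
  stop_if(m$duration_noise_sd < 0, "'duration_noise_sd' must be >= 0")
  stop_if(m$duration_scale <= 0, "'duration_scale' must be > 0")
  stop_if(m$plasticity_noise_sd < 0, "'plasticity_noise_sd' must be >= 0")
  stop_if(m$n_trials < 2L, "'n_trials' must be >= 2")
  stop_if(m$n_cells < 1L, "'n_cells' must be >= 1")
  stop_if(m$temporal_decorrelation < 0 || m$temporal_decorrelation > 1,
          "'temporal_decorrelation' must lie in [0, 1]")
  invisible(m)
}

#' @export
print.cs_model <- function(x, ...) {
  cat("Generative model of CS-linked single-trial plasticity\n")
  cat(sprintf("  CS seed: N(0, %g); threshold: %g * U(0,1)\n",
              x$prob_seed_sd, x$threshold_scale))
  cat(sprintf("  duration: %g * [%g*p + %g*N(0, %g) + 1] ms, D = d/4 - 1\n",
              x$duration_scale, x$duration_corr,
              1 - x$duration_corr^2, x$duration_noise_sd))
  cat(sprintf("  plasticity: -%g*D + N(0, %g) | CS;  %g + N(0, %g) | no CS\n",
              x$depression_gain, x$plasticity_noise_sd,
              x$potentiation_mean, x$plasticity_noise_sd))
  cat(sprintf("  temporal decorrelation: %g swaps/trial (temporal corr %g)\n",
              x$temporal_decorrelation, 1 - x$temporal_decorrelation))
  cat(sprintf("  %d cells x %d trials, seed %d\n",
              x$n_cells, x$n_trials, x$rng_seed))
  invisible(x)
}

#' @export
coef.cs_model <- function(object, ...) {
  unlist(object[c("prob_seed_sd", "threshold_scale", "duration_corr",
                  "duration_noise_sd", "duration_scale", "depression_gain",
                  "potentiation_mean", "plasticity_noise_sd",
                  "temporal_decorrelation")])
}

#' Draw the per-trial latent variables of the model
#'
#' Draws, for \code{n} trials, the CS seed \code{p ~ N(0, prob_seed_sd)}, the
#' CS threshold \code{t = threshold_scale * U(0, 1)}, the duration noise
#' \code{~ N(0, duration_noise_sd)} and the plasticity noise
#' \code{~ N(0, plasticity_noise_sd)}, all mutually independent. Uses the
#' current RNG state; seed beforehand for reproducibility.
#'
#' @param model A \code{\link{cs_model}} object.
#' @param n Number of trials (>= 1).
#' @return A data.frame with columns \code{p}, \code{t}, \code{duration_noise},
#'   \code{plasticity_noise}.
#' @export
draw_trial_latents <- function(model, n) {
  stopifnot(inherits(model, "cs_model"), n >= 1)
  n <- as.integer(n)
  data.frame(
    p = stats::rnorm(n, 0, model$prob_seed_sd),
    t = model$threshold_scale * stats::runif(n),
    duration_noise = stats::rnorm(n, 0, model$duration_noise_sd),
    plasticity_noise = stats::rnorm(n, 0, model$plasticity_noise_sd)
  )
}

#' CS occurrence rule
#'
#' A complex spike occurs on a trial iff its seed strictly exceeds its
#' threshold, \code{p > t}. Vectorized.
#'
#' @param p CS seed(s).
#' @param t threshold(s).
#' @return Logical vector.
#' @export
decide_cs <- function(p, t) {
  p > t
}

#' Raw CS duration from the seed
#'
#' \code{d = duration_scale * (r * p + (1 - r^2) * duration_noise + 1)} with
#' \code{r = duration_corr}. The coefficient on the noise term is
#' \code{(1 - r^2)}, not its square root, so the duration variance is not
#' preserved across \code{r}; this matches the model definition as stated.
#' Computed for every trial (CS or not): on CS-less trials \code{d} is a
#' latent used only as the sort key for imposing temporal correlation.
#'
#' @param p CS seed(s).
#' @param duration_noise Noise deviate(s), already scaled to
#'   \code{duration_noise_sd}.
#' @param model A \code{\link{cs_model}}.
#' @return Raw duration(s) in ms.
#' @export
duration_from_seed <- function(p, duration_noise, model) {
  r <- model$duration_corr
  model$duration_scale * (r * p + (1 - r^2) * duration_noise + 1)
}

#' Normalize a raw CS duration
#'
#' \code{D = d/4 - 1}, which at the default duration scale of 8 ms yields
#' values mostly between 0 and 2 with unconditional mean 1.
#'
#' @param d Raw duration(s), ms.
#' @return Normalized duration(s), dimensionless.
#' @export
normalize_duration <- function(d) {
  d / 4 - 1
}

#' Trial-over-trial simple-spike change
#'
#' Returns \code{-depression_gain * D + noise} on CS trials and
#' \code{potentiation_mean + noise} on CS-less trials. The change attaches to
#' the instruction trial of each consecutive pair: \code{delta_ss} for trial
#' \code{i} is the change in simple-spike rate from trial \code{i} to
#' \code{i + 1}.
#'
#' @param cs Logical: CS on the trial?
#' @param D Normalized duration (required where \code{cs} is TRUE).
#' @param plasticity_noise Noise deviate(s), spikes/s.
#' @param model A \code{\link{cs_model}}.
#' @return Change(s) in spikes/s.
#' @export
delta_ss <- function(cs, D, plasticity_noise, model) {
  if (any(cs & !is.finite(D)))
    stop("normalized duration D must be set on every CS trial", call. = FALSE)
  ifelse(cs,
         -model$depression_gain * D + plasticity_noise,
         model$potentiation_mean + plasticity_noise)
}

#' Impose temporal structure by sorting and partial shuffling
#'
#' Sorts trials by raw duration \code{d} (ascending), creating maximal
#' temporal correlation of duration, then disrupts it with exactly
#' \code{floor(decorrelation * n)} swaps. Each swap exchanges the contents of
#' two positions chosen independently and uniformly at random (a position may
#' repeat across swaps; a self-swap counts as executed). The imposed temporal
#' correlation is defined as \code{1 - decorrelation}: zero swaps leave the
#' pure sort (temporal correlation 1).
#'
#' Trial indices are reassigned \code{0..n-1} after reordering: the procedure
#' permutes trial contents, not indices.
#'
#' @param trials Data.frame of trials containing a numeric column \code{d}.
#' @param decorrelation Swaps per trial, in \eqn{[0, 1]}.
#' @return The reordered data.frame, with attribute \code{n_swaps} giving the
#'   number of swaps executed.
#' @export
apply_temporal_structure <- function(trials, decorrelation) {
  stopifnot(is.data.frame(trials), "d" %in% names(trials),
            decorrelation >= 0, decorrelation <= 1)
  n <- nrow(trials)
  perm <- order(trials$d)
  n_swaps <- floor(decorrelation * n)
  if (n_swaps > 0) {
    ii <- sample.int(n, n_swaps, replace = TRUE)
    jj <- sample.int(n, n_swaps, replace = TRUE)
    for (k in seq_len(n_swaps)) {
      tmp <- perm[ii[k]]
      perm[ii[k]] <- perm[jj[k]]
      perm[jj[k]] <- tmp
    }
  }
  out <- trials[perm, , drop = FALSE]
  if ("trial" %in% names(out)) out$trial <- seq_len(n) - 1L
  rownames(out) <- NULL
  attr(out, "n_swaps") <- n_swaps
  out
}

#' Simulate one model Purkinje cell
#'
#' Generates \code{n_trials} off-direction learning trials: latent draws, CS
#' decision, raw and normalized duration, sort-and-swap temporal structure,
#' then the trial-over-trial simple-spike change. \code{delta_ss} on row
#' \code{i} is the change from trial \code{i} to trial \code{i + 1}; the last
#' trial's value describes a hypothetical next trial, and pair-level analyses
#' should use only pairs fully inside the block.
#'
#' @param model A \code{\link{cs_model}}.
#' @param seed Optional integer seed set before drawing (default: leave the
#'   RNG state untouched).
#' @param n_trials Number of trials; defaults to \code{model$n_trials}.
#' @return Data.frame with columns \code{trial}, \code{p}, \code{t},
#'   \code{cs}, \code{d}, \code{D}, \code{delta_ss}.
#' @export
simulate_cell <- function(model, seed = NULL, n_trials = model$n_trials) {
  stopifnot(inherits(model, "cs_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  lat <- draw_trial_latents(model, n_trials)
  trials <- data.frame(
    trial = seq_len(n_trials) - 1L,
    p = lat$p,
    t = lat$t,
    cs = decide_cs(lat$p, lat$t),
    d = duration_from_seed(lat$p, lat$duration_noise, model),
    plasticity_noise = lat$plasticity_noise
  )
  trials$D <- normalize_duration(trials$d)
  trials <- apply_temporal_structure(trials, model$temporal_decorrelation)
  trials$delta_ss <- delta_ss(trials$cs, trials$D, trials$plasticity_noise,
                              model)
  trials$plasticity_noise <- NULL
  trials
}

#' Simulate a population of model Purkinje cells
#'
#' \code{simulate()} method for \code{\link{cs_model}}: generates
#' \code{nsim} independent cells, each \code{model$n_trials} trials long.
#' Cell \code{k} uses the RNG seed \code{seed + k}, so population runs are
#' bit-reproducible and a given cell's trials do not depend on how many other
#' cells are simulated.
#'
#' @param object A \code{\link{cs_model}}.
#' @param nsim Number of cells (default \code{object$n_cells}).
#' @param seed Base integer seed (default \code{object$rng_seed}).
#' @param ... Unused.
#' @return A data.frame of class \code{"cs_population"} with a leading
#'   \code{cell} column (1-based) followed by the \code{\link{simulate_cell}}
#'   columns; the generating model is attached as attribute \code{"model"}.
#' @export
simulate.cs_model <- function(object, nsim = object$n_cells,
                              seed = object$rng_seed, ...) {
  nsim <- as.integer(nsim)
  seed <- as.integer(seed)
  cells <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    tr <- simulate_cell(object, seed = seed + k)
    tr <- cbind(cell = k, tr)
    cells[[k]] <- tr
  }
  pop <- do.call(rbind, cells)
  rownames(pop) <- NULL
  attr(pop, "model") <- object
  class(pop) <- c("cs_population", "data.frame")
  pop
}

#' @export
print.cs_population <- function(x, ...) {
  m <- attr(x, "model")
  cat(sprintf("cs_population: %d cells x %d trials (%d rows)\n",
              length(unique(x$cell)), m$n_trials, nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' @export
summary.cs_population <- function(object, ...) {
  out <- list(
    n_cells = length(unique(object$cell)),
    n_trials = attr(object, "model")$n_trials,
    cs_fraction = mean(object$cs),
    mean_D = mean(object$D),
    mean_delta_cs = mean(object$delta_ss[object$cs]),
    mean_delta_nocs = mean(object$delta_ss[!object$cs])
  )
  class(out) <- "summary.cs_population"
  out
}

#' @export
print.summary.cs_population <- function(x, ...) {
  cat(sprintf("%d cells x %d trials\n", x$n_cells, x$n_trials))
  cat(sprintf("  CS fraction:            %.4f\n", x$cs_fraction))
  cat(sprintf("  mean normalized dur D:  %.4f\n", x$mean_D))
  cat(sprintf("  mean delta_ss | CS:     %+.3f spikes/s\n", x$mean_delta_cs))
  cat(sprintf("  mean delta_ss | no CS:  %+.3f spikes/s\n", x$mean_delta_nocs))
  invisible(x)
}

#' Theoretical per-trial CS probability
#'
#' Numerical integration of the upper normal tail over the uniform threshold:
#' \deqn{P(CS) = \frac{1}{s}\int_0^{s} \bar\Phi(t/\sigma_p)\, dt,}
#' the closed-form counterpart of the simulated CS fraction (about 0.0997 at
#' the default parameters). Serves as an independent check on the simulator.
#'
#' @param model A \code{\link{cs_model}}.
#' @return Probability that \code{p > t} on a trial.
#' @export
cs_probability_theoretical <- function(model) {
  s <- model$threshold_scale
  if (s == 0) return(0.5)  # p > 0 for half the seeds
  f <- function(t) stats::pnorm(t / model$prob_seed_sd, lower.tail = FALSE)
  stats::integrate(f, 0, s, rel.tol = 1e-10)$value / s
}
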