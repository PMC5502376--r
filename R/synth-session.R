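#' Instruction-paradigm specification
#'
#' Describes one block of smooth-pursuit direction-learning trials. Each
#' trial presents step-ramp target motion at \code{base_speed}; after
#' \code{instruction_onset} ms a \code{instruction_duration}-ms pulse of
#' orthogonal motion at \code{instruction_speed} is superimposed, in either
#' the cell's on- or off-direction for simple-spike firing. The paradigm
#' \code{kind} fixes the instruction-direction sequence: \code{"repeated"}
#' presents the off-direction on every trial, \code{"alternating"} strictly
#' alternates, \code{"random"} draws directions i.i.d. with
#' \code{P(on) = on_probability}.
#'
#' @param kind One of \code{"random"}, \code{"repeated"}, \code{"alternating"}.
#' @param n_trials Trials in the block (default 400 for random, 100 for
#'   repeated, 200 for alternating when left \code{NULL}).
#' @param on_probability P(on-direction) per trial in the random paradigm
#'   (default 0.5).
#' @param base_speed Ramp speed, deg/s (default 20).
#' @param instruction_speed Instructive pulse speed, deg/s (default 30).
#' @param instruction_onset Pulse onset, ms after target-motion onset
#'   (default 250).
#' @param instruction_duration Pulse duration, ms (default 400).
#' @param alternating_on_first Logical; does the alternating sequence start
#'   with an on-direction trial (default TRUE)?
#' @return Object of class \code{"paradigm_spec"}.
#' @export
paradigm_spec <- function(kind = c("random", "repeated", "alternating"),
                          n_trials = NULL,
                          on_probability = 0.5,
                          base_speed = 20,
                          instruction_speed = 30,
                          instruction_onset = 250,
                          instruction_duration = 400,
                          alternating_on_first = TRUE) {
  kind <- match.arg(kind)
  if (is.null(n_trials)) {
    n_trials <- switch(kind, random = 400L, repeated = 100L,
                       alternating = 200L)
  }
  stopifnot(n_trials >= 1, on_probability >= 0, on_probability <= 1,
            instruction_onset >= 0, instruction_duration > 0)
  structure(list(kind = kind,
                 n_trials = as.integer(n_trials),
                 on_probability = on_probability,
                 base_speed = base_speed,
                 instruction_speed = instruction_speed,
                 instruction_onset = instruction_onset,
                 instruction_duration = instruction_duration,
                 alternating_on_first = isTRUE(alternating_on_first)),
            class = "paradigm_spec")
}

#' Generator parameters for synthetic sessions
#'
#' Tunables of the synthetic-recording generator. Defaults emulate the
#' empirical random-paradigm regime: off-direction instructions evoke a CS
#' with probability 0.36 at a time uniform in the 75-175 ms window after
#' instruction onset, with duration drawn from a normal(8.4, 1.5) ms
#' truncated at 0. Simple-spike trains are Poisson at a per-trial rate level
#' of \code{baseline_rate} plus a learned component: a CS trial depresses the
#' next trial's level by \code{depression_gain}, a CS-less off trial
#' potentiates it by \code{potentiation_mean}, and the learned component
#' decays linearly to zero so that it is fully forgotten within
#' \code{forgetting_span} trials (span 2 = one-trial memory). Eye-velocity
#' traces carry an analogous learned anticipatory component of amplitude
#' \code{eye_learning_gain} in the direction of the previous instruction.
#'
#' @param cs_probability Per-off-trial CS probability (default 0.36).
#' @param cs_window Length-2 ms interval after instruction onset in which CS
#'   responses occur (default \code{c(75, 175)}).
#' @param cs_duration_mean,cs_duration_sd CS duration distribution, ms
#'   (defaults 8.4 and 1.5).
#' @param baseline_rate Baseline simple-spike rate, spikes/s (default 60).
#' @param depression_gain,potentiation_mean Learned rate changes, spikes/s
#'   (defaults 5.5 and 1.7).
#' @param rate_noise_sd SD of trial-to-trial rate-level noise, spikes/s
#'   (default 5).
#' @param eye_learning_gain Learned eye-velocity amplitude per instruction,
#'   deg/s (default 1).
#' @param forgetting_span Trials over which learning decays to zero
#'   (default 2).
#' @param trial_ms Trace length per trial, ms from target-motion onset
#'   (default 700).
#' @param rng_seed Integer seed.
#' @return Object of class \code{"gen_params"}.
#' @export
gen_params <- function(cs_probability = 0.36,
                       cs_window = c(75, 175),
                       cs_duration_mean = 8.4,
                       cs_duration_sd = 1.5,
                       baseline_rate = 60,
                       depression_gain = 5.5,
                       potentiation_mean = 1.7,
                       rate_noise_sd = 5,
                       eye_learning_gain = 1,
                       forgetting_span = 2L,
                       trial_ms = 700L,
                       rng_seed = 1L) {
  stopifnot(cs_probability >= 0, cs_probability <= 1,
            length(cs_window) == 2, cs_window[1] < cs_window[2],
            cs_duration_sd >= 0, baseline_rate >= 0, rate_noise_sd >= 0,
            forgetting_span >= 1, trial_ms > 0)
  structure(list(cs_probability = cs_probability,
                 cs_window = as.numeric(cs_window),
                 cs_duration_mean = cs_duration_mean,
                 cs_duration_sd = cs_duration_sd,
                 baseline_rate = baseline_rate,
                 depression_gain = depression_gain,
                 potentiation_mean = potentiation_mean,
                 rate_noise_sd = rate_noise_sd,
                 eye_learning_gain = eye_learning_gain,
                 forgetting_span = as.integer(forgetting_span),
                 trial_ms = as.integer(trial_ms),
                 rng_seed = as.integer(rng_seed)),
            class = "gen_params")
}

#' Instruction-direction sequence for a paradigm
#'
#' @param spec A \code{\link{paradigm_spec}}.
#' @param seed Optional integer seed (random paradigm only).
#' @return Character vector of \code{"on"}/\code{"off"} of length
#'   \code{spec$n_trials}.
#' @export
make_instruction_sequence <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "paradigm_spec"))
  n <- spec$n_trials
  switch(spec$kind,
    repeated = rep("off", n),
    alternating = {
      base <- if (spec$alternating_on_first) c("on", "off") else c("off", "on")
      rep_len(base, n)
    },
    random = {
      if (!is.null(seed)) set.seed(as.integer(seed))
      ifelse(stats::runif(n) < spec$on_probability, "on", "off")
    },
    stop("unknown paradigm kind: ", spec$kind, call. = FALSE)
  )
}

# learned component carried into trial i from the outcomes of earlier trials,
# with linear decay: outcome of trial j contributes weight
# max(0, 1 - (i - j - 1)/(span - 1)); span 2 => only trial i-1 contributes.
forgetting_weights <- function(span) {
  if (span <= 1L) return(numeric(0))
  k <- seq_len(span - 1L)              # lags 1 .. span-1
  pmax(0, 1 - (k - 1) / (span - 1))
}

#' Generate a synthetic Purkinje-cell recording session
#'
#' Produces one trial-structured session with the statistical structure the
#' measurement pipeline assumes: an instruction-direction sequence, CS events
#' confined to off-direction trials inside the CS window, Poisson
#' simple-spike trains whose per-trial rate level carries CS-contingent
#' learning, and 1-ms eye-velocity traces with a learned anticipatory
#' component. CS events never occur on on-direction trials.
#'
#' The latent per-trial rate level (before spike generation) is returned in
#' the trial table as \code{rate_level}, so noise-free limits are testable.
#'
#' @param spec A \code{\link{paradigm_spec}}.
#' @param gen A \code{\link{gen_params}}.
#' @param seed Integer seed (default \code{gen$rng_seed}).
#' @return Object of class \code{"cs_session"}: a list with elements
#'   \code{trials} (data.frame: \code{trial}, \code{direction},
#'   \code{instruction_onset}, \code{cs}, \code{cs_time}, \code{cs_duration},
#'   \code{rate_level}, \code{eye_learn}), \code{spike_times} (list of numeric
#'   vectors, ms), \code{eye_velocity} (matrix, trials x ms samples),
#'   \code{times} (sample times, ms from target-motion onset), \code{spec},
#'   \code{gen}.
#' @export
generate_session <- function(spec, gen = gen_params(), seed = gen$rng_seed) {
  stopifnot(inherits(spec, "paradigm_spec"), inherits(gen, "gen_params"))
  set.seed(as.integer(seed))
  n <- spec$n_trials
  onset <- spec$instruction_onset
  if (onset + gen$cs_window[2] > gen$trial_ms)
    stop("CS window extends beyond the trial trace", call. = FALSE)
  if (onset < 100 || onset + 400 > gen$trial_ms)
    stop("traces must cover -100..+400 ms around instruction onset",
         call. = FALSE)

  direction <- make_instruction_sequence(spec)
  cs <- direction == "off" & stats::runif(n) < gen$cs_probability
  cs_time <- ifelse(cs, onset + stats::runif(n, gen$cs_window[1],
                                             gen$cs_window[2]), NA_real_)
  cs_duration <- rep(NA_real_, n)
  if (any(cs)) {
    draw_trunc <- function(m) {
      x <- stats::rnorm(m, gen$cs_duration_mean, gen$cs_duration_sd)
      while (any(x <= 0))
        x[x <= 0] <- stats::rnorm(sum(x <= 0), gen$cs_duration_mean,
                                  gen$cs_duration_sd)
      x
    }
    cs_duration[cs] <- draw_trunc(sum(cs))
  }

  # per-trial learning outcome delta_j (applies to subsequent trials)
  outcome <- ifelse(direction == "off",
                    ifelse(cs, -gen$depression_gain, gen$potentiation_mean),
                    0)
  # learned components for rate and eye via the forgetting kernel
  w <- forgetting_weights(gen$forgetting_span)
  learn_rate <- numeric(n)
  eye_learn <- numeric(n)
  eye_sign <- ifelse(direction == "off", -1, 1)  # instruction direction sign
  for (i in seq_len(n)) {
    for (k in seq_along(w)) {
      j <- i - k
      if (j >= 1) {
        learn_rate[i] <- learn_rate[i] + w[k] * outcome[j]
        eye_learn[i] <- eye_learn[i] +
          w[k] * gen$eye_learning_gain * eye_sign[j]
      }
    }
  }
  rate_level <- pmax(0, gen$baseline_rate + learn_rate +
                       stats::rnorm(n, 0, gen$rate_noise_sd))

  # Poisson spike trains at the per-trial rate level
  spike_times <- vector("list", n)
  for (i in seq_len(n)) {
    m <- stats::rpois(1, rate_level[i] * gen$trial_ms / 1000)
    spike_times[[i]] <- sort(stats::runif(m, 0, gen$trial_ms))
  }

  # eye-velocity traces: base pursuit profile plus learned anticipatory ramp
  times <- 0:gen$trial_ms
  base <- numeric(length(times))
  react <- times >= onset + 80  # reactive response, well after the window
  ramp_len <- 100
  base[react] <- pmin(1, (times[react] - onset - 80) / ramp_len) *
    spec$instruction_speed
  eye <- matrix(0, n, length(times))
  learn_ramp <- pmin(1, pmax(0, (times - (onset - 100)) / 200))
  for (i in seq_len(n)) {
    eye[i, ] <- base * eye_sign[i] + eye_learn[i] * learn_ramp
  }

  trials <- data.frame(trial = seq_len(n) - 1L,
                       direction = direction,
                       instruction_onset = onset,
                       cs = cs,
                       cs_time = cs_time,
                       cs_duration = cs_duration,
                       rate_level = rate_level,
                       eye_learn = eye_learn)
  structure(list(trials = trials, spike_times = spike_times,
                 eye_velocity = eye, times = times, spec = spec, gen = gen),
            class = "cs_session")
}

#' @export
print.cs_session <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("cs_session: %s paradigm, %d trials (%d off, %d CS)\n",
              x$spec$kind, nrow(tr), sum(tr$direction == "off"), sum(tr$cs)))
  cat(sprintf("  instruction onset %d ms; traces 0..%d ms at 1 kHz\n",
              x$spec$instruction_onset, x$gen$trial_ms))
  invisible(x)
}

#' Write / read a session as plain-text files
#'
#' \code{write_session()} writes a session to a directory as a CSV trial
#' table, a JSON file of per-trial spike times and CS events, a CSV matrix of
#' eye-velocity traces, and a manifest JSON tying them together.
#' \code{read_session()} reconstructs the session from such a directory.
#'
#' @param session A \code{\link{generate_session}} result.
#' @param dir Output directory (created if needed).
#' @return \code{write_session}: the directory, invisibly.
#'   \code{read_session}: a \code{"cs_session"} object.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "cs_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  ev <- list(spike_times = session$spike_times,
             cs_events = lapply(seq_len(nrow(session$trials)), function(i) {
               if (isTRUE(session$trials$cs[i]))
                 list(time = session$trials$cs_time[i],
                      duration = session$trials$cs_duration[i])
               else list()
             }))
  jsonlite::write_json(ev, file.path(dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(session$eye_velocity),
                   file.path(dir, "eye_velocity.csv"), row.names = FALSE)
  manifest <- list(format = "cs_session", version = 1L,
                   files = c("trials.csv", "events.json", "eye_velocity.csv"),
                   times = range(session$times),
                   spec = unclass(session$spec),
                   gen = unclass(session$gen))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  if (!identical(man$format, "cs_session") || !identical(man$version, 1L))
    stop("unrecognized session format/version in manifest", call. = FALSE)
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  ev <- jsonlite::read_json(file.path(dir, "events.json"),
                            simplifyVector = TRUE)
  spikes <- lapply(ev$spike_times, as.numeric)
  eye <- as.matrix(utils::read.csv(file.path(dir, "eye_velocity.csv")))
  dimnames(eye) <- NULL
  spec <- do.call(paradigm_spec, man$spec[setdiff(names(man$spec), NULL)])
  gen <- do.call(gen_params, man$gen)
  structure(list(trials = trials, spike_times = spikes, eye_velocity = eye,
                 times = man$times[1]:man$times[2], spec = spec, gen = gen),
            class = "cs_session")
}
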