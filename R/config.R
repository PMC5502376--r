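#' Load and validate a run configuration
#'
#' Reads a flat key-value configuration file (JSON or YAML, by file
#' extension) for one of the pipeline subcommands. Keys mirror the argument
#' names of the corresponding constructors (\code{\link{cs_model}} for
#' \code{"simulate"} and \code{"sweep"}; \code{\link{paradigm_spec}} and
#' \code{\link{gen_params}} for \code{"synth"}; analysis options for
#' \code{"analyze"} and \code{"stats"}). Unknown keys are rejected by name;
#' missing keys take the package defaults; out-of-range values raise the
#' constructor's range error.
#'
#' @param path Path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @param subcommand One of \code{"simulate"}, \code{"synth"},
#'   \code{"analyze"}, \code{"stats"}, \code{"sweep"}.
#' @return List of class \code{"cs_config"} with elements \code{subcommand}
#'   and the resolved parameter objects/options.
#' @export
cs_load_config <- function(path, subcommand = c("simulate", "synth",
                                                "analyze", "stats",
                                                "sweep")) {
  subcommand <- match.arg(subcommand)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e)
                      stop("config parse failure (JSON): ",
                           conditionMessage(e), call. = FALSE)),
    yaml = ,
    yml = tryCatch(yaml::read_yaml(path),
                   error = function(e)
                     stop("config parse failure (YAML): ",
                          conditionMessage(e), call. = FALSE)),
    stop("config must be .json, .yaml or .yml", call. = FALSE))
  if (is.null(raw)) raw <- list()
  cs_resolve_config(raw, subcommand)
}

#' @rdname cs_load_config
#' @param values Named list of raw key-value settings (as from a parsed
#'   file); used directly by \code{cs_resolve_config}.
#' @export
cs_resolve_config <- function(values = list(), subcommand) {
  known <- switch(subcommand,
    simulate = names(formals(cs_model)),
    sweep = c(names(formals(cs_model)), "r_values", "temporal_corr_values",
              "replicates", "contour_level"),
    synth = c(names(formals(paradigm_spec)), names(formals(gen_params))),
    analyze = c("direction", "group_size", "what", "learning_window",
                "cs_window", "cs_bin_width"),
    stats = c("analysis", "group_size", "n_control", "noise_variance",
              "reps", "n_comparisons"))
  unknown <- setdiff(names(values), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- list(subcommand = subcommand)
  if (subcommand %in% c("simulate", "sweep")) {
    cfg$model <- do.call(cs_model,
                         values[intersect(names(values),
                                          names(formals(cs_model)))])
    if (subcommand == "sweep") {
      cfg$r_values <- values$r_values %||% seq(0, 1, by = 0.1)
      cfg$temporal_corr_values <- values$temporal_corr_values %||%
        seq(0, 1, by = 0.1)
      cfg$replicates <- values$replicates %||% 20L
      cfg$contour_level <- values$contour_level %||% 0.1
    }
  } else if (subcommand == "synth") {
    cfg$spec <- do.call(paradigm_spec,
                        values[intersect(names(values),
                                         names(formals(paradigm_spec)))])
    cfg$gen <- do.call(gen_params,
                       values[intersect(names(values),
                                        names(formals(gen_params)))])
  } else if (subcommand == "analyze") {
    cfg$direction <- values$direction %||% "off"
    cfg$what <- values$what %||% "rate"
    cfg$windows <- analysis_windows(
      learning_window = values$learning_window %||% c(-100, 50),
      cs_window = values$cs_window %||% c(75, 175),
      cs_bin_width = values$cs_bin_width %||% 100,
      group_size = values$group_size %||% 10L)
  } else if (subcommand == "stats") {
    cfg$analysis <- values$analysis %||% "bincorr"
    cfg$group_size <- values$group_size %||% 10L
    cfg$n_control <- values$n_control %||% 10L
    cfg$noise_variance <- values$noise_variance %||% 20
    cfg$reps <- values$reps %||% 1000L
    cfg$n_comparisons <- values$n_comparisons %||% 3L
  }
  class(cfg) <- "cs_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one pipeline step and write its artifacts
#'
#' Executes a subcommand (\code{simulate}, \code{synth}, \code{analyze},
#' \code{stats}, \code{sweep}) and writes its outputs to \code{out_dir}
#' together with a resolved-configuration JSON and a manifest listing the
#' outputs with their MD5 checksums. Runs are deterministic: the same
#' configuration and seed reproduce byte-identical outputs.
#'
#' Outputs by subcommand: \code{simulate} writes \code{trials.csv} (columns
#' \code{cell}, \code{trial}, \code{p}, \code{t}, \code{cs}, \code{d_ms},
#' \code{D}, \code{delta_ss}); \code{synth} writes a session directory (see
#' \code{\link{write_session}}); \code{analyze} (on a session directory
#' given via \code{input}) writes \code{pairs.csv}, \code{bins.csv} and
#' \code{curves.csv}; \code{stats} (on a bins table) writes
#' \code{correlations.csv}; \code{sweep} writes \code{sweep.json} with the
#' grid and contour.
#'
#' @param config A \code{"cs_config"} (or a config file path).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional integer overriding the configured RNG seed.
#' @param input Input directory/file for \code{analyze}/\code{stats}.
#' @return \code{out_dir}, invisibly.
#' @export
cs_run <- function(config, out_dir, seed = NULL, input = NULL) {
  if (is.character(config) && length(config) == 1)
    stop("pass the result of cs_load_config(), not a path", call. = FALSE)
  stopifnot(inherits(config, "cs_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  sub <- config$subcommand

  if (sub == "simulate") {
    model <- config$model
    if (!is.null(seed)) model$rng_seed <- as.integer(seed)
    pop <- simulate(model)
    tab <- data.frame(cell = pop$cell, trial = pop$trial, p = pop$p,
                      t = pop$t, cs = pop$cs, d_ms = pop$d, D = pop$D,
                      delta_ss = pop$delta_ss)
    f <- file.path(out_dir, "trials.csv")
    write_csv9(tab, f)
    outputs <- f
  } else if (sub == "synth") {
    gen <- config$gen
    if (!is.null(seed)) gen$rng_seed <- as.integer(seed)
    session <- generate_session(config$spec, gen)
    write_session(session, out_dir)
    outputs <- file.path(out_dir, c("trials.csv", "events.json",
                                    "eye_velocity.csv", "manifest.json"))
  } else if (sub == "analyze") {
    if (is.null(input)) stop("'analyze' needs a session directory as input",
                             call. = FALSE)
    session <- read_session(input)
    pairs <- pair_trials(session, direction = config$direction,
                         windows = config$windows)
    pairs <- pair_changes(session, pairs, what = config$what,
                          windows = config$windows)
    bins <- bin_groups(pairs, config$windows$group_size)
    curves <- cs_probability_curve(session,
                                   bin_width = config$windows$cs_bin_width)
    fp <- file.path(out_dir, "pairs.csv")
    fb <- file.path(out_dir, "bins.csv")
    fc <- file.path(out_dir, "curves.csv")
    write_csv9(pairs, fp); write_csv9(bins, fb); write_csv9(curves, fc)
    outputs <- c(fp, fb, fc)
  } else if (sub == "stats") {
    if (is.null(input)) stop("'stats' needs a bins.csv as input",
                             call. = FALSE)
    bins <- utils::read.csv(input)
    if (!is.null(seed)) set.seed(as.integer(seed))
    res <- switch(config$analysis,
      bincorr = {
        r <- binned_duration_probability_correlation(bins)
        data.frame(analysis = "bincorr", r = r$r, n = r$n)
      },
      partial = {
        pr <- partial_correlations(bins)
        data.frame(analysis = "partial", partial_prob = pr["prob"],
                   partial_dur = pr["dur"])
      },
      stop("unknown stats analysis: ", config$analysis, call. = FALSE))
    f <- file.path(out_dir, "correlations.csv")
    write_csv9(res, f)
    outputs <- f
  } else if (sub == "sweep") {
    model <- config$model
    if (!is.null(seed)) model$rng_seed <- as.integer(seed)
    sw <- sweep_measured_correlation(
      model, r_values = config$r_values,
      temporal_corr_values = config$temporal_corr_values,
      replicates = config$replicates, contour_level = config$contour_level)
    f <- file.path(out_dir, "sweep.json")
    jsonlite::write_json(
      list(r_values = sw$r_values,
           temporal_corr_values = sw$temporal_corr_values,
           grid = sw$grid, se = sw$se, contour = sw$contour),
      f, digits = NA, na = "null")
    outputs <- f
  }

  cfgf <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(config_as_list(config), cfgf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  manf <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(
    list(subcommand = sub,
         outputs = data.frame(file = basename(outputs),
                              md5 = unname(tools::md5sum(outputs)))),
    manf, auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

config_as_list <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(cfg)
}

# CSV writer guaranteeing >= 9 significant digits on numeric columns
write_csv9 <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 12, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
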