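# Configuration schema: every physical quantity carries its unit in the
# field name (seconds, Hz, ms). `default = NULL` entries are filled at
# execution time from the experiment drivers' own defaults.
config_fields <- function() {
  list(
    experiment = list(kind = "enum", required = TRUE,
                      values = c("exp1", "exp2_solo", "exp2_duet", "exp3",
                                 "sweep", "classify")),
    profile = list(kind = "enum", default = "musician",
                   values = c("musician", "nonmusician")),
    feedback = list(kind = "enum", default = "on", values = c("on", "off")),
    kind = list(kind = "enum", default = "sinusoid",
                values = c("sinusoid", "square_wave")),
    ioi_list_ms = list(kind = "numvec", default = seq(1000, 3500, by = 250),
                       min = 1),
    duration_s = list(kind = "num", default = 20, min = 0.01),
    cycles = list(kind = "num", default = 20, min = 2),
    dt_s = list(kind = "num", default = 0.001, min = 1e-6),
    tl_list_ms = list(kind = "numvec", default = c(0, 10, 20, 39, 58, 78),
                      min = 0),
    delta_hz = list(kind = "num", default = 0),
    f_hz = list(kind = "num", default = 1, min = 1e-6),
    A = list(kind = "num", default = -0.5),
    tau_s = list(kind = "num", default = 0.222, min = 0),
    D = list(kind = "num", default = 1, min = 0),
    D_grid = list(kind = "numvec", default = seq(0, 1, by = 0.05), min = 0),
    tau_grid = list(kind = "numvec", default = seq(0, 0.5, length.out = 27),
                    min = 0),
    normalize = list(kind = "flag", default = TRUE),
    warmup_turns = list(kind = "num", default = 3, min = 0),
    literal_joiner_sign = list(kind = "flag", default = FALSE),
    out = list(kind = "path", default = NULL),
    trajectory_out = list(kind = "path", default = NULL),
    verbosity = list(kind = "enum", default = "info",
                     values = c("quiet", "info", "debug"))
  )
}

check_field <- function(name, value, rule) {
  fail <- function(msg) abort(sprintf("config field `%s`: %s", name, msg))
  switch(rule$kind,
    enum = {
      if (!is.character(value) || length(value) != 1L || !(value %in% rule$values)) {
        fail(sprintf("must be one of %s.",
                     paste(sprintf('"%s"', rule$values), collapse = ", ")))
      }
    },
    num = {
      if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
        fail("must be a single finite number.")
      }
      if (!is.null(rule$min) && value < rule$min) {
        fail(sprintf("must be >= %g.", rule$min))
      }
    },
    numvec = {
      if (!is.numeric(value) || length(value) < 1L || any(!is.finite(value))) {
        fail("must be a non-empty numeric vector of finite values.")
      }
      if (!is.null(rule$min) && any(value < rule$min)) {
        fail(sprintf("all values must be >= %g.", rule$min))
      }
    },
    flag = {
      if (!is.logical(value) || length(value) != 1L || is.na(value)) {
        fail("must be TRUE or FALSE.")
      }
    },
    path = {
      if (!is.character(value) || length(value) != 1L) {
        fail("must be a single path string.")
      }
    }
  )
  invisible(TRUE)
}

#' Load and validate a run configuration
#'
#' Reads a YAML file (or takes an inline named list), rejects unknown keys,
#' checks every field against the schema, and fills in defaults. The
#' resulting configuration round-trips losslessly through
#' [serialize_config()].
#'
#' @param x Path to a YAML file, or a named list.
#' @return A validated `run_config` (named list).
#' @examples
#' cfg <- load_config(list(experiment = "exp1", profile = "musician"))
#' cfg$dt_s  # 0.001, the default
#' @export
load_config <- function(x) {
  raw <- if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(sprintf("config file not found: %s", x))
    yaml::read_yaml(x)
  } else if (is.list(x)) {
    x
  } else {
    abort("`x` must be a file path or a named list.")
  }
  schema <- config_fields()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s",
                  paste(sprintf("`%s`", unknown), collapse = ", ")))
  }
  for (req in names(schema)[vapply(schema, function(r) isTRUE(r$required), logical(1))]) {
    if (is.null(raw[[req]])) abort(sprintf("missing required config key `%s`.", req))
  }
  cfg <- list()
  for (nm in names(schema)) {
    rule <- schema[[nm]]
    value <- raw[[nm]]
    if (is.null(value)) value <- rule$default
    if (!is.null(value)) check_field(nm, value, rule)
    cfg[[nm]] <- value
  }
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' @param config A `run_config` from [load_config()].
#' @param path Optional file to write; when `NULL` the YAML text is
#'   returned.
#' @return The YAML string (invisibly when written to a file).
#' @export
serialize_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "run_config"))
  txt <- yaml::as.yaml(unclass(config), precision = 15L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Execute a validated run configuration
#'
#' Dispatches to the experiment and analysis drivers and collects their
#' summary tables.
#'
#' @param config A `run_config` from [load_config()].
#' @return A named list of tibbles (the run's summary tables), with the
#'   configuration attached as the `config` attribute.
#' @export
execute_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tables <- switch(config$experiment,
    exp1 = {
      res <- run_experiment1(profiles = config$profile,
                             feedback = config$feedback,
                             ioi_ms = config$ioi_list_ms,
                             kind = config$kind,
                             cycles = config$cycles, dt = config$dt_s)
      list(asynchrony = as_tibble(res))
    },
    exp2_solo = {
      res <- run_experiment2_solo(profile = config$profile,
                                  feedback = config$feedback,
                                  duration_s = config$duration_s,
                                  dt = config$dt_s)
      list(asynchrony = tibble(profile = config$profile,
                               feedback = config$feedback,
                               ioi_ms = 1000,
                               glance(res)))
    },
    exp2_duet = {
      res <- run_experiment2_duet(profile = config$profile,
                                  feedback = config$feedback,
                                  duration_s = config$duration_s,
                                  dt = config$dt_s,
                                  normalize = config$normalize)
      list(asynchrony = bind_rows(
        tibble(profile = config$profile, feedback = config$feedback,
               model = 1L, glance(res$model1)),
        tibble(profile = config$profile, feedback = config$feedback,
               model = 2L, glance(res$model2))
      ))
    },
    exp3 = {
      res <- run_experiment3(profile = config$profile,
                             tl_ms = config$tl_list_ms,
                             delta_hz = config$delta_hz,
                             duration_s = config$duration_s,
                             warmup_turns = config$warmup_turns,
                             dt = config$dt_s,
                             literal_joiner_sign = config$literal_joiner_sign)
      list(
        leadlag = dplyr::select(res$per_turn, "tl_ms", "turn", "L_ms",
                                "fraction", "percent"),
        summary = mutate(res$summary, slope_per_ms = res$slope_per_ms)
      )
    },
    sweep = {
      res <- sweep_asynchrony(A = config$A, f = config$f_hz,
                              D_grid = config$D_grid,
                              tau_grid = config$tau_grid,
                              cycles = config$cycles, dt = config$dt_s)
      list(sweep = as_tibble(res))
    },
    classify = {
      params <- oscillator_params(f = config$f_hz, D = config$D,
                                  tau = config$tau_s, A = config$A)
      fb <- if (config$A == 0) "off" else "constant_self"
      spec <- stimulus_spec("sinusoid", fs = config$f_hz, feedback_mode = fb)
      res <- classify_attractor(params, spec, dt = config$dt_s)
      list(classification = tibble(
        verdict = res$verdict,
        init_phase = seq(0, 2 * pi, length.out = 9L)[-9L],
        terminal_phase = res$terminal_phase,
        looping = res$looping
      ))
    }
  )
  attr(tables, "config") <- config
  tables
}

#' Write run results and a manifest
#'
#' Writes each summary table as a CSV file with a fixed column order and a
#' JSON run manifest (configuration echo, package version, timestamp)
#' alongside. The output directory is checked for writability before
#' anything is written.
#'
#' @param tables Named list of data frames (e.g. from [execute_run()]).
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to echo into the manifest; defaults
#'   to the `config` attribute of `tables`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, dir, config = attr(tables, "config")) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, mode = 2L) != 0L) {
    abort(sprintf("output directory is not writable: %s", dir))
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- list(
    config = if (!is.null(config)) unclass(config) else NULL,
    package = "sappa",
    version = as.character(utils::packageVersion("sappa")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, mp)
  invisible(paths)
}
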