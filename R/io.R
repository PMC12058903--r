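#' Save gridded fields to CSV
#'
#' Writes the fields of a state (and optionally the environment) in long
#' format, one row per cell, with coordinate columns `x1` (and `x2` in 2D)
#' and variable columns `n`, `q`, `v` (plus `Q`, `K` when an environment is
#' supplied). The format round-trips losslessly through [load_fields].
#'
#' @param state a [population_state].
#' @param grid a [habitat_grid].
#' @param path output file path.
#' @param env optional [environment_field] whose `Q` and `K` are included.
#' @return `path`, invisibly.
#' @export
save_fields <- function(state, grid, path, env = NULL) {
  df <- data.frame(x1 = as.vector(grid$X1))
  if (grid$m == 2L) df$x2 <- as.vector(grid$X2)
  df$n <- as.vector(state$n)
  df$q <- as.vector(state$q)
  df$v <- as.vector(state$v)
  if (!is.null(env)) {
    df$Q <- as.vector(env$Q)
    df$K <- as.vector(env$K)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load gridded fields from CSV
#'
#' Reads a long-format field file written by [save_fields] and validates
#' its schema against the grid. A missing required column raises an error
#' naming the variable.
#'
#' @param path CSV file path.
#' @param grid the [habitat_grid] the fields live on.
#' @param t time tag to attach to the returned state.
#' @return list with `state` (a [population_state]) and, when present in
#'   the file, `Q` and `K` fields.
#' @export
load_fields <- function(path, grid, t = 0) {
  df <- utils::read.csv(path)
  needed <- c("x1", if (grid$m == 2L) "x2", "n", "q", "v")
  for (nm in needed) {
    if (!nm %in% names(df))
      stop("field file is missing required variable '", nm, "'")
  }
  if (nrow(df) != prod(grid$nx))
    stop("field file has ", nrow(df), " rows; grid expects ", prod(grid$nx))
  shape <- function(x) matrix(x, grid$nx[1], grid$nx[2])
  out <- list(state = population_state(shape(df$n), shape(df$q), shape(df$v),
                                       t = t, grid = grid))
  if ("Q" %in% names(df)) out$Q <- shape(df$Q)
  if ("K" %in% names(df)) out$K <- shape(df$K)
  out
}

#' Read a run configuration
#'
#' Parses a YAML run configuration describing a scenario, parameter
#' overrides, grid, solver options and outputs. Unknown top-level keys are
#' rejected so that typos cannot silently change a run.
#'
#' @param path YAML file path.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("scenario", "params", "grid", "solver", "schedule",
             "fragmentation", "gradient", "seed", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$scenario)) stop("configuration must name a scenario")
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

config_params <- function(cfg) do.call(model_params, as.list(cfg$params))

config_solver <- function(cfg, defaults = list()) {
  args <- utils::modifyList(defaults, as.list(cfg$solver))
  do.call(solver_options, args)
}

#' Execute a configured run
#'
#' Dispatches on the configured scenario (`expansion`, `fluctuation`,
#' `fragmented` or `equilibrium`), executes it, and writes the requested
#' outputs: final-state fields as CSV, a one-row metrics CSV for dynamic
#' runs (or the sweep table for `equilibrium`), and a small provenance log.
#'
#' @param config a `run_config` (or path to one).
#' @param out_dir output directory (created if needed); overrides the
#'   configuration's `output` entry.
#' @return the computed object (a `trajectory` or a sweep data frame),
#'   invisibly.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$output %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(config)
  slope <- config$gradient %||% 0.2

  result <- switch(
    config$scenario,
    expansion = {
      grid <- habitat_grid(c(config$grid$a %||% -50, config$grid$b %||% 50),
                           nx = config$grid$nx %||% 400)
      env <- linear_optimum(grid, slope, params = params)
      s0 <- expansion_initial_state(grid, env)
      integrate_model(s0, env, params, grid, config_solver(config))
    },
    fluctuation = {
      grid <- habitat_grid(c(config$grid$a %||% -50, config$grid$b %||% 50),
                           nx = config$grid$nx %||% 400)
      env <- linear_optimum(grid, slope, params = params)
      sched <- shift_schedule(config$schedule$period %||% 2,
                              config$schedule$amplitude %||% 5)
      s0 <- fluctuation_initial_state(grid, env, params)
      integrate_model(s0, env, params, grid,
                      config_solver(config, list(record_every = 0.25)),
                      schedule = sched)
    },
    fragmented = {
      spec <- do.call(fragmentation_spec,
                      utils::modifyList(list(seed = config$seed %||% 1L),
                                        as.list(config$fragmentation)))
      sc <- fragmented_scenario(params, nx = config$grid$nx %||% 200,
                                spec = spec, slope = config$gradient %||% 1)
      traj <- integrate_model(sc$state0, sc$env, params, sc$grid,
                              config_solver(config))
      traj$central_box <- sc$central_box
      traj
    },
    equilibrium = equilibrium_sweep(params),
    stop("unknown scenario '", config$scenario, "'")
  )

  if (inherits(result, "trajectory")) {
    save_fields(final_state(result), result$grid,
                file.path(out_dir, "final_state.csv"), env = result$env)
    if (result$grid$m == 1L)
      utils::write.csv(run_metrics(result),
                       file.path(out_dir, "metrics.csv"), row.names = FALSE)
  } else {
    utils::write.csv(result, file.path(out_dir, "equilibrium.csv"),
                     row.names = FALSE)
  }
  writeLines(c(sprintf("scenario: %s", config$scenario),
               sprintf("package: optidisp %s",
                       as.character(utils::packageVersion("optidisp"))),
               sprintf("R: %s", R.version.string)),
             file.path(out_dir, "provenance.txt"))
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
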