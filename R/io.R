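#' Write a trajectory to CSV
#'
#' One row per recorded generation with the fixed schema `generation,
#' mean_C, q10_C, q90_C, mean_E, N, R` (plus `mean_T` when the automatic
#' habit evolves). Round-trips losslessly through [read_trajectory()].
#'
#' @param traj A `dualproc_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj) || !nrow(traj))
    stop("trajectory is empty", call. = FALSE)
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path.
#' @param extinct Extinction flag to attach (recorded in the run manifest,
#'   not in the CSV).
#' @return A `dualproc_trajectory`.
#' @export
read_trajectory <- function(path, extinct = FALSE) {
  traj <- utils::read.csv(path)
  class(traj) <- c("dualproc_trajectory", "data.frame")
  attr(traj, "extinct") <- extinct
  traj
}

#' @export
print.dualproc_trajectory <- function(x, ...) {
  cat("Trajectory (", attr(x, "scenario") %||% "?", "): ", nrow(x),
      " generations", if (isTRUE(attr(x, "extinct"))) " [EXTINCT]", "\n",
      sep = "")
  cat("  final: mean C =", format(x$mean_C[nrow(x)], digits = 4),
      ", mean E =", format(x$mean_E[nrow(x)], digits = 4),
      ", N =", x$N[nrow(x)], ", R =", x$R[nrow(x)], "\n")
  invisible(x)
}

#' Plot a trajectory
#'
#' Two stacked panels: mean control (with the 10-90% trait band) over
#' generations, and the coupled state variable (population size or
#' richness, whichever varies; both are flat in fixed runs).
#'
#' @param x A `dualproc_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dualproc_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$generation, x$mean_C, type = "l", ylim = c(0, 1),
                 xlab = "generation", ylab = "mean C", ...)
  graphics::polygon(c(x$generation, rev(x$generation)),
                    c(x$q10_C, rev(x$q90_C)),
                    border = NA, col = grDevices::adjustcolor("grey", 0.5))
  graphics::lines(x$generation, x$mean_C)
  varN <- length(unique(x$N)) > 1L
  y2 <- if (varN) x$N else x$R
  graphics::plot(x$generation, y2, type = "l", xlab = "generation",
                 ylab = if (varN) "N" else "R")
  invisible(x)
}

#' Summarize a run
#'
#' Condenses a trajectory into its equilibrium mean control (average over
#' the final 10% of generations; `NA` for extinct runs), the peak mean
#' control and when it occurred, the final population size and richness,
#' the extinction flag, and [detect_limit_cycle()] statistics.
#'
#' @param traj A `dualproc_trajectory`.
#' @param equilibrium_window Final fraction of generations averaged for
#'   the equilibrium value.
#' @param ... Passed to [detect_limit_cycle()].
#' @return A list of class `run_summary`.
#' @export
summarize_run <- function(traj, equilibrium_window = 0.1, ...) {
  if (is.null(traj) || !nrow(traj))
    stop("trajectory is empty", call. = FALSE)
  n <- nrow(traj)
  extinct <- isTRUE(attr(traj, "extinct"))
  tail_idx <- seq.int(max(1L, n - ceiling(equilibrium_window * n) + 1L), n)
  peak <- which.max(traj$mean_C)
  cycles <- if (n >= 7L) tryCatch(detect_limit_cycle(traj, ...),
                                  error = function(e) NULL)
  structure(list(
    equilibrium_mean_C = if (extinct) NA_real_ else
      mean(traj$mean_C[tail_idx]),
    peak_mean_C = traj$mean_C[peak],
    peak_generation = traj$generation[peak],
    final_N = traj$N[n], final_R = traj$R[n],
    generations = traj$generation[n], extinct = extinct,
    cycles = cycles
  ), class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Run summary:", x$generations, "generations",
      if (x$extinct) "[EXTINCT]", "\n")
  cat("  equilibrium mean C:",
      if (is.na(x$equilibrium_mean_C)) "undefined (extinct)"
      else format(x$equilibrium_mean_C, digits = 4), "\n")
  cat("  peak mean C:", format(x$peak_mean_C, digits = 4),
      "at generation", x$peak_generation, "\n")
  cat("  final N:", x$final_N, ", final R:", x$final_R, "\n")
  if (!is.null(x$cycles)) print(x$cycles)
  invisible(x)
}

# known configuration keys, their section, and validators
.config_schema <- function() {
  list(
    scenario = list(ok = function(v) v %in% c("fixed", "variable_N",
                                              "variable_R")),
    seed = list(ok = function(v) is.numeric(v) && v >= 0),
    N = list(ok = function(v) is.numeric(v) && v >= 1),
    generations = list(ok = function(v) is.numeric(v) && v >= 1),
    R = list(ok = function(v) is.numeric(v) && v >= 0 && v <= 1),
    drain = list(ok = function(v) is.numeric(v) && v > 0),
    rho = list(ok = function(v) is.numeric(v) && v > 0),
    E_max = list(ok = function(v) is.numeric(v) && v > 0),
    u = list(ok = function(v) is.numeric(v) && v > 0),
    kappa = list(ok = function(v) is.numeric(v) && v >= 0),
    w_auto = list(ok = function(v) is.numeric(v) && v > 0.5 && v <= 1),
    contest_form = list(ok = function(v) v %in% c("linear", "saturating")),
    n_E = list(ok = function(v) is.numeric(v) && v >= 2),
    n_S = list(ok = function(v) is.numeric(v) && v >= 2),
    S_cap = list(ok = function(v) is.numeric(v) && v > 0),
    n_x = list(ok = function(v) is.numeric(v) && v >= 2),
    gamma = list(ok = function(v) is.numeric(v) && v > 0 && v < 1),
    n_p = list(ok = function(v) is.numeric(v) && v >= 2),
    lambda = list(ok = function(v) is.numeric(v) && v > 0 && v < 1),
    mutation_rate = list(ok = function(v) is.numeric(v) && v >= 0 && v <= 1),
    mutation_step = list(ok = function(v) is.numeric(v) && v > 0),
    T_N = list(ok = is.numeric),
    T_R = list(ok = is.numeric),
    epsilon = list(ok = function(v) is.numeric(v) && v >= 0),
    delta_N = list(ok = function(v) is.numeric(v) && v >= 0),
    delta_R = list(ok = function(v) is.numeric(v) && v > 0),
    N_0 = list(ok = function(v) is.numeric(v) && v >= 1),
    R_0 = list(ok = function(v) is.numeric(v) && v > 0 && v <= 1),
    out = list(ok = is.character)
  )
}

#' Load and validate a run configuration
#'
#' Reads a flat JSON key-value file, rejects unknown keys, validates every
#' value against the documented constraint (error messages name the
#' offending key), and fills defaults. The result bundles ready-to-use
#' parameter objects for the other modules.
#'
#' Recognized keys: `scenario`, `seed`, `N`, `generations`, `R`, `drain`,
#' `rho`, `E_max`, `u`, `kappa`, `w_auto`, `contest_form`, `n_E`, `n_S`,
#' `S_cap`, `n_x`, `gamma`, `n_p`, `lambda`, `mutation_rate`,
#' `mutation_step`, `T_N`, `T_R`, `epsilon`, `delta_N`, `delta_R`, `N_0`,
#' `R_0`, `out`.
#'
#' @param path Path of the JSON configuration file.
#' @return An object of class `run_config` with elements `scenario`,
#'   `seed`, `N`, `generations`, `environment`, `competition`, `grid`,
#'   `mutation`, `feedback` (when thresholds are given), `gamma`, `n_p`,
#'   `lambda`, `out`, and the raw key-value list `raw`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- .config_schema()
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(raw)) {
    v <- raw[[k]]
    if (!isTRUE(schema[[k]]$ok(v)))
      stop("invalid value for config key '", k, "'", call. = FALSE)
  }
  get <- function(k, default) raw[[k]] %||% default

  env <- environment_params(
    R = get("R", 0.005), drain = get("drain", 1),
    rho = get("rho", 10 * get("drain", 1)),
    E_max = get("E_max", 100 * get("drain", 1)), u = get("u", 50))
  comp <- competition_model(kappa = get("kappa", 0.01),
                            w_auto = get("w_auto", 1),
                            form = get("contest_form", "linear"))
  grid <- grid_spec(n_E = get("n_E", 51L), n_S = get("n_S", 26L),
                    S_cap = get("S_cap", 50), n_x = get("n_x", 21L))
  mut <- mutation_params(rate = get("mutation_rate", 0.05),
                         step = get("mutation_step", 0.02))
  fb <- NULL
  if (!is.null(raw$T_N) || !is.null(raw$T_R))
    fb <- feedback_config(T_N = get("T_N", NA), T_R = get("T_R", NA),
                          N_0 = get("N_0", get("N", 100L)),
                          R_0 = get("R_0", env$R),
                          epsilon = raw$epsilon, delta_N = raw$delta_N,
                          delta_R = raw$delta_R)
  structure(list(
    scenario = get("scenario", "fixed"),
    seed = as.integer(get("seed", 1L)),
    N = as.integer(get("N", 100L)),
    generations = as.integer(get("generations", 5000L)),
    environment = env, competition = comp, grid = grid, mutation = mut,
    feedback = fb, gamma = get("gamma", 0.995), n_p = get("n_p", 21L),
    lambda = get("lambda", 0.01), out = get("out", NULL), raw = raw
  ), class = "run_config")
}

#' Write a run manifest
#'
#' JSON record that makes a run reproducible: the effective configuration,
#' package version, seed, timestamp, extinction note, and MD5 checksums of
#' the produced artifacts. Written atomically (temp file + rename).
#'
#' @param path Output JSON path.
#' @param config The effective configuration (any list-like object).
#' @param seed Integer seed used.
#' @param outputs Character vector of produced file paths to checksum.
#' @param extinct Logical extinction note (for trajectory runs).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs = character(),
                           extinct = FALSE) {
  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    package = "dualproc",
    version = as.character(utils::packageVersion("dualproc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    extinct = extinct,
    config = config,
    checksums = as.list(tools::md5sum(outputs))
  )
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
  invisible(path)
}
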