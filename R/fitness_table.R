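#' Build the fitness lookup table
#'
#' Precomputes fitness — lifetime mean energy — on a grid over the three
#' determinants of an agent's success: its control propensity `C`, its
#' automatic-mode access probability `p_auto`, and its controlled-mode
#' access probability `p_ctrl`. Evolutionary runs then index this table
#' instead of re-simulating lifetimes. The total simulation budget `n_sims`
#' is split evenly across cells (at least one lifetime per cell). An
#' optional fourth axis `T_levels` extends the table over the heritable
#' target level of the evolvable automatic habit.
#'
#' The reference build uses 30,000 lifetimes of 1,000 steps; scaled-down
#' builds preserve the table's ordering and monotonicity structure at
#' reduced precision.
#'
#' @param C_levels Increasing grid of control propensities in `[0, 1]`.
#' @param p_auto_levels,p_ctrl_levels Increasing grids of access
#'   probabilities in `[0, 1]`. Cover the range reachable in the intended
#'   scenario (access probabilities never exceed the richness `R`).
#' @param params An [environment_params()].
#' @param policies A [solve_policy_set()] result.
#' @param n_sims Total number of simulated lifetimes across all cells.
#' @param steps Timesteps per lifetime.
#' @param seed Integer seed recorded in the metadata.
#' @param T_levels Optional increasing grid of automatic target levels in
#'   `[0, E_max]` (adds a fourth axis).
#' @param lambda Memory parameter of the availability estimate.
#' @return An object of class `fitness_table`: axis levels, the mean-energy
#'   array `values`, and build metadata.
#' @seealso [lookup_fitness()], [write_fitness_table()]
#' @export
build_fitness_table <- function(C_levels, p_auto_levels,
                                p_ctrl_levels = p_auto_levels,
                                params = environment_params(),
                                policies, n_sims = 30000L, steps = 1000L,
                                seed = 1L, T_levels = NULL, lambda = 0.01) {
  check_axis <- function(v, name, hi = 1) {
    if (length(v) < 1L) stop("empty axis '", name, "'", call. = FALSE)
    if (is.unsorted(v, strictly = TRUE) || any(v < 0) || any(v > hi))
      stop("'", name, "' must be strictly increasing within [0, ", hi, "]",
           call. = FALSE)
  }
  check_axis(C_levels, "C_levels")
  check_axis(p_auto_levels, "p_auto_levels")
  check_axis(p_ctrl_levels, "p_ctrl_levels")
  if (!is.null(T_levels)) check_axis(T_levels, "T_levels", params$E_max)

  cells <- if (is.null(T_levels))
    expand.grid(C = C_levels, p_auto = p_auto_levels, p_ctrl = p_ctrl_levels)
  else
    expand.grid(C = C_levels, p_auto = p_auto_levels,
                p_ctrl = p_ctrl_levels, T_E = T_levels)
  n_cells <- nrow(cells)
  reps <- max(1L, as.integer(round(n_sims / n_cells)))

  set.seed(seed)
  idx <- rep(seq_len(n_cells), each = reps)
  meanE <- .simulate_agents(
    C = cells$C[idx], p_auto = cells$p_auto[idx], p_ctrl = cells$p_ctrl[idx],
    params = params, policies = policies, steps = steps, lambda = lambda,
    auto_target = if (is.null(T_levels)) NULL else cells$T_E[idx]
  )
  cell_mean <- as.numeric(tapply(meanE, idx, mean))

  dims <- c(length(C_levels), length(p_auto_levels), length(p_ctrl_levels))
  if (!is.null(T_levels)) dims <- c(dims, length(T_levels))
  structure(list(
    C_levels = C_levels, p_auto_levels = p_auto_levels,
    p_ctrl_levels = p_ctrl_levels, T_levels = T_levels,
    values = array(cell_mean, dims),
    n_sims_per_cell = reps, steps = steps, seed = seed,
    params = params, lambda = lambda
  ), class = "fitness_table")
}

#' @export
print.fitness_table <- function(x, ...) {
  cat("Fitness table:", length(x$C_levels), "C x",
      length(x$p_auto_levels), "p_auto x", length(x$p_ctrl_levels),
      "p_ctrl", if (!is.null(x$T_levels))
        paste("x", length(x$T_levels), "T_E"), "cells\n")
  cat("  ", x$n_sims_per_cell, "lifetimes/cell x", x$steps,
      "steps (seed", paste0(x$seed, ");"), "mean E in [",
      format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "]\n")
  invisible(x)
}

# multilinear interpolation over listed axes; q is a list of query vectors
# (one per axis, equal length), values an array with matching dims
.interp_multilinear <- function(axes, values, q) {
  n <- length(q[[1L]])
  nd <- length(axes)
  i0 <- w <- vector("list", nd)
  for (d in seq_len(nd)) {
    ax <- axes[[d]]
    if (length(ax) == 1L) {           # degenerate axis: constant
      i0[[d]] <- rep(1L, n); w[[d]] <- rep(0, n)
    } else {
      i <- findInterval(q[[d]], ax, all.inside = TRUE)
      i0[[d]] <- i
      w[[d]] <- (q[[d]] - ax[i]) / (ax[i + 1L] - ax[i])
    }
  }
  dims <- vapply(axes, length, 1L)
  stride <- cumprod(c(1L, dims[-nd]))
  out <- numeric(n)
  corners <- as.matrix(expand.grid(rep(list(0:1), nd)))
  for (r in seq_len(nrow(corners))) {
    lin <- rep(1L, n)
    cw <- rep(1, n)
    for (d in seq_len(nd)) {
      b <- corners[r, d]
      id <- pmin(i0[[d]] + b, dims[d]) # degenerate axes stay at 1
      lin <- lin + (id - 1L) * stride[d]
      cw <- cw * if (b == 1L) w[[d]] else 1 - w[[d]]
    }
    out <- out + cw * values[lin]
  }
  out
}

#' Interpolate fitness from the table
#'
#' Multilinear (trilinear, or quadrilinear with a target-level axis)
#' interpolation of mean energy at the queried coordinates; exact at grid
#' nodes, and always bounded by the surrounding cell's corner values.
#' Queries must lie inside the unit cube and within the span of the table's
#' axes.
#'
#' @param table A [build_fitness_table()] result.
#' @param C,p_auto,p_ctrl Query coordinates (vectors are recycled to a
#'   common length).
#' @param T_E Target-level coordinates; required iff the table has a
#'   `T_levels` axis.
#' @return Numeric vector of interpolated mean-energy values.
#' @export
lookup_fitness <- function(table, C, p_auto, p_ctrl, T_E = NULL) {
  stopifnot(inherits(table, "fitness_table"))
  n <- max(length(C), length(p_auto), length(p_ctrl), length(T_E %||% 0))
  C <- rep_len(C, n); p_auto <- rep_len(p_auto, n)
  p_ctrl <- rep_len(p_ctrl, n)
  if (any(C < 0 | C > 1 | p_auto < 0 | p_auto > 1 | p_ctrl < 0 | p_ctrl > 1))
    stop("fitness query outside the unit cube", call. = FALSE)
  in_span <- function(x, ax, name) {
    if (any(x < ax[1L] - 1e-12 | x > ax[length(ax)] + 1e-12))
      stop("fitness query outside the table's '", name, "' axis span",
           call. = FALSE)
  }
  in_span(C, table$C_levels, "C")
  in_span(p_auto, table$p_auto_levels, "p_auto")
  in_span(p_ctrl, table$p_ctrl_levels, "p_ctrl")
  axes <- list(table$C_levels, table$p_auto_levels, table$p_ctrl_levels)
  q <- list(C, p_auto, p_ctrl)
  if (!is.null(table$T_levels)) {
    if (is.null(T_E))
      stop("table has a target-level axis; supply 'T_E'", call. = FALSE)
    T_E <- rep_len(T_E, n)
    in_span(T_E, table$T_levels, "T_E")
    axes <- c(axes, list(table$T_levels))
    q <- c(q, list(T_E))
  } else if (!is.null(T_E)) {
    stop("table has no target-level axis", call. = FALSE)
  }
  .interp_multilinear(axes, table$values, q)
}

#' Serialize a fitness table
#'
#' Writes the table as a flat CSV (columns `C`, `p_auto`, `p_ctrl`,
#' optionally `T_E`, and `mean_E`) plus a JSON sidecar with the build
#' metadata.
#'
#' @param table A `fitness_table`.
#' @param path Path of the CSV to write; the sidecar is
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_fitness_table <- function(table, path) {
  cells <- if (is.null(table$T_levels))
    expand.grid(C = table$C_levels, p_auto = table$p_auto_levels,
                p_ctrl = table$p_ctrl_levels)
  else
    expand.grid(C = table$C_levels, p_auto = table$p_auto_levels,
                p_ctrl = table$p_ctrl_levels, T_E = table$T_levels)
  cells$mean_E <- as.vector(table$values)
  utils::write.csv(cells, path, row.names = FALSE)
  meta <- list(n_sims_per_cell = table$n_sims_per_cell, steps = table$steps,
               seed = table$seed, lambda = table$lambda,
               params = unclass(table$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a serialized fitness table
#'
#' @param path Path of the CSV written by [write_fitness_table()].
#' @return A `fitness_table`.
#' @export
read_fitness_table <- function(path) {
  cells <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  C_levels <- sort(unique(cells$C))
  p_auto_levels <- sort(unique(cells$p_auto))
  p_ctrl_levels <- sort(unique(cells$p_ctrl))
  T_levels <- if ("T_E" %in% names(cells)) sort(unique(cells$T_E))
  ord <- if (is.null(T_levels))
    order(cells$p_ctrl, cells$p_auto, cells$C)
  else
    order(cells$T_E, cells$p_ctrl, cells$p_auto, cells$C)
  dims <- c(length(C_levels), length(p_auto_levels), length(p_ctrl_levels))
  if (!is.null(T_levels)) dims <- c(dims, length(T_levels))
  structure(list(
    C_levels = C_levels, p_auto_levels = p_auto_levels,
    p_ctrl_levels = p_ctrl_levels, T_levels = T_levels,
    values = array(cells$mean_E[ord], dims),
    n_sims_per_cell = meta$n_sims_per_cell, steps = meta$steps,
    seed = meta$seed, lambda = meta$lambda,
    params = environment_params(meta$params$R, meta$params$drain,
                                meta$params$rho, meta$params$E_max,
                                meta$params$u)
  ), class = "fitness_table")
}
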