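#' Eco-evolutionary feedback configuration
#'
#' Parameters of the two feedback loops. In variable-population-size runs,
#' mean energy above `T_N + epsilon` grows the population by `delta_N`
#' individuals, below `T_N - epsilon` shrinks it by the same number, and
#' inside the dead band `N` is stable; `T_N` expresses how hard it is to
#' maintain a population. In variable-richness runs the driving statistic
#' is the product of mean energy and mean control: above `T_R + epsilon`
#' the environment is enriched by `delta_R`, below `T_R - epsilon` it
#' degrades, never falling below the nominal richness `R_0`; `T_R`
#' expresses how hard the environment is to modify.
#'
#' Default increments make the feedback slow relative to selection:
#' `epsilon` is 2% of the relevant threshold, `delta_N` is 0.5% of `N_0`
#' (at least 1), and `delta_R` is 5% of `R_0`.
#'
#' @param T_N Mean-energy threshold for population growth (`NA` if unused).
#' @param T_R Threshold on mean energy x mean control for enrichment
#'   (`NA` if unused).
#' @param N_0 Nominal initial population size (`>= 1`).
#' @param R_0 Nominal richness floor, in `(0, 1]`.
#' @param epsilon Dead-band half-width (`>= 0`).
#' @param delta_N Individuals added/removed per generation (integer
#'   `>= 1`).
#' @param delta_R Richness increment (`> 0`).
#' @return An object of class `feedback_config`.
#' @export
feedback_config <- function(T_N = NA, T_R = NA, N_0 = 100L, R_0 = 0.005,
                            epsilon = NULL, delta_N = NULL,
                            delta_R = NULL) {
  stopifnot(is.numeric(N_0), N_0 >= 1,
            is.numeric(R_0), R_0 > 0, R_0 <= 1)
  if (is.null(epsilon))
    epsilon <- 0.02 * max(c(T_N, T_R), na.rm = TRUE)
  if (is.na(epsilon) || !is.finite(epsilon)) epsilon <- 0
  if (epsilon < 0) stop("'epsilon' must be >= 0", call. = FALSE)
  if (is.null(delta_N)) delta_N <- max(1L, as.integer(round(0.005 * N_0)))
  delta_N <- as.integer(delta_N)
  if (delta_N < 0) stop("'delta_N' must be a non-negative integer",
                        call. = FALSE)
  if (is.null(delta_R)) delta_R <- 0.05 * R_0
  if (delta_R <= 0) stop("'delta_R' must be > 0", call. = FALSE)
  structure(list(T_N = T_N, T_R = T_R, epsilon = epsilon,
                 delta_N = delta_N, delta_R = delta_R,
                 N_0 = as.integer(N_0), R_0 = R_0),
            class = "feedback_config")
}

#' @export
print.feedback_config <- function(x, ...) {
  cat("Feedback: T_N =", x$T_N, ", T_R =", x$T_R, ", epsilon =", x$epsilon,
      "\n  delta_N =", x$delta_N, ", delta_R =", x$delta_R,
      ", N_0 =", x$N_0, ", R_0 =", x$R_0, "\n")
  invisible(x)
}

#' Update population size from mean energy
#'
#' Pure dead-band rule: grow by `delta_N` above `T_N + epsilon`, shrink by
#' `delta_N` below `T_N - epsilon` (flooring at 0, which flags
#' extinction), hold inside the band.
#'
#' @param N Current population size (`>= 0`).
#' @param mean_E Population mean energy this generation.
#' @param cfg A [feedback_config()] with `T_N` set.
#' @return The updated population size (0 means extinct).
#' @export
update_population_size <- function(N, mean_E, cfg) {
  if (is.na(cfg$T_N)) stop("'cfg$T_N' is not set", call. = FALSE)
  if (mean_E > cfg$T_N + cfg$epsilon) N + cfg$delta_N
  else if (mean_E < cfg$T_N - cfg$epsilon) max(0L, N - cfg$delta_N)
  else N
}

#' Update richness from mean energy and mean control
#'
#' Pure dead-band rule on the innovation statistic `mean_E * mean_C`:
#' enrich by `delta_R` above `T_R + epsilon` (capped at 1), degrade by
#' `delta_R` below `T_R - epsilon` but never below the nominal floor
#' `R_0`, hold inside the band.
#'
#' @param R Current richness (`>= R_0`).
#' @param mean_E Population mean energy this generation.
#' @param mean_C Population mean control propensity.
#' @param cfg A [feedback_config()] with `T_R` set.
#' @return The updated richness.
#' @export
update_richness <- function(R, mean_E, mean_C, cfg) {
  if (is.na(cfg$T_R)) stop("'cfg$T_R' is not set", call. = FALSE)
  drive <- mean_E * mean_C
  if (drive > cfg$T_R + cfg$epsilon) min(1, R + cfg$delta_R)
  else if (drive < cfg$T_R - cfg$epsilon) max(cfg$R_0, R - cfg$delta_R)
  else R
}

#' Evolve with fitness-driven population size
#'
#' Richness is held fixed while the population size tracks mean energy
#' through [update_population_size()]: each generation evaluates fitness,
#' reconstitutes the population by Wright-Fisher sampling, then grows it by
#' an extra round of fitness-proportional sampling (with mutation) or
#' shrinks it by uniform random removal. A population that hits `N = 0` is
#' extinct and the trajectory ends there (flagged in the result).
#'
#' This is the boom-bust engine: a small population evolves control, the
#' fitness surplus grows `N`, and the resulting competition hands the
#' advantage back to automatic processing.
#'
#' @param cfg A [feedback_config()] with `T_N` set; `N_0` seeds the run.
#' @param R Fixed environmental richness.
#' @param generations Maximum number of generations.
#' @param table Fitness table covering `p` in `[0, R]`.
#' @param comp A [competition_model()].
#' @param mut A [mutation_params()].
#' @param seed Optional integer seed.
#' @param C0 Initial control propensity.
#' @return A `dualproc_trajectory`; `attr(, "extinct")` is `TRUE` if the
#'   population died out.
#' @export
run_variable_N <- function(cfg, R, generations, table,
                           comp = competition_model(),
                           mut = mutation_params(), seed = NULL, C0 = 0) {
  stopifnot(inherits(cfg, "feedback_config"), generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  pop <- new_population(cfg$N_0, R, C0 = C0, T_max = table$params$E_max)
  rows <- vector("list", generations + 1L)
  extinct <- FALSE
  g <- 0L
  repeat {
    f <- population_fitnesses(pop, table, comp)
    rows[[g + 1L]] <- .traj_row(g, pop, f)
    if (g >= generations) break
    mean_E <- mean(f)
    new_N <- update_population_size(pop$N, mean_E, cfg)
    if (new_N == 0L) { extinct <- TRUE; break }
    pop2 <- wright_fisher_step(pop, f, mut)
    if (new_N > pop$N) {
      extra <- .sample_offspring(pop, f, new_N - pop$N, mut)
      pop2$C <- c(pop2$C, extra$C)
    } else if (new_N < pop$N) {
      pop2$C <- pop2$C[sample.int(pop$N, new_N)]
    }
    pop2$N <- as.integer(new_N)
    pop <- pop2
    g <- g + 1L
  }
  .finish_trajectory(rows[!vapply(rows, is.null, TRUE)],
                     scenario = "variable_N", extinct = extinct)
}

#' Evolve with control-driven richness
#'
#' Population size is held fixed while richness tracks the innovation
#' statistic `mean_E * mean_C` through [update_richness()]. Enrichment
#' feeds back negatively on the very trait that produced it — richer
#' environments favour automatic processing — which for intermediate
#' nominal richness sustains limit cycles in mean control and `R`.
#'
#' @param cfg A [feedback_config()] with `T_R` set; `R_0` seeds the run.
#' @param N Fixed population size (the reference uses 10,000; scale down
#'   for desk-sized runs).
#' @param generations Number of generations.
#' @param table Fitness table whose `p` axes cover the reachable richness
#'   range.
#' @param comp A [competition_model()].
#' @param mut A [mutation_params()].
#' @param seed Optional integer seed.
#' @param C0 Initial control propensity.
#' @return A `dualproc_trajectory`.
#' @export
run_variable_R <- function(cfg, N, generations, table,
                           comp = competition_model(),
                           mut = mutation_params(), seed = NULL, C0 = 0) {
  stopifnot(inherits(cfg, "feedback_config"), generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  pop <- new_population(N, cfg$R_0, C0 = C0, T_max = table$params$E_max)
  rows <- vector("list", generations + 1L)
  for (g in 0:generations) {
    f <- population_fitnesses(pop, table, comp)
    rows[[g + 1L]] <- .traj_row(g, pop, f)
    if (g >= generations) break
    new_R <- update_richness(pop$R, mean(f), mean(pop$C), cfg)
    pop <- wright_fisher_step(pop, f, mut)
    pop$R <- new_R
  }
  .finish_trajectory(rows, scenario = "variable_R")
}

# centred moving average, window forced odd
.smooth_ma <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window <= 1L) return(x)
  k <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - k - 1L)
  hi <- pmin(n, seq_len(n) + k)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Detect limit cycles in a trajectory
#'
#' Quantifies sustained oscillation of mean control after a burn-in: the
#' series is smoothed with a centred moving average (window 2% of the
#' post-burn-in length), its local peaks and troughs are extracted, and
#' alternations whose peak-to-trough swing reaches `min_amplitude` are
#' counted. The trajectory is declared cycling when at least `min_cycles`
#' such alternations occur. Constant or monotone series are never cycling.
#'
#' @param traj A `dualproc_trajectory` (or data frame with a `mean_C`
#'   column).
#' @param burn_in Fraction of the trajectory discarded before detection.
#' @param min_amplitude Minimum peak-to-trough swing in mean `C`.
#' @param min_cycles Minimum number of qualifying alternations.
#' @param window Smoothing window in generations; `NULL` for the default.
#' @return An object of class `cycle_stats`: `is_cycling`, mean
#'   `amplitude`, `period` (mean peak-to-peak spacing, `NA` when not
#'   cycling), and `n_cycles` (qualifying alternations).
#' @export
detect_limit_cycle <- function(traj, burn_in = 0.2, min_amplitude = 0.2,
                               min_cycles = 3L, window = NULL) {
  x <- traj$mean_C
  stopifnot(!is.null(x), burn_in >= 0, burn_in < 1)
  x <- x[-seq_len(floor(length(x) * burn_in))]
  if (length(x) < 5L)
    stop("trajectory too short after burn-in", call. = FALSE)
  if (is.null(window)) window <- ceiling(0.02 * length(x))
  z <- .smooth_ma(x, window)

  # raw extrema: sign changes of the first difference, plateaus collapsed
  dz <- diff(z)
  sgn <- sign(dz)[sign(dz) != 0]
  pos <- which(sign(dz) != 0)
  none <- structure(list(is_cycling = FALSE, amplitude = 0, period = NA_real_,
                         n_cycles = 0L), class = "cycle_stats")
  if (length(sgn) < 2L) return(none)
  turn <- which(sgn[-1L] != sgn[-length(sgn)])
  if (!length(turn)) return(none)
  ext_idx <- pos[turn] + 1L                     # index into z
  ext_val <- z[ext_idx]

  # zigzag filter: keep alternating major extrema; swings below the
  # amplitude floor either extend the previous move or are discarded
  ki <- ext_idx[1L]; kv <- ext_val[1L]
  for (e in seq_along(ext_idx)[-1L]) {
    last <- length(kv)
    if (abs(ext_val[e] - kv[last]) >= min_amplitude) {
      ki <- c(ki, ext_idx[e]); kv <- c(kv, ext_val[e])
    } else if (last >= 2L) {
      prev_move <- kv[last] - kv[last - 1L]
      new_move <- ext_val[e] - kv[last - 1L]
      if (sign(new_move) == sign(prev_move) &&
          abs(new_move) > abs(prev_move)) {
        ki[last] <- ext_idx[e]; kv[last] <- ext_val[e]   # extend the move
      }
    } else if (abs(ext_val[e]) > abs(kv[1L])) {
      ki[1L] <- ext_idx[e]; kv[1L] <- ext_val[e]
    }
  }
  swings <- abs(diff(kv))
  ok <- swings >= min_amplitude
  n_alt <- sum(ok)
  if (n_alt < min_cycles) {
    return(structure(list(is_cycling = FALSE,
                          amplitude = if (n_alt) mean(swings[ok]) else 0,
                          period = NA_real_, n_cycles = as.integer(n_alt)),
                     class = "cycle_stats"))
  }
  # period: mean spacing between successive same-type major extrema
  period <- if (length(ki) >= 3L) mean(ki[-(1:2)] - ki[seq_len(length(ki) - 2L)])
            else NA_real_
  structure(list(is_cycling = TRUE, amplitude = mean(swings[ok]),
                 period = period, n_cycles = as.integer(n_alt)),
            class = "cycle_stats")
}

#' @export
print.cycle_stats <- function(x, ...) {
  if (x$is_cycling)
    cat("Limit cycle: amplitude", format(x$amplitude, digits = 3),
        ", period ~", format(x$period, digits = 4), "generations (",
        x$n_cycles, "alternations )\n")
  else
    cat("No limit cycle detected (", x$n_cycles, "qualifying alternations,",
        "amplitude", format(x$amplitude, digits = 3), ")\n")
  invisible(x)
}
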