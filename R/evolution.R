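#' Mutation parameters
#'
#' Local mutation of the heritable traits: with probability `rate` each
#' offspring perturbs its inherited control propensity by `step`, the sign
#' chosen equiprobably, clamped to `[0, 1]`. The defaults (5% and 0.02) are
#' the reference values. When the automatic target level also evolves it
#' mutates in the same manner; its step defaults to `step` scaled to the
#' energy range (`step * E_max`).
#'
#' @param rate Per-offspring mutation probability in `[0, 1]`.
#' @param step Trait increment magnitude (`> 0`).
#' @param target_step Increment magnitude for the automatic target level;
#'   `NULL` to use `step * E_max`.
#' @return An object of class `mutation_params`.
#' @export
mutation_params <- function(rate = 0.05, step = 0.02, target_step = NULL) {
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1,
            is.numeric(step), step > 0)
  if (!is.null(target_step)) stopifnot(is.numeric(target_step),
                                       target_step > 0)
  structure(list(rate = rate, step = step, target_step = target_step),
            class = "mutation_params")
}

#' Create a population
#'
#' A population of `N` agents, each carrying a control propensity `C`
#' (and optionally an automatic target level `T_E`), living at richness
#' `R`. Evolutionary runs start homogeneous at `C = 0`: a world of pure
#' automata into which control must spread.
#'
#' @param N Population size (`>= 1`).
#' @param R Environmental richness in `[0, 1]`.
#' @param C0 Initial control propensity (scalar or length-`N` vector).
#' @param T0 Optional initial automatic target level(s) in `[0, T_max]`;
#'   enables the second heritable trait.
#' @param T_max Upper bound for the target trait (the satiety ceiling).
#' @return An object of class `population`.
#' @export
new_population <- function(N, R, C0 = 0, T0 = NULL, T_max = 100) {
  stopifnot(is.numeric(N), N >= 1, is.numeric(R), R >= 0, R <= 1)
  N <- as.integer(N)
  C <- rep_len(C0, N)
  if (any(C < 0 | C > 1)) stop("'C0' must lie in [0, 1]", call. = FALSE)
  T_E <- NULL
  if (!is.null(T0)) {
    T_E <- rep_len(T0, N)
    if (any(T_E < 0 | T_E > T_max))
      stop("'T0' must lie in [0, T_max]", call. = FALSE)
  }
  structure(list(C = C, T_E = T_E, T_max = T_max, N = N, R = R,
                 generation = 0L),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("Population: N =", x$N, ", R =", x$R, ", generation", x$generation,
      ", mean C =", format(mean(x$C), digits = 4),
      if (!is.null(x$T_E))
        paste(", mean T_E =", format(mean(x$T_E), digits = 4)), "\n")
  invisible(x)
}

#' Fitness of every agent in a population
#'
#' Computes the per-mode access probabilities from the current richness,
#' population size, and mean automatic share `mean(1 - C)`, then
#' interpolates each agent's fitness from the precomputed table at
#' `(C_i, p_auto, p_ctrl)` (and `T_E_i` when the automatic habit evolves).
#'
#' @param pop A [new_population()].
#' @param table A [build_fitness_table()] result covering the queried range.
#' @param comp A [competition_model()].
#' @return Non-negative numeric vector aligned with `pop$C`.
#' @export
population_fitnesses <- function(pop, table, comp = competition_model()) {
  acc <- access_probabilities(pop$R, pop$N, mean(1 - pop$C), comp)
  lookup_fitness(table, pop$C, acc$p_auto, acc$p_ctrl, T_E = pop$T_E)
}

# sample n offspring (traits only) proportional to fitness, with mutation
.sample_offspring <- function(pop, fitnesses, n, mut) {
  total <- sum(fitnesses)
  parents <- if (total <= 0)
    sample.int(pop$N, n, replace = TRUE)       # starving: pure drift
  else
    sample.int(pop$N, n, replace = TRUE, prob = fitnesses)
  C <- pop$C[parents]
  hit <- stats::runif(n) < mut$rate
  if (any(hit)) {
    sgn <- ifelse(stats::runif(sum(hit)) < 0.5, -1, 1)
    C[hit] <- pmin(1, pmax(0, C[hit] + sgn * mut$step))
  }
  T_E <- NULL
  if (!is.null(pop$T_E)) {
    T_E <- pop$T_E[parents]
    tstep <- mut$target_step %||% (mut$step * pop$T_max)
    hitT <- stats::runif(n) < mut$rate
    if (any(hitT)) {
      sgnT <- ifelse(stats::runif(sum(hitT)) < 0.5, -1, 1)
      T_E[hitT] <- pmin(pop$T_max, pmax(0, T_E[hitT] + sgnT * tstep))
    }
  }
  list(C = C, T_E = T_E)
}

#' One Wright-Fisher generation
#'
#' Reconstitutes the population by drawing `N` offspring with replacement,
#' each parent chosen with probability proportional to fitness, then
#' applies local mutation. If total fitness is zero the population is
#' starving but not yet extinct: parents are drawn uniformly (pure drift).
#' Traits are clamped at their bounds.
#'
#' @param pop A [new_population()].
#' @param fitnesses Non-negative vector aligned with `pop$C`.
#' @param mut A [mutation_params()].
#' @return The next-generation `population` (same `N`, `R`).
#' @export
wright_fisher_step <- function(pop, fitnesses, mut = mutation_params()) {
  if (length(fitnesses) != pop$N)
    stop("length(fitnesses) must equal the population size", call. = FALSE)
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative",
                               call. = FALSE)
  off <- .sample_offspring(pop, fitnesses, pop$N, mut)
  pop$C <- off$C
  pop$T_E <- off$T_E
  pop$generation <- pop$generation + 1L
  pop
}

# one trajectory record
.traj_row <- function(gen, pop, fitnesses) {
  q <- stats::quantile(pop$C, c(0.1, 0.9), names = FALSE, type = 7)
  row <- data.frame(generation = gen, mean_C = mean(pop$C),
                    q10_C = q[1L], q90_C = q[2L],
                    mean_E = mean(fitnesses), N = pop$N, R = pop$R)
  if (!is.null(pop$T_E)) row$mean_T <- mean(pop$T_E)
  row
}

.finish_trajectory <- function(rows, scenario, extinct = FALSE) {
  traj <- do.call(rbind, rows)
  rownames(traj) <- NULL
  class(traj) <- c("dualproc_trajectory", "data.frame")
  attr(traj, "scenario") <- scenario
  attr(traj, "extinct") <- extinct
  traj
}

#' Evolve control at fixed population size and richness
#'
#' Iterates fitness evaluation and Wright-Fisher reproduction for a fixed
#' `(N, R)`, starting from a homogeneous `C = 0` population, and records
#' one trajectory row per generation (including generation 0). Long runs
#' (the reference uses 100,000 generations) approach the
#' mutation-selection-drift equilibrium; the final 10% of generations is
#' the conventional equilibrium window (see [summarize_run()]).
#'
#' @param N Population size.
#' @param R Environmental richness.
#' @param generations Number of generations to simulate.
#' @param table A [build_fitness_table()] result covering `p` in `[0, R]`.
#' @param comp A [competition_model()].
#' @param mut A [mutation_params()].
#' @param seed Optional integer seed; runs are deterministic given it.
#' @param C0 Initial control propensity (default 0).
#' @param T0 Optional initial automatic target level (enables the second
#'   trait; the table must then carry a `T_levels` axis).
#' @return A `dualproc_trajectory` data frame with columns `generation`,
#'   `mean_C`, `q10_C`, `q90_C`, `mean_E`, `N`, `R` (plus `mean_T` with an
#'   evolving automatic habit).
#' @export
run_fixed_scenario <- function(N, R, generations, table,
                               comp = competition_model(),
                               mut = mutation_params(), seed = NULL,
                               C0 = 0, T0 = NULL) {
  if (missing(table) || !inherits(table, "fitness_table"))
    stop("a fitness_table is required; build one with build_fitness_table()",
         call. = FALSE)
  stopifnot(generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  pop <- new_population(N, R, C0 = C0, T0 = T0,
                        T_max = table$params$E_max)
  rows <- vector("list", generations + 1L)
  for (g in 0:generations) {
    f <- population_fitnesses(pop, table, comp)
    rows[[g + 1L]] <- .traj_row(g, pop, f)
    if (g < generations) pop <- wright_fisher_step(pop, f, mut)
  }
  .finish_trajectory(rows, scenario = "fixed")
}
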