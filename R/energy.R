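#' Environment parameters
#'
#' Bundles the physical constants of the simulated environment: the
#' per-timestep probability `R` of encountering a resource, the constant
#' metabolic drain `d` paid every step, the magnitude `rho` of one resource
#' packet, the satiety ceiling `E_max` on energy, and the utility rate
#' constant `u` of the concave consumption function.
#'
#' Consumption follows the marginal-gain law `dE/dx = u * (1 - E/E_max)`:
#' a unit of resource is most valuable when energy is lowest and worthless at
#' satiety. The defaults (`drain = 1`, `rho = 10 * drain`,
#' `E_max = 100 * drain`, `u = 50`) are calibrated so that under scarce
#' conditions (`R = 0.005`) an always-automatic consumer spends most of its
#' life near the energy floor, while saturation is strong enough
#' (`u * rho > E_max`) that splitting a packet across several sittings beats
#' gorging — the premise that makes deliberate storage worthwhile.
#'
#' @param R Per-timestep resource-encounter probability, in `[0, 1]`.
#' @param drain Energy drained every timestep (`d > 0`).
#' @param rho Resource magnitude per encounter (`> 0`).
#' @param E_max Satiety ceiling on energy (`> 0`).
#' @param u Utility rate constant (`> 0`); larger values saturate faster.
#' @return An object of class `environment_params`.
#' @seealso [consume()], [marginal_gain()], [solve_policy()]
#' @examples
#' env <- environment_params(R = 0.005)
#' consume(energy_state(0, 0, env), x = env$rho, env)
#' @export
environment_params <- function(R = 0.005, drain = 1, rho = 10 * drain,
                               E_max = 100 * drain, u = 50) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R),
            is.numeric(drain), length(drain) == 1L, is.finite(drain),
            is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.numeric(E_max), length(E_max) == 1L, is.finite(E_max),
            is.numeric(u), length(u) == 1L, is.finite(u))
  if (R < 0 || R > 1) stop("'R' must lie in [0, 1]", call. = FALSE)
  if (drain <= 0) stop("'drain' must be strictly positive", call. = FALSE)
  if (rho <= 0) stop("'rho' must be strictly positive", call. = FALSE)
  if (E_max <= 0) stop("'E_max' must be strictly positive", call. = FALSE)
  if (u <= 0) stop("'u' must be strictly positive", call. = FALSE)
  structure(list(R = R, drain = drain, rho = rho, E_max = E_max, u = u),
            class = "environment_params")
}

#' @export
print.environment_params <- function(x, ...) {
  cat("Environment: R =", x$R, ", drain =", x$drain, ", rho =", x$rho,
      ", E_max =", x$E_max, ", u =", x$u, "\n")
  invisible(x)
}

#' Energy state of a single agent
#'
#' An agent's within-lifetime state: current energy `E` (bounded by the
#' satiety ceiling) and the stock `S` of resources it has set aside. The
#' store carries no interest and does not decay.
#'
#' @param E Energy level, in `[0, E_max]`.
#' @param S Stored resource, `>= 0`.
#' @param params An [environment_params()] object supplying `E_max`.
#' @return An object of class `energy_state`.
#' @export
energy_state <- function(E, S = 0, params) {
  stopifnot(is.numeric(E), length(E) == 1L, is.finite(E),
            is.numeric(S), length(S) == 1L, is.finite(S))
  if (E < 0 || E > params$E_max)
    stop("'E' must lie in [0, E_max]", call. = FALSE)
  if (S < 0) stop("'S' must be non-negative", call. = FALSE)
  structure(list(E = E, S = S), class = "energy_state")
}

#' @export
print.energy_state <- function(x, ...) {
  cat("Energy state: E =", format(x$E), ", S =", format(x$S), "\n")
  invisible(x)
}

#' Apply the per-timestep metabolic drain
#'
#' Subtracts the constant subsistence cost from the agent's energy, flooring
#' at zero. The store is untouched; running out of energy is not lethal
#' within a lifetime (fitness is the lifetime mean of `E`, and extinction is
#' a population-level event).
#'
#' @param state An [energy_state()].
#' @param params An [environment_params()].
#' @return The drained `energy_state`.
#' @export
apply_drain <- function(state, params) {
  energy_state(max(0, state$E - params$drain), state$S, params)
}

# closed-form energy after consuming x, vectorised over E and x
.consume_energy <- function(E, x, E_max, u) {
  E_max - (E_max - E) * exp(-u * x / E_max)
}

#' Consume an amount of resource
#'
#' Raises energy according to the closed form of the saturating marginal
#' gain `dE/dx = u * (1 - E/E_max)`:
#' `E' = E_max - (E_max - E) * exp(-u * x / E_max)`.
#' The result is monotone increasing and concave in `x` and can never exceed
#' `E_max`; at satiety consumption is wasted entirely. Bookkeeping of where
#' `x` came from (fresh encounter or store) is the caller's concern — `S` is
#' returned unchanged.
#'
#' @param state An [energy_state()].
#' @param x Non-negative amount to consume.
#' @param params An [environment_params()].
#' @return The updated `energy_state`.
#' @export
consume <- function(state, x, params) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  if (x < 0) stop("negative consumption amount 'x'", call. = FALSE)
  energy_state(.consume_energy(state$E, x, params$E_max, params$u),
               state$S, params)
}

#' Marginal energy gain of consumption
#'
#' The instantaneous return `u * (1 - E/E_max)` on the next unit consumed:
#' strictly decreasing in `E`, zero at satiety. This is the derivative the
#' policy solver trades off against the future value of storage.
#'
#' @param E Energy level(s), each in `[0, E_max]`.
#' @param params An [environment_params()].
#' @return Numeric vector of marginal gains.
#' @export
marginal_gain <- function(E, params) {
  stopifnot(is.numeric(E))
  if (any(E < 0 | E > params$E_max))
    stop("'E' outside [0, E_max]", call. = FALSE)
  params$u * (1 - E / params$E_max)
}

#' Consumption needed to reach a target energy level
#'
#' Inverts the consumption closed form: the amount `x` such that
#' `consume(E, x)` lands exactly on `target`, i.e.
#' `x = (E_max/u) * log((E_max - E) / (E_max - target))`.
#' Targets at or below the current level need nothing (`0`); the satiety
#' ceiling itself is unreachable in finite consumption (`Inf`). Used by the
#' target-level automatic policy, which tops energy up to a heritable set
#' point.
#'
#' @param E Current energy level(s).
#' @param target Target energy level(s), in `[0, E_max]`.
#' @param params An [environment_params()].
#' @return Required consumption amount(s); `Inf` where `target == E_max`.
#' @export
consumption_to_reach <- function(E, target, params) {
  stopifnot(is.numeric(E), is.numeric(target))
  if (any(E < 0 | E > params$E_max))
    stop("'E' outside [0, E_max]", call. = FALSE)
  if (any(target < 0 | target > params$E_max))
    stop("'target' outside [0, E_max]", call. = FALSE)
  x <- (params$E_max / params$u) *
    log((params$E_max - E) / (params$E_max - target))
  x[target <= E] <- 0
  x[target >= params$E_max & E < params$E_max] <- Inf
  x
}
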