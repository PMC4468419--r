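#' Automatic consumption policy
#'
#' The baseline automatic habit fully consumes any encountered packet and
#' cannot touch the store. The evolvable variant instead tops energy up to a
#' heritable target level, drawing on the packet and the store, and banks
#' the remainder.
#'
#' @param mode `"full_consume"` (baseline) or `"target_level"`.
#' @param target Target energy level in `[0, E_max]`; required for
#'   `"target_level"`.
#' @param params An [environment_params()] (used to validate `target`).
#' @return An object of class `automatic_policy`.
#' @export
automatic_policy <- function(mode = c("full_consume", "target_level"),
                             target = NULL, params = environment_params()) {
  mode <- match.arg(mode)
  if (mode == "target_level") {
    stopifnot(is.numeric(target), length(target) == 1L)
    if (target < 0 || target > params$E_max)
      stop("'target' must lie in [0, E_max]", call. = FALSE)
  }
  structure(list(mode = mode, target = target), class = "automatic_policy")
}

# Vectorised lifetime engine.
#
# Simulates n agents in parallel for `steps` timesteps; all per-agent
# arguments are recycled to length n. Per step and agent: draw the acting
# mode (controlled w.p. C), pay the drain, draw acquisition with the
# mode-specific access probability, act (automatic: habitual consumption;
# controlled: indexed optimal policy over store + packet), then update the
# experience-based availability estimate with the realised outcome. Fitness
# is the mean of E over steps, E being measured at the end of each step.
#
# auto_target: NULL for the baseline full-consume habit, else a vector of
# target energy levels (automatic acts then also access the store).
.simulate_agents <- function(C, p_auto, p_ctrl, params, policies, steps,
                             lambda = 0.01, p_hat0 = NULL,
                             auto_target = NULL, trace = FALSE) {
  stopifnot(inherits(policies, "policy_set"), steps >= 1)
  n <- max(length(C), length(p_auto), length(p_ctrl),
           length(auto_target %||% 0))
  C <- rep_len(C, n); p_auto <- rep_len(p_auto, n)
  p_ctrl <- rep_len(p_ctrl, n)
  if (!is.null(auto_target)) auto_target <- rep_len(auto_target, n)
  stopifnot(all(C >= 0 & C <= 1), all(p_auto >= 0 & p_auto <= 1),
            all(p_ctrl >= 0 & p_ctrl <= 1))

  g <- policies$grid
  E_max <- params$E_max; rho <- params$rho; d <- params$drain
  px <- policies$px
  p_levels <- policies$p_levels

  E <- numeric(n)                       # lifetimes start at the floor
  S <- numeric(n)
  p_hat <- rep_len(if (is.null(p_hat0)) params$R else p_hat0, n)
  sumE <- numeric(n)
  sumE2 <- numeric(n)
  clamped <- FALSE
  tr <- if (trace) matrix(NA_real_, steps, 5L,
                          dimnames = list(NULL, c("E", "S", "mode_ctrl",
                                                  "acquired", "x")))

  for (t in seq_len(steps)) {
    ctrl <- stats::runif(n) < C
    acq <- stats::runif(n) < ifelse(ctrl, p_ctrl, p_auto)
    E <- pmax(0, E - d)
    x_tr <- if (trace) numeric(n)

    # automatic acts
    ia <- which(!ctrl)
    if (length(ia)) {
      if (is.null(auto_target)) {
        # habitual: consume the whole packet, no store access
        iac <- ia[acq[ia]]
        if (length(iac)) {
          E[iac] <- .consume_energy(E[iac], rho, E_max, params$u)
          if (trace) x_tr[iac] <- rho
        }
      } else {
        # evolvable habit: top up to the target from packet + store
        pool <- S[ia] + acq[ia] * rho
        need <- consumption_to_reach(E[ia], auto_target[ia], params)
        x <- pmin(pool, need)
        E[ia] <- .consume_energy(E[ia], x, E_max, params$u)
        S[ia] <- pool - x
        if (trace) x_tr[ia] <- x
      }
    }

    # controlled acts: consult the pre-solved policy nearest the estimate
    ic <- which(ctrl)
    if (length(ic)) {
      Sq <- S[ic]
      if (any(Sq > g$S_cap)) { clamped <- TRUE; Sq <- pmin(Sq, g$S_cap) }
      pi_ <- .nearest_p_idx(p_levels, p_hat[ic])
      eb <- .nearest_bin(E[ic], E_max, g$n_E)
      sb <- .nearest_bin(Sq, g$S_cap, g$n_S)
      frac <- px[cbind(pi_, eb, sb, as.integer(acq[ic]) + 1L)]
      pool <- S[ic] + acq[ic] * rho
      x <- frac * pool
      E[ic] <- .consume_energy(E[ic], x, E_max, params$u)
      S[ic] <- pool - x
      if (trace) x_tr[ic] <- x
    }

    p_hat <- (1 - lambda) * p_hat + lambda * acq
    sumE <- sumE + E
    sumE2 <- sumE2 + E * E
    if (trace) tr[t, ] <- c(E[1L], S[1L], ctrl[1L], acq[1L], x_tr[1L])
  }

  if (clamped)
    warning("store exceeded S_cap during simulation; policy lookups clamped",
            call. = FALSE)
  out <- sumE / steps
  attr(out, "var_E") <- pmax(0, sumE2 / steps - out * out)
  if (trace) attr(out, "trace") <- as.data.frame(tr)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one agent's lifetime
#'
#' Runs a single dual-process agent for `steps` timesteps under fixed
#' per-mode access probabilities and returns its fitness: the lifetime mean
#' energy level. Each step the agent acts in a controlled manner with
#' probability `C` and automatically otherwise; automatic acts fully consume
#' any encountered packet (and cannot reach the store), controlled acts
#' consume the policy-optimal amount from store + packet and bank the rest.
#'
#' @param C Probability of acting in a controlled manner on any step.
#' @param access An [access_probabilities()] object (or list with `p_auto`,
#'   `p_ctrl`).
#' @param params An [environment_params()].
#' @param policies A [solve_policy_set()] result.
#' @param steps Lifetime length in timesteps.
#' @param seed Optional integer seed for reproducibility.
#' @param n_rep Number of independent lifetimes to simulate.
#' @param lambda Memory parameter of the availability estimate.
#' @param p_hat0 Initial availability estimate (defaults to the
#'   environment's true `R`).
#' @param trace If `TRUE` (and `n_rep == 1`), attach a per-step trace
#'   (`E`, `S`, mode, acquisition, consumption) as attribute `"trace"`.
#' @return Mean energy per lifetime: a scalar if `n_rep == 1`, else a
#'   vector of length `n_rep`. The within-lifetime variance of `E` (the
#'   volatility that storage smooths away) is attached as attribute
#'   `"var_E"`.
#' @export
simulate_lifetime <- function(C, access, params, policies, steps = 1000L,
                              seed = NULL, n_rep = 1L, lambda = 0.01,
                              p_hat0 = NULL, trace = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  .simulate_agents(rep(C, n_rep), access$p_auto, access$p_ctrl, params,
                   policies, steps, lambda = lambda, p_hat0 = p_hat0,
                   trace = trace && n_rep == 1L)
}

#' Simulate a lifetime with an evolvable automatic policy
#'
#' Variant of [simulate_lifetime()] in which automatic acts follow a
#' heritable target-level habit: if energy is below the target, consume
#' from packet + store exactly enough to reach it (inverting the
#' consumption closed form), banking the remainder; if at or above it,
#' store the whole packet. With `target = E_max` and an empty store this
#' reduces to the baseline full-consumption habit.
#'
#' @inheritParams simulate_lifetime
#' @param auto_policy An [automatic_policy()] of mode `"target_level"` (a
#'   `"full_consume"` policy delegates to [simulate_lifetime()]).
#' @return As [simulate_lifetime()].
#' @export
simulate_lifetime_evolvable_auto <- function(C, auto_policy, access, params,
                                             policies, steps = 1000L,
                                             seed = NULL, n_rep = 1L,
                                             lambda = 0.01, p_hat0 = NULL,
                                             trace = FALSE) {
  stopifnot(inherits(auto_policy, "automatic_policy"))
  if (auto_policy$mode == "full_consume")
    return(simulate_lifetime(C, access, params, policies, steps, seed,
                             n_rep, lambda, p_hat0, trace))
  if (!is.null(seed)) set.seed(seed)
  .simulate_agents(rep(C, n_rep), access$p_auto, access$p_ctrl, params,
                   policies, steps, lambda = lambda, p_hat0 = p_hat0,
                   auto_target = auto_policy$target,
                   trace = trace && n_rep == 1L)
}
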