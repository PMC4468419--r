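#' Discretization grid for the consumption problem
#'
#' The consume-versus-store problem is solved on a rectangular grid over
#' energy and store, with a fixed menu of candidate consumption levels
#' expressed as evenly spaced fractions of the currently available pool
#' (store plus any just-acquired packet).
#'
#' @param n_E Number of energy bins (`>= 2`).
#' @param n_S Number of store bins (`>= 2`).
#' @param S_cap Largest store represented (`> 0`); states above it are
#'   clamped with a warning at lookup time.
#' @param n_x Number of candidate consumption fractions per decision
#'   (`>= 2`), evenly spaced on `[0, 1]`.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_E = 51L, n_S = 26L, S_cap = 50, n_x = 21L) {
  stopifnot(is.numeric(n_E), n_E >= 2, is.numeric(n_S), n_S >= 2,
            is.numeric(n_x), n_x >= 2, is.numeric(S_cap), S_cap > 0)
  structure(list(n_E = as.integer(n_E), n_S = as.integer(n_S),
                 S_cap = S_cap, n_x = as.integer(n_x)),
            class = "grid_spec")
}

# Precompute the discretized transition model shared by all solver sweeps.
#
# One decision step is: drain, then (exogenously) acquire a packet of size
# rho or nothing, then consume a fraction of the pool S + acquired, then
# store the remainder (clamped at S_cap). The reward is the energy level at
# the end of the step. Off-grid landing states are resolved by bilinear
# interpolation of the value function, i.e. the discretized chain jumps to
# the four surrounding grid nodes with the interpolation weights.
.policy_model <- function(params, grid) {
  n_E <- grid$n_E; n_S <- grid$n_S; n_x <- grid$n_x
  E_grid <- seq(0, params$E_max, length.out = n_E)
  S_grid <- seq(0, grid$S_cap, length.out = n_S)
  fracs <- seq(0, 1, length.out = n_x)
  step_E <- params$E_max / (n_E - 1)
  step_S <- grid$S_cap / (n_S - 1)

  st_E <- rep(E_grid, times = n_S)          # E varies fastest
  st_S <- rep(S_grid, each = n_E)
  n_states <- n_E * n_S
  E_drained <- pmax(0, st_E - params$drain)

  n_rows <- n_states * n_x * 2L             # (state, frac, acq) combos
  reward <- numeric(n_rows)
  idx <- matrix(0L, n_rows, 4L)
  wgt <- matrix(0, n_rows, 4L)

  row0 <- 0L
  for (a in 0:1) {                          # acq flag: 0 none, 1 packet rho
    pool <- st_S + a * params$rho
    for (k in seq_len(n_x)) {
      x <- fracs[k] * pool
      E2 <- .consume_energy(E_drained, x, params$E_max, params$u)
      S2 <- pmin(grid$S_cap, pool - x)
      # bilinear corner decomposition on the uniform grid
      fE <- E2 / step_E
      i0 <- pmin(floor(fE), n_E - 2); wE <- fE - i0
      fS <- S2 / step_S
      j0 <- pmin(floor(fS), n_S - 2); wS <- fS - j0
      base <- i0 + 1 + j0 * n_E
      rows <- row0 + seq_len(n_states)
      idx[rows, ] <- cbind(base, base + 1L, base + n_E, base + n_E + 1L)
      wgt[rows, ] <- cbind((1 - wE) * (1 - wS), wE * (1 - wS),
                           (1 - wE) * wS, wE * wS)
      reward[rows] <- E2
      row0 <- row0 + n_states
    }
  }
  list(E_grid = E_grid, S_grid = S_grid, fracs = fracs,
       n_states = n_states, reward = reward, idx = idx, wgt = wgt)
}

# One Bellman backup: returns list(V = updated value, Q = array
# (n_states, n_x, 2) of action values) for acquisition probability p.
.bellman <- function(model, V, gamma, p, n_x) {
  EV <- model$wgt[, 1L] * V[model$idx[, 1L]] +
    model$wgt[, 2L] * V[model$idx[, 2L]] +
    model$wgt[, 3L] * V[model$idx[, 3L]] +
    model$wgt[, 4L] * V[model$idx[, 4L]]
  Q <- array(model$reward + gamma * EV, c(model$n_states, n_x, 2L))
  v0 <- Q[, 1L, 1L]
  v1 <- Q[, 1L, 2L]
  for (k in 2:n_x) {
    v0 <- pmax(v0, Q[, k, 1L])
    v1 <- pmax(v1, Q[, k, 2L])
  }
  list(V = (1 - p) * v0 + p * v1, Q = Q)
}

#' Solve the optimal consume-versus-store policy
#'
#' Computes, for a fixed per-step acquisition probability, the consumption
#' policy that maximizes the expected discounted sum of per-step energy over
#' the induced Markov chain on (energy, store). Each step drains energy,
#' acquires a packet of size `rho` with probability `p_acquire`, consumes a
#' chosen fraction of the pool (store + packet), and stores the remainder.
#' Infinite-horizon problems are solved by value iteration to a sup-norm
#' residual below `tol`; finite horizons by exact backward induction. The
#' returned policy is greedy with respect to the converged values, breaking
#' exact ties toward the smallest consumption (prefer storage).
#'
#' @param p_acquire Per-step probability of acquiring a resource packet.
#' @param params An [environment_params()].
#' @param grid A [grid_spec()].
#' @param gamma Discount factor in `(0, 1)`; values near 1 approximate the
#'   average-energy (fitness) criterion.
#' @param tol Convergence threshold on the max absolute value change
#'   (ignored for finite horizons).
#' @param max_iter Iteration cap; exceeding it is an error that reports the
#'   achieved residual.
#' @param horizon `Inf` for the stationary problem, or a positive integer
#'   number of remaining steps for the finite-horizon variant.
#' @param V_init Optional warm-start value vector (length `n_E * n_S`),
#'   e.g. the converged values at a neighbouring acquisition probability.
#' @return An object of class `consumption_policy`: grids, the optimal
#'   consumption fraction `x_frac[E_bin, S_bin, acq_flag]`, the value
#'   surface, and solver metadata.
#' @seealso [optimal_consumption()], [solve_policy_set()]
#' @export
solve_policy <- function(p_acquire, params, grid = grid_spec(),
                         gamma = 0.995, tol = 1e-6, max_iter = 20000L,
                         horizon = Inf, V_init = NULL) {
  stopifnot(is.numeric(p_acquire), length(p_acquire) == 1L,
            p_acquire >= 0, p_acquire <= 1,
            is.numeric(gamma), gamma > 0, gamma < 1)
  model <- .policy_model(params, grid)
  n_x <- grid$n_x
  V <- if (is.null(V_init)) numeric(model$n_states)
       else { stopifnot(length(V_init) == model$n_states); V_init }
  iter <- 0L
  residual <- Inf

  if (is.finite(horizon)) {
    stopifnot(horizon >= 1)
    for (h in seq_len(horizon)) {
      bk <- .bellman(model, V, gamma, p_acquire, n_x)
      residual <- max(abs(bk$V - V))
      V <- bk$V
      iter <- h
    }
  } else {
    repeat {
      bk <- .bellman(model, V, gamma, p_acquire, n_x)
      residual <- max(abs(bk$V - V))
      V <- bk$V
      iter <- iter + 1L
      if (residual < tol) break
      if (iter >= max_iter)
        stop(sprintf(
          "value iteration did not converge in %d iterations (residual %.3g)",
          max_iter, residual), call. = FALSE)
    }
  }

  # greedy policy w.r.t. the final values; ties -> first (smallest) fraction
  Q <- bk$Q
  frac_idx <- array(0L, c(grid$n_E, grid$n_S, 2L))
  for (a in 1:2)
    frac_idx[, , a] <- max.col(Q[, , a], ties.method = "first")
  x_frac <- array(model$fracs[frac_idx], dim(frac_idx))

  structure(list(
    E_grid = model$E_grid, S_grid = model$S_grid, fracs = model$fracs,
    x_frac = x_frac, frac_idx = frac_idx,
    value = matrix(V, grid$n_E, grid$n_S),
    p_acquire = p_acquire, gamma = gamma, tol = tol,
    residual = residual, iterations = iter, horizon = horizon,
    grid = grid, params = params
  ), class = "consumption_policy")
}

#' @export
print.consumption_policy <- function(x, ...) {
  cat("Consumption policy: p_acquire =", x$p_acquire,
      ", gamma =", x$gamma,
      if (is.finite(x$horizon)) paste0(", horizon = ", x$horizon)
      else paste0(", converged in ", x$iterations,
                  " iterations (residual ", format(x$residual, digits = 3),
                  ")"), "\n")
  cat("  grid:", x$grid$n_E, "x", x$grid$n_S, "states,",
      x$grid$n_x, "consumption fractions, S_cap =", x$grid$S_cap, "\n")
  invisible(x)
}

#' Availability grid for a policy set
#'
#' Default acquisition-probability levels at which policies are pre-solved.
#' Levels are quadratically spaced on `[0, p_max]` so that resolution is
#' concentrated near zero, where scarce-environment agents live.
#'
#' @param n Number of levels.
#' @param p_max Largest availability represented.
#' @return Increasing numeric vector of length `n` starting at 0.
#' @export
availability_levels <- function(n = 21L, p_max = 1) {
  stopifnot(n >= 2, p_max > 0, p_max <= 1)
  p_max * (seq(0, 1, length.out = n))^2
}

#' Solve policies across an availability grid
#'
#' Agents do not re-solve the consumption problem online; policies are
#' pre-solved at a coarse grid of acquisition probabilities and each agent
#' indexes the policy nearest its current experience-based estimate.
#'
#' @param p_levels Increasing vector of acquisition probabilities (see
#'   [availability_levels()]).
#' @inheritParams solve_policy
#' @return An object of class `policy_set`.
#' @export
solve_policy_set <- function(p_levels = availability_levels(),
                             params = environment_params(),
                             grid = grid_spec(), gamma = 0.995, tol = 1e-6,
                             max_iter = 20000L) {
  stopifnot(is.numeric(p_levels), length(p_levels) >= 1,
            !is.unsorted(p_levels), all(p_levels >= 0), all(p_levels <= 1))
  policies <- vector("list", length(p_levels))
  V_prev <- NULL                  # warm-start each level from the last
  for (i in seq_along(p_levels)) {
    policies[[i]] <- solve_policy(p_levels[i], params = params, grid = grid,
                                  gamma = gamma, tol = tol,
                                  max_iter = max_iter, V_init = V_prev)
    V_prev <- as.vector(policies[[i]]$value)
  }
  # stacked fraction array for fast vectorised lookup:
  # [p_level, E_bin, S_bin, acq_flag]
  px <- array(0, c(length(p_levels), grid$n_E, grid$n_S, 2L))
  for (i in seq_along(policies)) px[i, , , ] <- policies[[i]]$x_frac
  structure(list(p_levels = p_levels, policies = policies, px = px,
                 grid = grid, params = params, gamma = gamma),
            class = "policy_set")
}

#' @export
print.policy_set <- function(x, ...) {
  cat("Policy set:", length(x$p_levels), "availability levels in [",
      min(x$p_levels), ",", max(x$p_levels), "], grid",
      x$grid$n_E, "x", x$grid$n_S, "\n")
  invisible(x)
}

# nearest availability level index for each p_hat
.nearest_p_idx <- function(p_levels, p_hat) {
  if (length(p_levels) == 1L) return(rep(1L, length(p_hat)))
  mids <- (p_levels[-1L] + p_levels[-length(p_levels)]) / 2
  findInterval(p_hat, mids) + 1L
}

# nearest grid-bin index on a uniform grid from 0 to hi with n points
.nearest_bin <- function(v, hi, n) {
  pmin(n, pmax(1L, as.integer(round(v / hi * (n - 1))) + 1L))
}

#' Optimal consumption at a state
#'
#' Looks up the solved policy at the grid cell nearest the queried energy,
#' store, and acquisition flag, and scales the stored fraction by the actual
#' pool. Queries outside the represented grid (store above `S_cap`, energy
#' outside `[0, E_max]`) are clamped with a warning.
#'
#' @param policy A `consumption_policy` from [solve_policy()].
#' @param E Energy level(s) after the drain.
#' @param S Store level(s) before acquisition.
#' @param acquired Amount(s) just acquired (0 or `rho`; any positive value
#'   selects the acquisition branch of the policy).
#' @return Amount(s) to consume, in `[0, S + acquired]`.
#' @export
optimal_consumption <- function(policy, E, S, acquired = 0) {
  if (!inherits(policy, "consumption_policy"))
    stop("'policy' must be a solved consumption_policy", call. = FALSE)
  n <- max(length(E), length(S), length(acquired))
  E <- rep_len(E, n); S <- rep_len(S, n); acquired <- rep_len(acquired, n)
  p <- policy$params
  if (any(E < 0 | E > p$E_max | S < 0 | S > policy$grid$S_cap)) {
    warning("state outside policy grid; clamping", call. = FALSE)
    E <- pmin(p$E_max, pmax(0, E))
    S <- pmax(0, S)
  }
  eb <- .nearest_bin(E, p$E_max, policy$grid$n_E)
  sb <- .nearest_bin(pmin(S, policy$grid$S_cap), policy$grid$S_cap,
                     policy$grid$n_S)
  acq <- as.integer(acquired > 0) + 1L
  frac <- policy$x_frac[cbind(eb, sb, acq)]
  frac * (S + acquired)
}

#' Experience-based availability estimate
#'
#' Agents track resource availability as an exponential moving average of
#' their own acquisition outcomes. Because resources lost to competitors
#' never enter the agent's experience, the estimate is biased downward
#' exactly as competition intensifies — the intended coupling between
#' population density and perceived scarcity.
#'
#' @param p_hat Current estimate, in `[0, 1]`.
#' @param lambda Memory parameter in `(0, 1)`: weight of the newest outcome.
#' @return An object of class `availability_estimate`.
#' @export
availability_estimate <- function(p_hat, lambda = 0.01) {
  stopifnot(is.numeric(p_hat), p_hat >= 0, p_hat <= 1,
            is.numeric(lambda), lambda > 0, lambda < 1)
  structure(list(p_hat = p_hat, lambda = lambda),
            class = "availability_estimate")
}

#' Update an availability estimate with one outcome
#'
#' `p_hat' = (1 - lambda) * p_hat + lambda * 1{acquired}`; the estimate
#' stays in `[0, 1]`.
#'
#' @param est An [availability_estimate()].
#' @param acquired Logical: did the agent acquire a resource this step?
#' @return The updated `availability_estimate`.
#' @export
update_availability <- function(est, acquired) {
  est$p_hat <- (1 - est$lambda) * est$p_hat +
    est$lambda * as.numeric(isTRUE(acquired) | (is.numeric(acquired) && acquired > 0))
  est
}

#' Serialize a consumption policy
#'
#' Writes the policy as a flat CSV (`E_bin`, `S_bin`, `acquired_flag`, `x`,
#' `x_frac`) plus a JSON sidecar of solver metadata (acquisition
#' probability, discount, grid, residual). `x` is the consumption amount at
#' the cell's nominal pool (`S_bin` value plus `rho` on the acquisition
#' branch).
#'
#' @param policy A `consumption_policy`.
#' @param path Path of the CSV to write; the sidecar is `paste0(path,
#'   ".json")`.
#' @return `path`, invisibly.
#' @export
write_policy <- function(policy, path) {
  g <- policy$grid
  cells <- expand.grid(E_bin = seq_len(g$n_E), S_bin = seq_len(g$n_S),
                       acquired_flag = 0:1)
  frac <- policy$x_frac[cbind(cells$E_bin, cells$S_bin,
                              cells$acquired_flag + 1L)]
  pool <- policy$S_grid[cells$S_bin] + cells$acquired_flag * policy$params$rho
  cells$x <- frac * pool
  cells$x_frac <- frac
  utils::write.csv(cells, path, row.names = FALSE)
  meta <- list(p_acquire = policy$p_acquire, gamma = policy$gamma,
               tol = policy$tol, residual = policy$residual,
               iterations = policy$iterations,
               horizon = if (is.finite(policy$horizon)) policy$horizon else "Inf",
               grid = unclass(policy$grid), params = unclass(policy$params))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a serialized consumption policy
#'
#' Reconstructs a usable `consumption_policy` from the CSV + JSON pair
#' written by [write_policy()]. The value surface is not persisted; the
#' returned object carries the policy (sufficient for simulation) with
#' `value = NULL`.
#'
#' @param path Path of the CSV written by [write_policy()].
#' @return A `consumption_policy`.
#' @export
read_policy <- function(path) {
  cells <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  grid <- grid_spec(meta$grid$n_E, meta$grid$n_S, meta$grid$S_cap,
                    meta$grid$n_x)
  params <- environment_params(meta$params$R, meta$params$drain,
                               meta$params$rho, meta$params$E_max,
                               meta$params$u)
  x_frac <- array(0, c(grid$n_E, grid$n_S, 2L))
  x_frac[cbind(cells$E_bin, cells$S_bin, cells$acquired_flag + 1L)] <-
    cells$x_frac
  fracs <- seq(0, 1, length.out = grid$n_x)
  frac_idx <- array(match(round(x_frac, 12), round(fracs, 12)),
                    dim(x_frac))
  structure(list(
    E_grid = seq(0, params$E_max, length.out = grid$n_E),
    S_grid = seq(0, grid$S_cap, length.out = grid$n_S),
    fracs = fracs, x_frac = x_frac, frac_idx = frac_idx, value = NULL,
    p_acquire = meta$p_acquire, gamma = meta$gamma, tol = meta$tol,
    residual = meta$residual, iterations = meta$iterations,
    horizon = if (identical(meta$horizon, "Inf")) Inf else meta$horizon,
    grid = grid, params = params
  ), class = "consumption_policy")
}
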