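env <- environment_params(R = 0.01, u = 30)

# ---- independent finite-horizon oracle -------------------------------------
# Exhaustive expectimax tree walk over the discretized decision process: at
# every stage all candidate consumption fractions are enumerated and chance
# nodes (acquisition, interpolation corners) are expanded explicitly. No
# value arrays are reused, so this shares nothing with the solver's
# synchronous sweeps.
oracle_value <- function(iE, jS, h, p, env, grid, gamma) {
  if (h == 0L) return(0)
  E_grid <- seq(0, env$E_max, length.out = grid$n_E)
  S_grid <- seq(0, grid$S_cap, length.out = grid$n_S)
  fracs <- seq(0, 1, length.out = grid$n_x)
  stepE <- env$E_max / (grid$n_E - 1)
  stepS <- grid$S_cap / (grid$n_S - 1)
  Ed <- max(0, E_grid[iE] - env$drain)
  branch <- function(a) {                     # a: 0 or rho acquired
    best <- -Inf
    for (f in fracs) {
      pool <- S_grid[jS] + a
      x <- f * pool
      E2 <- env$E_max - (env$E_max - Ed) * exp(-env$u * x / env$E_max)
      S2 <- min(grid$S_cap, pool - x)
      i0 <- min(floor(E2 / stepE), grid$n_E - 2); wE <- E2 / stepE - i0
      j0 <- min(floor(S2 / stepS), grid$n_S - 2); wS <- S2 / stepS - j0
      ev <- 0
      for (bi in 0:1) for (bj in 0:1) {
        w <- (if (bi) wE else 1 - wE) * (if (bj) wS else 1 - wS)
        if (w > 0)
          ev <- ev + w * oracle_value(i0 + bi + 1L, j0 + bj + 1L, h - 1L,
                                      p, env, grid, gamma)
      }
      best <- max(best, E2 + gamma * ev)
    }
    best
  }
  if (p == 0) branch(0)
  else if (p == 1) branch(env$rho)
  else (1 - p) * branch(0) + p * branch(env$rho)
}

test_that("finite-horizon backward induction matches exhaustive tree search", {
  grid <- grid_spec(n_E = 4, n_S = 3, S_cap = 12, n_x = 3)
  for (p in c(0, 1)) {
    pol <- solve_policy(p, env, grid, gamma = 0.9, horizon = 5)
    # depth-4 oracle values at every state, then one explicit decision layer
    V4 <- outer(1:4, 1:3, Vectorize(function(i, j)
      oracle_value(i, j, 4L, p, env, grid, gamma = 0.9)))
    # full-depth check at two corner states: all 3^5 action paths enumerated
    for (s in list(c(1L, 1L), c(4L, 3L))) {
      expect_equal(pol$value[s[1], s[2]],
                   oracle_value(s[1], s[2], 5L, p, env, grid, gamma = 0.9),
                   tolerance = 1e-10)
    }
    # greedy first action against the oracle's decision layer, all states
    E_grid <- pol$E_grid; S_grid <- pol$S_grid; fracs <- pol$fracs
    stepE <- env$E_max / 3; stepS <- grid$S_cap / 2
    for (i in 1:4) for (j in 1:3) {
      Ed <- max(0, E_grid[i] - env$drain)
      a <- p * env$rho
      q <- sapply(fracs, function(f) {
        pool <- S_grid[j] + a; x <- f * pool
        E2 <- env$E_max - (env$E_max - Ed) * exp(-env$u * x / env$E_max)
        S2 <- min(grid$S_cap, pool - x)
        i0 <- min(floor(E2 / stepE), 2); wE <- E2 / stepE - i0
        j0 <- min(floor(S2 / stepS), 1); wS <- S2 / stepS - j0
        ev <- (1 - wE) * (1 - wS) * V4[i0 + 1, j0 + 1] +
          wE * (1 - wS) * V4[i0 + 2, j0 + 1] +
          (1 - wE) * wS * V4[i0 + 1, j0 + 2] +
          wE * wS * V4[i0 + 2, j0 + 2]
        E2 + 0.9 * ev
      })
      expect_equal(pol$frac_idx[i, j, (p == 1) + 1L], which.max(q))
    }
  }
})

test_that("stochastic acquisition matches the expectimax oracle", {
  grid <- grid_spec(n_E = 4, n_S = 3, S_cap = 12, n_x = 3)
  pol <- solve_policy(0.5, env, grid, gamma = 0.9, horizon = 3)
  for (s in list(c(1L, 1L), c(2L, 2L), c(4L, 3L))) {
    expect_equal(pol$value[s[1], s[2]],
                 oracle_value(s[1], s[2], 3L, 0.5, env, grid, gamma = 0.9),
                 tolerance = 1e-10)
  }
})

test_that("value iteration converges, reports residuals, and errors on a cap", {
  grid <- grid_spec(n_E = 10, n_S = 5, S_cap = 20, n_x = 5)
  pol <- solve_policy(0.02, env, grid, gamma = 0.95, tol = 1e-7)
  expect_lt(pol$residual, 1e-7)
  expect_error(solve_policy(0.02, env, grid, gamma = 0.95, tol = 1e-12,
                            max_iter = 3L), "did not converge")
  # value function non-decreasing in E and in S
  expect_true(all(apply(pol$value, 2, diff) >= -1e-9))
  expect_true(all(apply(pol$value, 1, diff) >= -1e-9))
})

test_that("optimal consumption respects the pool and trivial cases", {
  ps <- tiny_policies()
  pol <- ps$policies[[2]]
  # nothing available -> nothing consumed
  expect_equal(optimal_consumption(pol, E = 0, S = 0, acquired = 0), 0)
  x <- optimal_consumption(pol, E = c(0, 30, 80), S = c(0, 10, 25),
                           acquired = c(10, 0, 10))
  expect_true(all(x >= 0 & x <= c(0, 10, 25) + c(10, 0, 10)))
  expect_warning(optimal_consumption(pol, E = 0, S = 1e6, acquired = 0),
                 "clamp")
  expect_error(optimal_consumption(list(), 0, 0, 0), "solved")
})

test_that("solved policy dominates every fixed-fraction rule", {
  ps <- tiny_policies()
  env0 <- ps$params
  acc <- list(p_auto = 0.01, p_ctrl = 0.01)
  solved <- simulate_lifetime(1, acc, env0, ps, steps = 400, seed = 21,
                              n_rep = 300)
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    fixed <- ps
    fixed$px[] <- f
    mf <- suppressWarnings(simulate_lifetime(1, acc, env0, fixed,
                                             steps = 400, seed = 21,
                                             n_rep = 300))
    se <- sqrt(var(solved) / 300 + var(mf) / 300)
    expect_gt(mean(solved) - mean(mf), -3 * se)
  }
})

test_that("scarcer environments induce (weakly) more storage", {
  ps <- tiny_policies()
  lo <- ps$policies[[2]]$x_frac     # p = 0.0025
  hi <- ps$policies[[5]]$x_frac     # p = 0.2
  expect_lte(mean(lo), mean(hi) + 1e-9)
  expect_gte(mean(lo <= hi + 1e-9), 0.9)
})

test_that("availability estimate updates as an EMA and converges in mean", {
  est <- availability_estimate(0.5, lambda = 0.1)
  expect_equal(update_availability(est, TRUE)$p_hat, 0.55)
  est0 <- availability_estimate(0, lambda = 0.1)
  expect_equal(update_availability(est0, FALSE)$p_hat, 0)
  # long-run time average matches the true acquisition rate
  set.seed(4)
  p <- 0.3
  lam <- 0.05
  hits <- runif(1e5) < p
  ph <- as.numeric(stats::filter(lam * hits, 1 - lam, method = "recursive"))
  m <- mean(ph[-(1:500)])
  # stationary sd of the EMA, thinned to effectively independent samples
  se <- sqrt(lam / (2 - lam) * p * (1 - p)) / sqrt(1e5 * lam / 2)
  expect_lt(abs(m - p), 3 * se + 0.003)
})

test_that("policies round-trip through CSV + JSON serialization", {
  ps <- tiny_policies()
  pol <- ps$policies[[3]]
  path <- file.path(tempdir(), "pol.csv")
  write_policy(pol, path)
  back <- read_policy(path)
  expect_equal(back$x_frac, pol$x_frac)
  expect_equal(back$p_acquire, pol$p_acquire)
  expect_equal(back$grid$n_E, pol$grid$n_E)
  expect_equal(optimal_consumption(back, 10, 5, 10),
               optimal_consumption(pol, 10, 5, 10))
  unlink(c(path, paste0(path, ".json")))
})
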