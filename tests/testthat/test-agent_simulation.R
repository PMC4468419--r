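# brute-force contest oracle: enumerate the discrete outcome tree for a
# focal agent in mode m ("auto"/"ctrl") given the population state
enumerate_access <- function(mode, R, p_contest, share_auto, w_auto) {
  p <- 0
  # uncontested encounter
  p <- p + R * (1 - p_contest) * 1
  # contested, opponent automatic
  win_vs_auto <- if (mode == "auto") 0.5 else 1 - w_auto
  p <- p + R * p_contest * share_auto * win_vs_auto
  # contested, opponent controlled
  win_vs_ctrl <- if (mode == "auto") w_auto else 0.5
  p <- p + R * p_contest * (1 - share_auto) * win_vs_ctrl
  p
}

test_that("access probabilities match enumeration of contest outcomes", {
  for (w in c(0.6, 1.0)) for (s in c(0, 0.3, 1)) for (R in c(0.1, 0.02)) {
    comp <- competition_model(kappa = 0.05, w_auto = w)
    for (N in c(1, 5, 50)) {
      acc <- access_probabilities(R, N, s, comp)
      pc <- min(1, 0.05 * (N - 1))
      expect_equal(acc$p_auto, enumerate_access("auto", R, pc, s, w),
                   tolerance = 1e-12)
      expect_equal(acc$p_ctrl, enumerate_access("ctrl", R, pc, s, w),
                   tolerance = 1e-12)
      expect_lte(acc$p_ctrl, acc$p_auto + 1e-12)
    }
  }
})

test_that("winner probabilities are conserved in every mode pairing", {
  # for one contested resource the two contestants' win chances sum to 1
  for (w in c(0.6, 1)) {
    expect_equal(0.5 + 0.5, 1)                       # same-mode split
    expect_equal(w + (1 - w), 1)                     # auto vs ctrl
  }
  # consequence at the population level: with everyone in one mode the
  # per-capita contested acquisition rate is R/2
  comp <- competition_model(kappa = 1, w_auto = 0.8)
  acc <- access_probabilities(0.2, 2, 1, comp)       # p_contest = 1, all auto
  expect_equal(acc$p_auto, 0.1)
  acc2 <- access_probabilities(0.2, 2, 0, comp)      # all controlled
  expect_equal(acc2$p_ctrl, 0.1)
})

test_that("edge cases from the contest rules come out exactly", {
  comp <- competition_model(kappa = 1, w_auto = 1)
  expect_equal(access_probabilities(0.1, 1, 0.5, comp)$p_auto, 0.1)
  expect_equal(access_probabilities(0.1, 1, 0.5, comp)$p_ctrl, 0.1)
  acc <- access_probabilities(0.1, 2, 1, comp)       # p_contest = 1
  expect_equal(acc$p_auto, 0.05)                     # split among automatics
  expect_equal(acc$p_ctrl, 0)                        # always loses to them
  acc2 <- access_probabilities(0.1, 2, 0, comp)
  expect_equal(acc2$p_ctrl, 0.05)                    # ctrl vs ctrl splits
  expect_error(access_probabilities(0.1, 0, 0.5, comp), "N")
  expect_error(competition_model(w_auto = 0.4), "w_auto")
})

test_that("saturating contest form stays in [0,1) and increases with N", {
  comp <- competition_model(kappa = 0.01, form = "saturating")
  pcs <- sapply(c(2, 10, 100, 1000),
                function(N) access_probabilities(0.1, N, 1, comp)$p_contest)
  expect_true(all(diff(pcs) > 0))
  expect_true(all(pcs < 1))
})

test_that("lifetime simulation honours starvation and saturation limits", {
  ps <- tiny_policies()
  env <- ps$params
  # no access, no control: drains to the floor forever
  expect_equal(as.numeric(
    simulate_lifetime(0, list(p_auto = 0, p_ctrl = 0), env, ps,
                      steps = 200, seed = 1)), 0)
  # guaranteed access for an automatic consumer: steady drain/gorge cycle
  # whose fixed point is E* = E_max - (E_max - (E* - d)) exp(-u rho / E_max)
  m <- simulate_lifetime(0, list(p_auto = 1, p_ctrl = 1), env, ps,
                         steps = 2000, seed = 2)
  fp <- 0
  for (i in 1:200)
    fp <- env$E_max -
      (env$E_max - max(0, fp - env$drain)) * exp(-env$u * env$rho / env$E_max)
  expect_lt(abs(m - fp), 2)
  expect_gt(m, env$E_max - 3 * env$drain)     # near satiety minus the drain
})

test_that("same seed reproduces a lifetime exactly", {
  ps <- tiny_policies()
  acc <- list(p_auto = 0.02, p_ctrl = 0.02)
  a <- simulate_lifetime(0.5, acc, ps$params, ps, steps = 300, seed = 9,
                         n_rep = 5)
  b <- simulate_lifetime(0.5, acc, ps$params, ps, steps = 300, seed = 9,
                         n_rep = 5)
  expect_identical(a, b)
})

test_that("controlled beats automatic at matched scarce access", {
  ps <- tiny_policies()
  acc <- list(p_auto = 0.01, p_ctrl = 0.01)
  m1 <- simulate_lifetime(1, acc, ps$params, ps, steps = 600, seed = 3,
                          n_rep = 200)
  m0 <- simulate_lifetime(0, acc, ps$params, ps, steps = 600, seed = 4,
                          n_rep = 200)
  se <- sqrt(var(m1) / 200 + var(m0) / 200)
  expect_gt(mean(m1) - mean(m0), 3 * se)
})

test_that("the evolvable automatic habit generalizes full consumption", {
  ps <- tiny_policies()
  env <- ps$params
  acc <- list(p_auto = 0.05, p_ctrl = 0.05)
  # at C = 0 the store never fills, so target = E_max with store access
  # reduces exactly to the baseline habit under the same seed
  base <- simulate_lifetime(0, acc, env, ps, steps = 400, seed = 5)
  ap <- automatic_policy("target_level", target = env$E_max, params = env)
  same <- simulate_lifetime_evolvable_auto(0, ap, acc, env, ps, steps = 400,
                                           seed = 5)
  expect_equal(as.numeric(base), as.numeric(same))
  # a zero target never consumes: everything is banked, energy stays 0
  ap0 <- automatic_policy("target_level", target = 0, params = env)
  expect_equal(as.numeric(
    simulate_lifetime_evolvable_auto(0, ap0, acc, env, ps, steps = 200,
                                     seed = 6)), 0)
  # full_consume mode delegates
  apf <- automatic_policy("full_consume", params = env)
  expect_equal(
    as.numeric(simulate_lifetime_evolvable_auto(0, apf, acc, env, ps,
                                                steps = 100, seed = 7)),
    as.numeric(simulate_lifetime(0, acc, env, ps, steps = 100, seed = 7)))
})

test_that("fitness tables record metadata and reproduce known cells", {
  tab <- tiny_table()
  expect_equal(tab$n_sims_per_cell,
               as.integer(round(20000 / (5 * 6 * 6))))
  expect_equal(tab$steps, 300)
  expect_true(all(tab$values >= 0 & tab$values <= tab$params$E_max))
  # starvation corner: no access at all
  expect_equal(lookup_fitness(tab, 0, 0, 0), 0)
  # mean E non-decreasing in access at fixed C, within Monte-Carlo error
  f <- lookup_fitness(tab, 0.5, tab$p_auto_levels, tab$p_auto_levels)
  expect_true(all(diff(f) > -3))
  expect_gt(f[6], f[1])
  expect_error(build_fitness_table(numeric(0), 0.1,
                                   policies = tiny_policies()), "empty")
})

test_that("table lookup is exact at nodes, linear between, and bounded", {
  tab <- synthetic_table(function(C, pa, pc) 10 * C + 100 * pa + 50 * pc)
  # exact at grid nodes
  expect_equal(lookup_fitness(tab, 0.5, 0.02, 0.005),
               10 * 0.5 + 100 * 0.02 + 50 * 0.005)
  # midway between two nodes differing only in C: arithmetic mean
  v1 <- lookup_fitness(tab, 0.25, 0.02, 0.02)
  v2 <- lookup_fitness(tab, 0.5, 0.02, 0.02)
  expect_equal(lookup_fitness(tab, 0.375, 0.02, 0.02), (v1 + v2) / 2)
  # interpolation stays inside the enclosing cell's corner range
  tab2 <- tiny_table()
  set.seed(31)
  for (i in 1:50) {
    q <- c(runif(1), runif(2, 0, 0.05))
    v <- lookup_fitness(tab2, q[1], q[2], q[3])
    expect_gte(v, min(tab2$values) - 1e-9)
    expect_lte(v, max(tab2$values) + 1e-9)
  }
  expect_error(lookup_fitness(tab2, 1.2, 0.01, 0.01), "unit cube")
  expect_error(lookup_fitness(tab2, 0.5, 0.9, 0.01), "span")
})

test_that("fitness tables round-trip through CSV + JSON", {
  tab <- tiny_table()
  path <- file.path(tempdir(), "tab.csv")
  write_fitness_table(tab, path)
  back <- read_fitness_table(path)
  expect_equal(back$values, tab$values)
  expect_equal(back$C_levels, tab$C_levels)
  expect_equal(back$params$R, tab$params$R)
  expect_equal(lookup_fitness(back, 0.3, 0.01, 0.008),
               lookup_fitness(tab, 0.3, 0.01, 0.008))
  unlink(c(path, paste0(path, ".json")))
})
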