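# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

tiny_env <- function(...) environment_params(...)

tiny_grid <- function() grid_spec(n_E = 15, n_S = 8, S_cap = 20, n_x = 5)

# small but usable policy set for engine-level tests (seconds to solve)
tiny_policies <- function() cached("tiny_policies", function() {
  suppressWarnings(solve_policy_set(
    p_levels = c(0, 0.0025, 0.01, 0.05, 0.2),
    params = tiny_env(), grid = grid_spec(n_E = 21, n_S = 11, S_cap = 30,
                                          n_x = 7),
    gamma = 0.98, tol = 1e-5))
})

# small fitness table over p in [0, 0.05] for evolution-level tests
tiny_table <- function() cached("tiny_table", function() {
  suppressWarnings(build_fitness_table(
    C_levels = seq(0, 1, 0.25),
    p_auto_levels = c(0, 0.0025, 0.005, 0.0125, 0.025, 0.05),
    params = tiny_env(), policies = tiny_policies(),
    n_sims = 20000, steps = 300, seed = 11))
})

# hand-built fitness table with prescribed values (no simulation)
synthetic_table <- function(values_fun,
                            C_levels = seq(0, 1, 0.25),
                            p_levels = c(0, 0.005, 0.02, 0.05)) {
  tab <- suppressWarnings(build_fitness_table(
    C_levels = C_levels, p_auto_levels = p_levels,
    params = tiny_env(), policies = tiny_policies(),
    n_sims = length(C_levels) * length(p_levels)^2, steps = 1, seed = 1))
  g <- expand.grid(C = C_levels, p_auto = p_levels, p_ctrl = p_levels)
  tab$values <- array(values_fun(g$C, g$p_auto, g$p_ctrl),
                      dim(tab$values))
  tab
}

# ---- full-scale world for the acceptance suite (minutes; built once) ----

acc_env <- function() environment_params()          # package defaults

acc_policies <- function() cached("acc_policies", function() {
  suppressWarnings(solve_policy_set(params = acc_env()))
})

# per-richness fitness tables at the reference build scale
acc_table <- function(R) {
  key <- paste0("acc_table_", R)
  cached(key, function() {
    suppressWarnings(build_fitness_table(
      C_levels = seq(0, 1, 0.2),
      p_auto_levels = seq(0, R, length.out = 7),
      params = acc_env(), policies = acc_policies(),
      n_sims = 30000, steps = 1000, seed = 99))
  })
}

# full-span table for variable-richness runs (richness may climb to 1)
acc_table_full <- function() cached("acc_table_full", function() {
  suppressWarnings(build_fitness_table(
    C_levels = seq(0, 1, 0.2),
    p_auto_levels = availability_levels(11, 1),
    params = acc_env(), policies = acc_policies(),
    n_sims = 30000, steps = 1000, seed = 98))
})

equilibrium_mean_C <- function(traj, window = 0.1) {
  n <- nrow(traj)
  mean(traj$mean_C[seq.int(max(1, n - ceiling(window * n) + 1), n)])
}
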