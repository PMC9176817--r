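# Expensive optimal-control solutions are shared across test files through a
# session-level cache (test_dir runs all files in one process).

.sol_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sol_cache, inherits = FALSE))
    assign(key, force(expr), envir = .sol_cache)
  get(key, envir = .sol_cache, inherits = FALSE)
}

get_balance_healthy <- function()
  cached("bal_healthy", solve_balance(balance_condition()))

get_balance_vl <- function()
  cached("bal_vl", solve_balance(balance_condition(sensory = "vestibular_loss")))

get_translation_sweep <- function()
  cached("sweep_trans", sweep_conditions(
    lapply(1:7, function(i) balance_condition("translation", i))))

get_reach <- function(kind)
  cached(paste0("reach_", kind), solve_reach(reach_task(kind)))

get_circle_ensemble <- function() {
  cached("circle_ens", {
    sol <- get_reach("circle")
    simulate_ensemble(sol$policy, attr(sol, "model"), n_episodes = 100,
                      seed = 4242, dt_sim = 1e-3, t_final = 0.8,
                      x0 = sol$trajectory$mean[1, ])
  })
}
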