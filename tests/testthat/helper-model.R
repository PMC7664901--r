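# Shared fixtures and a cache for results reused across test files.
# All fixtures are built in code; expensive shared computations (steady-state
# solutions, the x1 sweep, replicate Monte Carlo runs) are computed once per
# test run and memoized here.

.xb_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .xb_test_cache, inherits = FALSE))
    assign(name, expr, envir = .xb_test_cache)
  get(name, envir = .xb_test_cache, inherits = FALSE)
}

default_model <- function() cached("model", crossbridge_model())
nonlinear_model <- function() cached("model_nl", crossbridge_model(elasticity = "nonlinear"))

model_vmax <- function() cached("vmax", xbridge:::xb_vmax(default_model()))

# 20-seed zero-load step experiments (shared by engine tests and acceptance)
step_experiments <- function() cached("steps20", {
  lapply(1:20, function(s) run_step_experiment(default_model(), seed = s,
                                               duration = 0.05))
})

# x1 sweep under the default study conditions (shared by acceptance blocks)
x1_sweep_result <- function() cached("sweep", run_x1_sweep(seed = 1))

# two-state (attach/detach) reduced scheme with constant windowed rates:
# the classical sliding-filament occupancy problem with a closed-form
# steady-state solution
two_state_model <- function(f1 = 40, g1 = 10, g2 = 1500, h = 8) {
  states <- data.frame(
    state = c("D", "A"), attached = c(FALSE, TRUE),
    xmin = c(NA, "zero"), g = c(0, 0), stringsAsFactors = FALSE)
  transitions <- data.frame(
    from = c("D", "A", "A"), to = c("A", "D", "D"),
    type = "irrev", k0 = c(f1, g1, g2), xref = NA, split = NA,
    reversible = FALSE,
    window_lo = c(0, 0, -Inf), window_hi = c(h, Inf, 0),
    stringsAsFactors = FALSE)
  crossbridge_model(states = states, transitions = transitions,
                    check_cycle = FALSE)
}

# all n! permutations of a vector (test-side oracle for exact Spearman p)
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}
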