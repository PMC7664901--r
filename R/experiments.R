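# Orchestrated computational experiments: force-velocity condition grids,
# zero-load step records, and the x1 parameter sweep (maximum power vs
# isometric force-rise rate).

#' Force-velocity curves across model conditions
#'
#' Computes steady-state force-velocity and power curves for the condition
#' grid 1 vs 3 binding sites per target zone crossed with linear vs nonlinear
#' cross-bridge elasticity, plus a summary table (F0, Vmax, Pmax per
#' condition).
#'
#' @param model base [crossbridge_model()]; each condition overrides
#'   `sites_per_zone` and `elasticity`.
#' @param n_heads ensemble size used for force scaling.
#' @param sites,elasticity condition levels.
#' @param n_points velocity samples per curve.
#' @param dx strain grid resolution, nm.
#' @return list of class `xb_fv_experiment`: `curves` (named list of
#'   [fv_curve()] objects) and `summary` (data frame).
#' @export
run_fv_experiment <- function(model = crossbridge_model(), n_heads = 3000,
                              sites = c(1L, 3L),
                              elasticity = c("linear", "nonlinear"),
                              n_points = 9, dx = 0.1) {
  curves <- list()
  rows <- list()
  for (s in sites) for (el in elasticity) {
    p <- model$params
    p$sites_per_zone <- s
    p$elasticity <- el
    m <- do.call(crossbridge_model,
                 c(p, list(states = model$states, transitions = model$transitions,
                           check_cycle = TRUE)))
    nm <- sprintf("%dsite_%s", s, el)
    cv <- fv_curve(m, n_heads = n_heads, n_points = n_points, dx = dx)
    curves[[nm]] <- cv
    rows[[nm]] <- data.frame(sites = s, elasticity = el, F0 = cv$F0,
                             vmax = cv$vmax, pmax = cv$pmax,
                             v_at_pmax = cv$v_at_pmax)
  }
  structure(list(curves = curves, summary = do.call(rbind, rows)),
            class = "xb_fv_experiment")
}

#' @export
print.xb_fv_experiment <- function(x, ...) {
  cat("Force-velocity experiment (per condition):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Zero-load step record for a small motor ensemble
#'
#' Simulates the displacement record of a small ensemble (default 18 heads,
#' the scale of myosin-rod cofilament optical-trap experiments) sliding
#' against zero load, detects displacement steps and clusters them in short
#' time windows.
#'
#' @param model a [crossbridge_model()].
#' @param n_heads ensemble size.
#' @param duration simulated time, s.
#' @param seed integer seed (reproducible record).
#' @param min_amplitude_nm step-detection threshold, nm.
#' @param window_ms clustering window, ms.
#' @return list of class `xb_step_experiment`: `trace`, `steps` (with
#'   clusters), `clusters` summary, `mean_velocity` (nm/s).
#' @export
run_step_experiment <- function(model = crossbridge_model(), n_heads = 18,
                                duration = 0.05, seed = 1,
                                min_amplitude_nm = 0.5, window_ms = 0.4) {
  tr <- simulate(model, mode = "zero_load", n_heads = n_heads,
                 duration = duration, seed = seed)
  steps <- cluster_steps(detect_steps(tr, min_amplitude_nm), window_ms)
  tspan <- max(tr$time) - min(tr$time)
  structure(list(trace = tr, steps = steps, clusters = attr(steps, "clusters"),
                 mean_velocity = if (tspan > 0)
                   (tr$position[length(tr$position)] - tr$position[1]) / tspan
                 else NA_real_,
                 seed = seed),
            class = "xb_step_experiment")
}

#' @export
print.xb_step_experiment <- function(x, ...) {
  cl <- x$clusters
  multi <- cl[cl$n_steps >= 2, , drop = FALSE]
  cat(sprintf("Step experiment: %d steps, %d clusters (%d with >= 2 steps)\n",
              nrow(x$steps), nrow(cl), nrow(multi)))
  cat(sprintf("  mean sliding velocity %.4g nm/s\n", x$mean_velocity))
  if (nrow(x$steps))
    cat(sprintf("  step amplitudes %.2g to %.2g nm\n",
                min(abs(x$steps$amplitude)), max(abs(x$steps$amplitude))))
  invisible(x)
}

#' Sweep the pre-power-stroke minimum position x1
#'
#' For each `x1` (with `x11` tied to `x1 - 0.5` nm) computes the maximum
#' steady-state power and the rate of isometric force development fitted to
#' replicate Monte Carlo transients, then reports Spearman correlations of
#' `x1` with maximum power and with the pooled force-rise rates. Increasing
#' `x1` lengthens the distance over which an attached head can do positive
#' work (raising power) while shifting the attachment optimum away from
#' strains that permit progression into the high-force states (slowing
#' isometric force development) -- opposite trends in the two observables.
#'
#' @param model base [crossbridge_model()].
#' @param x1_values swept `x1` positions, nm (>= 3 values).
#' @param n_heads_rise ensemble size of the isometric force-rise simulations
#'   (default 3000, the half-sarcomere head count of a 20 um filament at
#'   saturating motor density).
#' @param reps Monte Carlo replicates per `x1`.
#' @param duration isometric simulation time, s; the default (0.2 s) covers
#'   the rising phase of force development, which is what the fitted rate
#'   quantifies (longer windows mix in the much slower final creep of the
#'   quasi-plateau toward the true stationary state).
#' @param seed integer seed.
#' @param init initial condition of the isometric runs (default `"MDP"`, the
#'   detached start every simulation of the engine otherwise uses; see the
#'   vignette for why the all-attached start does not yield a well-defined
#'   rise rate).
#' @param rise_window fit window for [fit_force_rise()].
#' @param dx strain grid resolution, nm.
#' @return object of class `x1_sweep`: per-x1 table (`pmax`, mean rise rate
#'   +/- SEM), the replicate rate matrix, and `spearman_power` /
#'   `spearman_rise` correlation results.
#' @export
run_x1_sweep <- function(model = crossbridge_model(),
                         x1_values = seq(7.5, 9.5, by = 0.5),
                         n_heads_rise = 3000, reps = 4, duration = 0.2,
                         seed = 1, init = "MDP", rise_window = "full",
                         dx = 0.1) {
  if (length(x1_values) < 3) stop("need at least 3 x1 values")
  if (length(unique(x1_values)) < 2) stop("constant input: correlation undefined")
  pmax <- numeric(length(x1_values))
  rates <- matrix(NA_real_, length(x1_values), reps)
  for (i in seq_along(x1_values)) {
    x1 <- x1_values[i]
    p <- model$params
    p$x1 <- x1
    p$x11 <- x1 - 0.5
    m <- do.call(crossbridge_model,
                 c(p, list(states = model$states, transitions = model$transitions)))
    pmax[i] <- max_power(m, dx = dx)$pmax
    for (r in seq_len(reps)) {
      tr <- simulate(m, mode = "isometric", n_heads = n_heads_rise,
                     duration = duration, seed = seed + 1000 * i + r,
                     init = init, record_dt = 5e-4)
      rates[i, r] <- fit_force_rise(tr, window = rise_window)$k
    }
  }
  tab <- data.frame(x1 = x1_values, pmax = pmax,
                    rise_mean = rowMeans(rates),
                    rise_sem = apply(rates, 1, sd) / sqrt(reps))
  pooled_x1 <- rep(x1_values, times = reps)
  pooled_rate <- as.vector(rates)
  structure(list(table = tab, rates = rates, reps = reps,
                 spearman_power = spearman(x1_values, pmax),
                 spearman_rise = spearman(pooled_x1, pooled_rate),
                 seed = seed),
            class = "x1_sweep")
}

#' @export
print.x1_sweep <- function(x, ...) {
  cat("x1 sweep (x11 = x1 - 0.5 nm):\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("  Spearman r(x1, Pmax) = %.3g, p = %.4g (%s)\n",
              x$spearman_power$r, x$spearman_power$p, x$spearman_power$method))
  cat(sprintf("  Spearman r(x1, rise rate, pooled) = %.3g, p = %.4g (%s)\n",
              x$spearman_rise$r, x$spearman_rise$p, x$spearman_rise$method))
  invisible(x)
}

#' @export
plot.x1_sweep <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$table$x1, x$table$pmax, type = "b", pch = 16,
       xlab = "x1 (nm)", ylab = "max power (pN nm/s)", main = "power")
  plot(x$table$x1, x$table$rise_mean, type = "b", pch = 16,
       ylim = range(c(x$table$rise_mean - x$table$rise_sem,
                      x$table$rise_mean + x$table$rise_sem)),
       xlab = "x1 (nm)", ylab = "force-rise rate (1/s)", main = "force rise")
  arrows(x$table$x1, x$table$rise_mean - x$table$rise_sem,
         x$table$x1, x$table$rise_mean + x$table$rise_sem,
         angle = 90, code = 3, length = 0.03)
  invisible(x)
}
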