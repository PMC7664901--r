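# Steady-state (Huxley/Hill formalism) solver: state probabilities vs strain
# at fixed sliding velocity, force-velocity and power curves.
#
# The strain coordinate of every head advances at the sliding velocity, so the
# stationary transport problem -v dp/dx = kinetic fluxes is solved by a
# semi-Lagrangian march over a 0.1 nm grid (per-bin exact matrix-exponential
# propagators, rates evaluated at bin centres). Detached heads wrap
# periodically over the 36 nm repeat; attached heads dragged past the core
# boundary continue on an extended domain (down to -d) and their detachment
# reinjects detached probability one period up. At v = 0 the algebraic
# stationary problem is solved independently at every strain.

xb_grid <- function(model, dx = 0.1) {
  d <- model$params$d
  n_core <- round(d / dx)
  n_ext <- round((d / 2) / dx)
  x_top <- d / 2
  list(dx = dx, x_top = x_top, n_core = n_core, n_ext = n_ext,
       N = n_core + n_ext,
       centers = x_top - (seq_len(n_core + n_ext) - 0.5) * dx,
       edges = x_top - seq_len(n_core + n_ext) * dx)
}

xb_Q_array <- function(model, x) {
  n <- model$scheme$n_states
  A <- array(0, dim = c(n, n, length(x)))
  for (k in seq_along(x)) A[, , k] <- t(rate_matrix(model, x[k]))
  A
}

#' Steady-state state probabilities versus strain
#'
#' Solves for the stationary distribution of cross-bridge states over the
#' strain coordinate at a fixed sliding velocity. At `velocity = 0` the
#' algebraic flux balance is solved independently at every strain; at
#' `velocity > 0` the transport problem is solved over one 36 nm period with
#' periodic closure for detached heads and an open extension for attached
#' heads dragged past the boundary.
#'
#' @param model a [crossbridge_model()].
#' @param velocity sliding velocity, nm/s per half sarcomere (>= 0).
#' @param dx strain grid resolution, nm (default 0.1, matching the
#'   head-offset bin width).
#' @param tol fixed-point convergence tolerance (v > 0).
#' @param max_sweeps iteration cap; non-convergence raises an error with the
#'   residual.
#' @return An object of class `xb_occupancy`: grid `x`, per-strain
#'   conditional probabilities `p` (states x grid, columns sum to 1), mass
#'   distribution `rho` (sums to 1 overall), attached fraction, diagnostics.
#' @export
solve_state_probabilities <- function(model, velocity, dx = 0.1,
                                      tol = 1e-11, max_sweeps = 5000) {
  stopifnot(velocity >= 0)
  g <- xb_grid(model, dx)
  sc <- model$scheme
  n <- sc$n_states
  if (velocity == 0) {
    x <- g$centers[seq_len(g$n_core)]
    rho <- matrix(0, n, length(x))
    for (k in seq_along(x)) {
      Q <- rate_matrix(model, x[k])
      A <- t(Q)
      A[n, ] <- 1
      p <- tryCatch(solve(A, c(rep(0, n - 1), 1)), error = function(e) {
        sv <- svd(t(Q))           # fallback for (near-)singular generators
        v <- sv$u[, n]
        v / sum(v)
      })
      p[p < 0] <- 0
      rho[, k] <- p / sum(p)
    }
    mass <- rho / sum(rho)
    out <- list(x = x, p = rho, rho = mass, velocity = 0,
                converged = TRUE, sweeps = 0L, leak = 0)
  } else {
    A <- xb_Q_array(model, g$centers)
    det_idx <- which(!sc$states$attached)
    res <- cpp_steady_march(as.vector(A), n, g$N, det_idx, g$n_core,
                            g$dx / velocity, max_sweeps, tol)
    if (!res$converged)
      stop(sprintf("steady-state solver did not converge (residual %.3g after %d sweeps)",
                   res$delta, res$sweeps))
    rho <- res$rho
    mass <- rho / sum(rho)
    cs <- colSums(rho)
    p <- sweep(rho, 2, ifelse(cs > 0, cs, 1), "/")
    out <- list(x = g$edges, p = p, rho = mass, velocity = velocity,
                converged = TRUE, sweeps = res$sweeps,
                leak = res$leak / sum(res$rho))
  }
  out$attached_fraction <- sum(out$rho[sc$states$attached, , drop = FALSE])
  out$model <- model
  class(out) <- "xb_occupancy"
  out
}

#' @export
print.xb_occupancy <- function(x, ...) {
  cat(sprintf(
    "Steady-state occupancy at v = %g nm/s: attached fraction %.4f (%d strains)\n",
    x$velocity, x$attached_fraction, length(x$x)))
  invisible(x)
}

# per-head mean force from an occupancy object
xb_mean_force <- function(occ) {
  sc <- occ$model$scheme
  f <- 0
  for (s in which(sc$states$attached)) {
    f <- f + sum(occ$rho[s, ] *
                   elastic_force_num(occ$x - sc$states$xshift[s], occ$model$params))
  }
  # rho mass sums to 1 over the period, so this is already the per-head mean
  f
}

#' Ensemble force at a fixed sliding velocity
#'
#' Mean steady-state force: `n_heads` times the period-average over strain of
#' the attached-state probabilities weighted by the cross-bridge force law.
#'
#' @inheritParams solve_state_probabilities
#' @param n_heads ensemble size the force is scaled to.
#' @param occ optional precomputed [solve_state_probabilities()] result.
#' @return force in pN.
#' @export
force_at_velocity <- function(model, velocity, n_heads = 1, occ = NULL, dx = 0.1) {
  if (n_heads == 0) return(0)
  if (is.null(occ)) occ <- solve_state_probabilities(model, velocity, dx = dx)
  n_heads * xb_mean_force(occ)
}

#' Fit the Hill hyperbola to force-velocity data
#'
#' Least-squares fit of `(F + a)(v + b) = (F0 + a) b`.
#'
#' @param velocity,force numeric vectors.
#' @return list with coefficients `a`, `b`, `F0`, the fitted [stats::nls]
#'   object, and `vmax` implied by the fit.
#' @export
hill_fit <- function(velocity, force) {
  df <- data.frame(v = velocity, f = force)
  F0_0 <- max(force)
  start <- list(F0 = F0_0, a = 0.25 * F0_0, b = 0.25 * max(velocity[velocity > 0], 1))
  fit <- minpack.lm::nlsLM(
    f ~ ((F0 + a) * b) / (v + b) - a, data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  cf <- as.list(coef(fit))
  cf$vmax <- cf$b * cf$F0 / cf$a
  cf$fit <- fit
  cf
}

# root-find the unloaded (zero-force) velocity
xb_vmax <- function(model, dx = 0.1, v_hint = 2000) {
  f <- function(v) xb_mean_force(solve_state_probabilities(model, v, dx = dx))
  vhi <- v_hint
  fhi <- f(vhi)
  while (fhi > 0 && vhi < 1e6) { vhi <- vhi * 2; fhi <- f(vhi) }
  if (fhi > 0) stop("no force zero-crossing below 1e6 nm/s; extend the grid")
  vlo <- 0
  while (vhi / 2 > vlo && f(vhi / 2) < 0) vhi <- vhi / 2
  uniroot(f, c(max(vlo, vhi / 4), vhi), tol = 1e-3 * vhi)$root
}

#' Steady-state force-velocity and power curve
#'
#' Samples the force-velocity relation from isometric (`v = 0`, force `F0`)
#' to the unloaded velocity `V_max` (located by root finding on the solved
#' force), computes power `P = F v`, locates the maximum power, and fits the
#' Hill hyperbola.
#'
#' @inheritParams force_at_velocity
#' @param n_points number of velocity samples.
#' @param velocities optional explicit velocity grid (nm/s); must span the
#'   force zero-crossing if `vmax` is not located first.
#' @return An object of class `fv_curve` with the sampled points
#'   (velocity, force, power, attached fraction), `F0`, `vmax`, `pmax`,
#'   `v_at_pmax` and the Hill fit.
#' @export
fv_curve <- function(model, n_heads = 1, n_points = 13, velocities = NULL,
                     dx = 0.1) {
  vmax <- xb_vmax(model, dx = dx)
  if (is.null(velocities))
    velocities <- unique(sort(c(seq(0, vmax, length.out = n_points))))
  pts <- lapply(velocities, function(v) {
    occ <- solve_state_probabilities(model, v, dx = dx)
    fh <- xb_mean_force(occ)
    c(velocity = v, force = n_heads * fh, power = n_heads * fh * v,
      attached = occ$attached_fraction)
  })
  df <- as.data.frame(do.call(rbind, pts))
  F0 <- df$force[df$velocity == 0][1]
  pw <- function(v) -v * force_at_velocity(model, v, n_heads = n_heads, dx = dx)
  op <- optimize(pw, interval = c(0, vmax), tol = vmax * 2e-3)
  hill <- tryCatch(hill_fit(df$velocity, df$force), error = function(e) NULL)
  structure(list(points = df, F0 = F0, vmax = vmax, pmax = -op$objective,
                 v_at_pmax = op$minimum, hill = hill, n_heads = n_heads,
                 model = model),
            class = "fv_curve")
}

#' @export
print.fv_curve <- function(x, ...) {
  cat(sprintf("Force-velocity curve (%g head%s):\n", x$n_heads,
              if (x$n_heads == 1) "" else "s"))
  cat(sprintf("  F0 = %.4g pN, Vmax = %.4g nm/s, Pmax = %.4g pN nm/s at v = %.4g nm/s\n",
              x$F0, x$vmax, x$pmax, x$v_at_pmax))
  if (!is.null(x$hill))
    cat(sprintf("  Hill fit: a/F0 = %.3f, b = %.4g nm/s\n",
                x$hill$a / x$hill$F0, x$hill$b))
  invisible(x)
}

#' @export
as.data.frame.fv_curve <- function(x, ..., normalized = FALSE) {
  df <- x$points
  if (normalized) {
    df$force <- df$force / x$F0
    df$velocity <- df$velocity / x$vmax
    df$power <- df$power / (x$F0 * x$vmax)
  }
  df
}

#' @export
plot.fv_curve <- function(x, normalized = TRUE, ...) {
  df <- as.data.frame(x, normalized = normalized)
  op <- par(mar = c(4, 4, 1, 4))
  on.exit(par(op))
  plot(df$velocity, df$force, type = "b", pch = 16,
       xlab = if (normalized) "v / Vmax" else "velocity (nm/s)",
       ylab = if (normalized) "F / F0" else "force (pN)", ...)
  pr <- df$power / max(df$power) * max(df$force)
  lines(df$velocity, pr, col = 2, lty = 2)
  abline(h = 0, col = "grey")
  invisible(x)
}

#' Maximum power output of the steady-state force-velocity relation
#'
#' @inheritParams fv_curve
#' @return list with `pmax` (pN nm/s), `v_at_pmax` (nm/s) and `vmax`.
#' @export
max_power <- function(model, n_heads = 1, dx = 0.1) {
  vmax <- xb_vmax(model, dx = dx)
  pw <- function(v) -v * force_at_velocity(model, v, n_heads = n_heads, dx = dx)
  op <- optimize(pw, interval = c(0, vmax), tol = vmax * 2e-3)
  list(pmax = -op$objective, v_at_pmax = op$minimum, vmax = vmax)
}

#' Predict steady-state contractile observables
#'
#' @param object a [crossbridge_model()].
#' @param velocity sliding velocity (nm/s), scalar or vector.
#' @param type `"force"`, `"power"`, `"attached"` or `"probabilities"`.
#' @param n_heads ensemble size for force/power scaling.
#' @param dx strain grid resolution (nm).
#' @param ... unused.
#' @return numeric vector (or an `xb_occupancy` for `"probabilities"`).
#' @export
predict.crossbridge_model <- function(object, velocity = 0,
                                      type = c("force", "power", "attached",
                                               "probabilities"),
                                      n_heads = 1, dx = 0.1, ...) {
  type <- match.arg(type)
  if (type == "probabilities") {
    stopifnot(length(velocity) == 1)
    return(solve_state_probabilities(object, velocity, dx = dx))
  }
  vapply(velocity, function(v) {
    occ <- solve_state_probabilities(object, v, dx = dx)
    switch(type,
           force = n_heads * xb_mean_force(occ),
           power = n_heads * xb_mean_force(occ) * v,
           attached = occ$attached_fraction)
  }, numeric(1))
}
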