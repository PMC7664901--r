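# Monte Carlo engine: event-driven (Gillespie) simulation of head ensembles
# with quasi-static filament mechanics.
#
# Modes:
#   zero_load / constant_load -- the filament position re-equilibrates after
#     every event so the summed cross-bridge force equals the external load
#     (exact Gillespie: propensities are piecewise constant between events);
#     event-level trace.
#   isometric -- filament fixed; heads are independent; trace sampled on a
#     regular time grid.
#   velocity_clamp -- filament slides at fixed velocity; heads are
#     independent; rates are taken from per-bin tables on the same 0.1 nm
#     grid as the steady-state solver.

xb_init_states <- function(model, offsets, init) {
  sc <- model$scheme
  if (init == "MDP") {
    i0 <- which(sc$states$canon == "MDP")
    if (length(i0) == 0) i0 <- which(!sc$states$attached)[1]  # custom schemes
    if (is.na(i0[1])) stop("scheme has no detached state to initialize from")
    return(rep(i0[1], length(offsets)))
  }
  if (init != "AMDP_PP") stop("init must be 'MDP' or 'AMDP_PP'")
  offs <- sc$site_offsets
  vapply(offsets, function(x) {
    j <- which.min(abs(x - offs))
    i0 <- which(sc$states$canon == "AMDP_PP" & sc$states$site == j)
    if (length(i0) != 1) stop("scheme has no AMDP_PP state")
    i0
  }, integer(1))
}

xb_trace <- function(res, model, n_heads, mode, seed, record, load = 0,
                     velocity = NA_real_) {
  counts <- res$counts
  colnames(counts) <- model$states$state
  structure(list(
    time = res$time, position = res$position, force = res$force,
    counts = counts, n_heads = n_heads, mode = mode, load = load,
    velocity = velocity, seed = seed, record = record,
    params = model$params,
    diagnostics = res[intersect(c("held_events", "runaway", "n_events"), names(res))]
  ), class = "xb_trace")
}

#' Simulate stochastic trajectories of a motor ensemble
#'
#' Runs the event-driven (Gillespie) Monte Carlo engine. Waiting times are
#' exponential in the summed propensity of all head transitions at their
#' current strain; after every event in the load-bearing modes the filament
#' position is re-equilibrated so the total cross-bridge force matches the
#' external load (quasi-static mechanics, which keeps propensities piecewise
#' constant and the algorithm exact).
#'
#' @param object a [crossbridge_model()].
#' @param nsim number of replicate trajectories.
#' @param seed integer seed; replicate `i` uses `seed + i - 1`.
#' @param mode `"zero_load"`, `"constant_load"`, `"isometric"` or
#'   `"velocity_clamp"`.
#' @param n_heads ensemble size (ignored when `ensemble` is given).
#' @param ensemble optional [motor_ensemble()] fixing head placements.
#' @param duration simulated time, s.
#' @param load external load, pN (`constant_load`).
#' @param velocity sliding velocity, nm/s (`velocity_clamp`).
#' @param init initial state of every head: `"MDP"` (detached, post
#'   hydrolysis) or `"AMDP_PP"` (attached pre-power-stroke at the head's
#'   resting offset).
#' @param record_dt sampling interval for grid-recorded modes, s.
#' @param burn burn-in time excluded from time-averages (`velocity_clamp`,
#'   `isometric` summaries), s.
#' @param dx strain discretisation of the clamp rate tables, nm.
#' @param placement head placement mode for [place_heads()].
#' @param ... unused.
#' @return For `nsim = 1` a single result, else a list: an `xb_trace` for the
#'   trace modes, or a summary list (mean force, attached fraction) for
#'   `velocity_clamp`.
#' @export
#' @examples
#' m <- crossbridge_model()
#' tr <- simulate(m, mode = "zero_load", n_heads = 18, duration = 0.005, seed = 1)
#' tr
simulate.crossbridge_model <- function(object, nsim = 1, seed = NULL,
                                       mode = c("zero_load", "constant_load",
                                                "isometric", "velocity_clamp"),
                                       n_heads = 18, ensemble = NULL,
                                       duration = 0.1, load = 0, velocity = NULL,
                                       init = c("MDP", "AMDP_PP"),
                                       record_dt = 1e-3, burn = 0.2 * duration,
                                       dx = 0.1, placement = "random_binned", ...) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  stopifnot(duration >= 0)
  if (mode == "velocity_clamp" && (is.null(velocity) || velocity < 0))
    stop("velocity_clamp requires a non-negative velocity")
  pack <- xb_pack(object)
  d <- object$params$d
  one <- function(i) {
    if (!is.null(seed)) set.seed(seed + i - 1)
    offsets <- if (!is.null(ensemble)) ensemble$heads$offset
               else place_heads(n_heads, mode = placement, d = d)$offset
    s0 <- xb_init_states(object, offsets, init)
    if (mode %in% c("zero_load", "constant_load")) {
      ld <- if (mode == "zero_load") 0 else load
      maxexc <- if (!is.null(ensemble)) ensemble$lattice$length_nm else 2e4
      res <- cpp_sim_coupled(pack, offsets, s0, ld, duration, d, maxexc, 1e-9)
      tr <- xb_trace(res, object, length(offsets), mode,
                     if (is.null(seed)) NA else seed + i - 1, "event", load = ld)
      if (res$runaway)
        warning("filament displacement exceeded the lattice; simulation stopped early")
      tr
    } else if (mode == "isometric") {
      res <- cpp_sim_isometric(pack, offsets, s0, duration, burn, record_dt)
      res$position <- rep(0, length(res$time))
      tr <- xb_trace(res, object, length(offsets), mode,
                     if (is.null(seed)) NA else seed + i - 1, "grid")
      tr$mean_force <- res$mean_force
      tr$attached_fraction <- res$attached_fraction
      tr
    } else {
      g <- xb_grid(object, dx)
      tabs <- xb_clamp_tables(object, g)
      res <- cpp_sim_clamp(tabs$rate_tab, tabs$tfrom, tabs$tto, tabs$attached,
                           tabs$force_tab, g$x_top, g$dx, g$n_core, velocity,
                           offsets, s0, duration, burn)
      list(mean_force = res$mean_force,
           attached_fraction = res$attached_fraction,
           velocity = velocity, n_heads = length(offsets),
           n_events = res$n_events, ext_clamp = res$ext_clamp,
           seed = if (is.null(seed)) NA else seed + i - 1)
    }
  }
  out <- lapply(seq_len(nsim), one)
  if (nsim == 1) out[[1]] else out
}

# per-bin rate and force tables for the velocity clamp (bin-centre values,
# shared discretisation with the steady-state solver)
xb_clamp_tables <- function(model, g) {
  sc <- model$scheme
  nt <- nrow(sc$trans)
  rate_tab <- matrix(0, nt, g$N)
  for (k in seq_len(g$N)) rate_tab[, k] <- xb_rates_at(model, g$centers[k])
  force_tab <- matrix(0, sc$n_states, g$N)
  for (s in which(sc$states$attached))
    force_tab[s, ] <- elastic_force_num(g$centers - sc$states$xshift[s], model$params)
  list(rate_tab = rate_tab, tfrom = as.integer(sc$trans$from),
       tto = as.integer(sc$trans$to), attached = sc$states$attached,
       force_tab = force_tab)
}

#' Run a configured simulation
#'
#' Thin wrapper over [simulate.crossbridge_model()] taking a configuration
#' list, convenient for scripted experiments.
#'
#' @param config list with entries `mode`, `n_heads`, `duration`, `seed` and
#'   any other arguments of [simulate.crossbridge_model()].
#' @param model a [crossbridge_model()].
#' @return see [simulate.crossbridge_model()].
#' @export
run_simulation <- function(config, model = crossbridge_model()) {
  do.call(simulate, c(list(object = model), config))
}

#' @export
print.xb_trace <- function(x, ...) {
  cat(sprintf("Monte Carlo trace: mode %s, %d heads, %d %s records, %.4g s\n",
              x$mode, x$n_heads, length(x$time),
              x$record, if (length(x$time)) max(x$time) else 0))
  if (x$mode %in% c("zero_load", "constant_load") && length(x$position) > 1)
    cat(sprintf("  net displacement %.3g nm (load %g pN)\n",
                x$position[length(x$position)] - x$position[1], x$load))
  if (!is.null(x$mean_force))
    cat(sprintf("  mean force %.4g pN, attached fraction %.4f\n",
                x$mean_force, x$attached_fraction))
  invisible(x)
}

#' @export
as.data.frame.xb_trace <- function(x, ...) {
  data.frame(time = x$time, position = x$position, force = x$force,
             x$counts, check.names = FALSE)
}

#' @export
plot.xb_trace <- function(x, what = c("position", "force"), ...) {
  what <- match.arg(what)
  plot(x$time, x[[what]], type = if (x$record == "event") "s" else "l",
       xlab = "time (s)",
       ylab = if (what == "position") "displacement (nm)" else "force (pN)", ...)
  invisible(x)
}

#' Propensity table of an ensemble configuration
#'
#' Reference (R-level) computation of every head's transition propensities at
#' the current strains; the C++ engine consumes the identical rate law.
#'
#' @param model a [crossbridge_model()].
#' @param states integer vector of expanded state indices (one per head),
#'   see `model$scheme$states`.
#' @param x numeric vector of head strain coordinates (one per head), nm.
#' @return data frame with columns `head`, `from`, `to`, `rate`.
#' @export
gillespie_propensities <- function(model, states, x) {
  sc <- model$scheme
  out <- list()
  for (h in seq_along(states)) {
    r <- xb_rates_at(model, x[h])
    idx <- which(sc$trans$from == states[h] & r > 0)
    if (length(idx))
      out[[length(out) + 1L]] <- data.frame(
        head = h, from = states[h], to = sc$trans$to[idx], rate = r[idx])
  }
  if (!length(out)) return(data.frame(head = integer(), from = integer(),
                                      to = integer(), rate = numeric()))
  do.call(rbind, out)
}

#' Execute one Gillespie step (reference implementation)
#'
#' Draws an exponential waiting time from the total propensity and selects an
#' event proportionally to the per-transition propensities, then updates the
#' ensemble state. This R-level step is the oracle against which the C++
#' engine is validated; it is exact but slow.
#'
#' @param model a [crossbridge_model()].
#' @param state list with elements `states` (expanded state index per head),
#'   `x` (strain coordinate per head, nm), `t` (time, s).
#' @return updated `state` with elements `event` (head, from, to) and
#'   `waiting_time`; `NULL` event if all propensities vanish (absorbing).
#' @export
gillespie_step <- function(model, state) {
  pr <- gillespie_propensities(model, state$states, state$x)
  if (nrow(pr) == 0 || sum(pr$rate) <= 0) {
    state$event <- NULL
    return(state)
  }
  Rtot <- sum(pr$rate)
  wt <- stats::rexp(1, Rtot)
  k <- sample.int(nrow(pr), 1, prob = pr$rate)
  state$states[pr$head[k]] <- pr$to[k]
  state$t <- state$t + wt
  state$event <- list(head = pr$head[k], from = pr$from[k], to = pr$to[k])
  state$waiting_time <- wt
  state
}

#' Re-equilibrate the filament position (quasi-static force balance)
#'
#' Finds the filament displacement increment at which the summed
#' cross-bridge force of the attached heads equals the external load
#' (residual below `tol`). All attached heads share the common displacement.
#' Reference implementation using [stats::uniroot]; the C++ engine solves the
#' same monotone 1-D root problem by safeguarded Newton iteration.
#'
#' @param model a [crossbridge_model()].
#' @param x_attached strain coordinates of the attached heads, nm.
#' @param states expanded state indices of the attached heads.
#' @param load external load, pN.
#' @param tol force residual tolerance, pN.
#' @return displacement increment (nm, positive = shortening); with no
#'   attached heads returns 0 flagged with `attr(, "unsupported") = TRUE`
#'   when the load is nonzero.
#' @export
rebalance_filament <- function(model, x_attached, states, load = 0, tol = 1e-9) {
  sc <- model$scheme
  if (length(x_attached) == 0) {
    out <- 0
    if (load != 0) attr(out, "unsupported") <- TRUE
    return(out)
  }
  stopifnot(all(sc$states$attached[states]))
  fres <- function(delta)
    sum(elastic_force_num((x_attached - delta) - sc$states$xshift[states],
                          model$params)) - load
  lo <- -200; hi <- 200
  while (fres(lo) < 0) lo <- lo - 200
  while (fres(hi) > 0) hi <- hi + 200
  uniroot(fres, c(lo, hi), tol = 1e-12)$root
}
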