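# Free-energy diagrams, cross-bridge elasticity, and strain-dependent rates.

# elastic energy (pN nm) as a function of spring elongation s = x - x_i,
# given a params list. Linear mode: ks s^2 / 2. Nonlinear mode
# (Kaya-Higuchi-type): stiffness ks when stretched, exponentially softening
# under compression with bounded buckling force ks*w:
#   f(s) = ks s                 (s >= 0)
#   f(s) = ks w (exp(s/w) - 1)  (s <  0)
# The energy is the integral of f from 0; w = Inf reproduces the linear law
# bit-for-bit.
elastic_energy_num <- function(s, p) {
  w <- if (p$elasticity == "nonlinear") p$buckling_w else Inf
  if (!is.finite(w)) return(0.5 * p$ks * s^2)
  ifelse(s >= 0, 0.5 * p$ks * s^2,
         p$ks * w * (w * (exp(s / w) - 1) - s))
}

elastic_force_num <- function(s, p) {
  w <- if (p$elasticity == "nonlinear") p$buckling_w else Inf
  if (!is.finite(w)) return(p$ks * s)
  ifelse(s >= 0, p$ks * s, p$ks * w * (exp(s / w) - 1))
}

resolve_state <- function(model, state, site = 1L) {
  cs <- canonical_state(state)
  sc <- model$scheme
  i <- which(sc$states$canon == cs &
               (!sc$states$attached | sc$states$site == site))
  if (length(i) != 1) stop("unknown state: ", state)
  i
}

#' Elastic contribution to the free energy of an attached cross-bridge
#'
#' For an attached state with free-energy minimum at `x_i`, returns the
#' elastic energy stored at strain coordinate `x`: `ks (x - x_i)^2 / 2` with
#' linear elasticity, or the integral of the nonlinear force law in nonlinear
#' mode. Always non-negative and zero exactly at `x = x_i`.
#'
#' @param model a [crossbridge_model()].
#' @param state attached state identifier (e.g. `"AMDP_PP"`, `"AM"`).
#' @param x strain coordinate(s), nm.
#' @param site binding-site index within the target zone (1-based; only
#'   relevant for `sites_per_zone = 3`).
#' @return elastic energy in pN nm (vectorized over `x`).
#' @export
#' @examples
#' m <- crossbridge_model()
#' elastic_energy(m, "AMDP_PP", m$params$x1)        # 0 at the minimum
#' elastic_energy(m, "AMDP_PP", m$params$x1 + 1)    # ks/2 = 1.4 pN nm
elastic_energy <- function(model, state, x, site = 1L) {
  i <- resolve_state(model, state, site)
  if (!model$scheme$states$attached[i])
    stop("elastic energy is undefined for detached state ", state)
  stopifnot(all(is.finite(x)))
  elastic_energy_num(x - model$scheme$states$xshift[i], model$params)
}

#' Free energy of a cross-bridge state
#'
#' Basal (chemical) free-energy level of the state plus, for attached states,
#' the elastic energy at strain `x`. Detached states carry no x-dependence.
#'
#' @inheritParams elastic_energy
#' @return free energy in kBT units (vectorized over `x`).
#' @export
free_energy <- function(model, state, x, site = 1L) {
  i <- resolve_state(model, state, site)
  sc <- model$scheme
  if (!sc$states$attached[i]) return(rep(sc$states$g[i], length(x)))
  stopifnot(all(is.finite(x)))
  sc$states$g[i] +
    elastic_energy_num(x - sc$states$xshift[i], model$params) / model$params$kBT
}

#' Force exerted by an attached cross-bridge on the filament
#'
#' The x-derivative of the elastic energy: `ks (x - x_i)` in linear mode, the
#' nonlinear force law otherwise. Positive force drives filament shortening
#' (decreasing x).
#'
#' @inheritParams elastic_energy
#' @return force in pN (vectorized over `x`).
#' @export
cross_bridge_force <- function(model, state, x, site = 1L) {
  i <- resolve_state(model, state, site)
  if (!model$scheme$states$attached[i])
    stop("force is undefined for detached state ", state)
  elastic_force_num(x - model$scheme$states$xshift[i], model$params)
}

# Evaluate every directed transition rate of the expanded scheme at scalar x.
# Reference implementation (the C++ engine mirrors it); reversible pairs are
# capped multiplicatively so the forward/reverse ratio -- hence detailed
# balance -- is preserved exactly when the cap binds.
xb_rates_at <- function(model, x) {
  sc <- model$scheme
  p <- model$params
  G <- function(i) {
    if (!sc$states$attached[i]) return(sc$states$g[i])
    sc$states$g[i] + elastic_energy_num(x - sc$states$xshift[i], p) / p$kBT
  }
  tr <- sc$trans
  raw <- numeric(nrow(tr))
  for (t in seq_len(nrow(tr))) {
    if (x < tr$window_lo[t] || x > tr$window_hi[t]) { raw[t] <- 0; next }
    raw[t] <- if (tr$kind[t] == 0L) tr$c0[t]
              else tr$c0[t] * exp(tr$q[t] * (G(tr$gi[t]) - G(tr$gj[t])) -
                                    tr$rf_i2[t] * (x - tr$rf_c[t])^2)
  }
  out <- raw
  done <- logical(nrow(tr))
  for (t in seq_len(nrow(tr))) {
    if (done[t]) next
    pr <- tr$pair[t]
    if (is.na(pr)) {
      out[t] <- min(raw[t], p$rate_cap)
      done[t] <- TRUE
    } else {
      m2 <- max(raw[t], raw[pr])
      sc2 <- if (m2 > p$rate_cap) p$rate_cap / m2 else 1
      out[t] <- raw[t] * sc2
      out[pr] <- raw[pr] * sc2
      done[c(t, pr)] <- TRUE
    }
  }
  out
}

#' Strain-dependent transition rate
#'
#' Rate of the transition `from -> to` of the kinetic scheme, at strain
#' coordinate `x`. Rates are constructed from the free-energy diagrams: the
#' forward rate of a power-stroke transition carries the full strain
#' dependence, attachment is Boltzmann-weighted by the elastic energy of the
#' pre-power-stroke state, and every reversible pair satisfies
#' `forward(x)/reverse(x) = exp((G_from(x) - G_to(x))/kBT)` at all `x`
#' (detailed balance), including where the rate cap binds.
#'
#' @inheritParams elastic_energy
#' @param from,to state identifiers forming a transition of the scheme.
#' @return rate in 1/s (vectorized over `x`).
#' @export
#' @examples
#' m <- crossbridge_model()
#' transition_rate(m, "MDP", "AMDP_PP", m$params$x1)  # k0 of attachment
transition_rate <- function(model, from, to, x, site = 1L) {
  i <- resolve_state(model, from, site)
  j <- resolve_state(model, to, site)
  tr <- model$scheme$trans
  t_idx <- which(tr$from == i & tr$to == j)
  if (length(t_idx) != 1)
    stop("no transition ", from, " -> ", to, " in the scheme")
  vapply(x, function(xx) xb_rates_at(model, xx)[t_idx], numeric(1))
}

# n_states x n_states generator-style rate matrix at scalar x:
# Q[i, j] = rate i -> j (i != j); diagonal = -rowSums.
rate_matrix <- function(model, x) {
  sc <- model$scheme
  n <- sc$n_states
  r <- xb_rates_at(model, x)
  Q <- matrix(0, n, n)
  tr <- sc$trans
  for (t in seq_len(nrow(tr))) Q[tr$from[t], tr$to[t]] <- Q[tr$from[t], tr$to[t]] + r[t]
  diag(Q) <- -rowSums(Q)
  Q
}
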