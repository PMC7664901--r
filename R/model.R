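# Model object: parameters + kinetic scheme + expanded (per-site) state space.
#
# Canonical states of the cross-bridge cycle (detached first):
#   MT        myosin.ATP            (detached)
#   MDP       myosin.ADP.Pi         (detached)
#   AMDP_PP   pre-power-stroke      (attached, free-energy minimum at x1)
#   AMDP_PiR  Pi-release state      (attached, minimum at x11)
#   AMD_L     low-force bound state (attached, minimum at x11)
#   AMD_H     high-force bound state(attached, minimum at x2)
#   AM        rigor                 (attached, minimum at 0)
#
# Sign convention: x is the axial distance (nm) from a head's thick-filament
# anchor to the actin site; x = 0 where the AM free energy is minimal and
# filament shortening carries attached heads toward decreasing x, so
# 0 <= x2 < x11 < x1.

.xb_states <- c("MT", "MDP", "AMDP_PP", "AMDP_PiR", "AMD_L", "AMD_H", "AM")
.xb_aliases <- c(
  AMD_PP = "AMDP_PP", AMD_PiR = "AMDP_PiR",
  "M.T" = "MT", "M.D.P" = "MDP", "A.M" = "AM"
)

#' Canonicalize a cross-bridge state identifier
#'
#' Resolves the historical alias spellings of the pre-power-stroke and
#' Pi-release states (e.g. `"AMD_PP"`) to the canonical identifiers used
#' throughout the package.
#'
#' @param state character vector of state names.
#' @return character vector of canonical state names.
#' @export
#' @examples
#' canonical_state(c("AMD_PP", "AM"))
canonical_state <- function(state) {
  out <- ifelse(state %in% names(.xb_aliases), unname(.xb_aliases[state]), state)
  bad <- !(out %in% .xb_states)
  if (any(bad)) {
    # custom schemes may use their own names; only flag when a default-looking
    # name fails to resolve
    out[bad] <- state[bad]
  }
  out
}

xb_default_states <- function() {
  data.frame(
    state    = .xb_states,
    attached = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    xmin     = c(NA, NA, "x1", "x11", "x11", "x2", "zero"),
    # basal (chemical) free-energy levels in kBT; the full cycle drops by
    # exactly dG_ATP = 25 kBT (MT level minus AM level)
    g        = c(25, 23.5, 21.5, 19.5, 17, 4, 0),
    stringsAsFactors = FALSE
  )
}

xb_default_transitions <- function() {
  data.frame(
    from = c("MT", "MDP", "AMDP_PP", "AMDP_PiR", "AMD_L", "AMD_H", "AM"),
    to   = c("MDP", "AMDP_PP", "AMDP_PiR", "AMD_L", "AMD_H", "AM", "MT"),
    # type: "detached" (both states detached, x-independent), "attach"
    # (detached <-> attached), "stroke" (attached-attached), "irrev"
    # (one-way, constant). Reversible rates derive from the free-energy gap
    # dG(x) = G_from(x) - G_to(x) via detailed balance with a configurable
    # split: forward = c exp(split dG), reverse = c exp((split - 1) dG).
    type = c("detached", "attach", "stroke", "stroke", "stroke", "stroke", "irrev"),
    k0   = c(100, 200, 1000, 1000, 50, 1500, 3000),
    # strain at which k0 is realized (minimum of the from state for strokes,
    # of the target state for attachment); symbolic, resolved per model.
    xref = c(NA, "x1", "x1", "x11", "x11", "x2", NA),
    # fraction of the strain dependence carried by the forward rate: strokes
    # carry it fully; attachment splits it evenly, so detachment of a badly
    # strained weakly bound head accelerates (slip-bond behaviour) instead of
    # staying constant.
    split = c(1, 0.5, 1, 1, 1, 1, NA),
    reversible = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

xb_default_params <- function() {
  list(
    kBT = 4.0,            # thermal energy, pN nm
    ks = 2.8,             # cross-bridge stiffness, pN/nm
    dG_ATP = 25,          # free energy of MgATP turnover, kBT units
    d = 36,               # actin target-zone spacing, nm
    sites_per_zone = 1L,  # 1 or 3 myosin-binding sites per target zone
    site_sep = 5.5,       # intra-zone site separation, nm (actin monomer rise)
    x1 = 8.0,             # AMDP_PP free-energy minimum, nm
    x11 = 7.5,            # AMDP_PiR / AMD_L minimum, nm (x1 - 0.5)
    x2 = 1.0,             # AMD_H minimum, nm
    elasticity = "linear",# "linear" or "nonlinear"
    buckling_w = 2.0,     # nonlinear mode: compressive buckling length, nm
    attach_reach = 2.0,   # axial reach of the head around the attachment
                          # optimum (Gaussian s.d., nm; Inf = unlimited).
                          # Multiplies BOTH directions of the attachment
                          # step, so detailed balance is untouched.
    rate_cap = 1e6        # maximum allowed transition rate, 1/s
  )
}

resolve_x <- function(sym, p) {
  if (is.na(sym)) return(NA_real_)
  if (is.numeric(sym)) return(sym)
  num <- suppressWarnings(as.numeric(sym))
  if (!is.na(num)) return(num)
  switch(as.character(sym),
    x1 = p$x1, x11 = p$x11, x2 = p$x2, zero = 0,
    stop("unknown symbolic strain reference: ", sym)
  )
}

#' Construct an actomyosin cross-bridge model
#'
#' Builds the full parameterization of the cross-bridge cycle: kinetic scheme,
#' basal free-energy levels, free-energy minima positions `x1 > x11 > x2 >= 0`
#' (nm), cross-bridge elasticity, geometry and rate caps. Strain-dependent
#' transition rates are derived from the free-energy diagrams so that detailed
#' balance holds exactly at every strain for every reversible transition; rate
#' caps are applied to reversible pairs multiplicatively so capping never
#' violates detailed balance.
#'
#' @param ... named parameter overrides: `kBT`, `ks`, `dG_ATP`, `d`,
#'   `sites_per_zone`, `site_sep`, `x1`, `x11`, `x2`, `elasticity`
#'   (`"linear"` or `"nonlinear"`), `buckling_w`, `attach_reach`, `rate_cap`.
#' @param file optional path to a YAML parameter file (as written by
#'   [write_params()]); entries in `...` override the file.
#' @param states,transitions optional data frames replacing the default
#'   kinetic scheme (advanced use; the scheme is data-driven so branches or
#'   reduced schemes can be supplied without code change). See
#'   `xbridge:::xb_default_states()` for the expected columns.
#' @param check_cycle logical; verify that the basal free-energy levels drop
#'   by exactly `dG_ATP` over one cycle (disable for reduced custom schemes).
#' @return An object of class `crossbridge_model`.
#' @export
#' @examples
#' m <- crossbridge_model()
#' m
#' coef(m)[c("ks", "x1", "x11", "x2")]
crossbridge_model <- function(..., file = NULL, states = NULL,
                              transitions = NULL, check_cycle = is.null(states)) {
  p <- xb_default_params()
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    if (!is.null(y$params)) p <- utils::modifyList(p, y$params)
    if (is.null(states) && !is.null(y$states)) {
      states <- do.call(rbind.data.frame, lapply(y$states, as.data.frame))
    }
    if (is.null(transitions) && !is.null(y$transitions)) {
      transitions <- do.call(rbind.data.frame, lapply(y$transitions, as.data.frame))
    }
  }
  force(check_cycle)  # resolve against the caller's `states`, not the default
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p <- utils::modifyList(p, dots)
  }
  p$sites_per_zone <- as.integer(p$sites_per_zone)
  if (is.null(states)) states <- xb_default_states()
  if (is.null(transitions)) transitions <- xb_default_transitions()
  states$state <- canonical_state(states$state)
  transitions$from <- canonical_state(transitions$from)
  transitions$to <- canonical_state(transitions$to)
  if (is.null(transitions$window_lo)) transitions$window_lo <- -Inf
  if (is.null(transitions$window_hi)) transitions$window_hi <- Inf

  # --- validation -----------------------------------------------------------
  stopifnot(p$ks > 0, p$kBT > 0, p$d > 0, p$rate_cap > 0,
            p$buckling_w > 0, all(transitions$k0 >= 0))
  if (!p$elasticity %in% c("linear", "nonlinear"))
    stop("elasticity must be 'linear' or 'nonlinear'")
  if (!p$sites_per_zone %in% c(1L, 3L))
    stop("sites_per_zone must be 1 or 3")
  if (check_cycle) {
    if (!(p$x2 < p$x11 && p$x11 < p$x1))
      stop("free-energy minima must satisfy x2 < x11 < x1")
    g <- states$g[match(c("MT", "AM"), states$state)]
    if (!anyNA(g) && abs((g[1] - g[2]) - p$dG_ATP) > 1e-9)
      stop("basal free-energy levels must drop by exactly dG_ATP over one cycle")
  }
  if (anyDuplicated(states$state)) stop("duplicated state names")
  miss <- setdiff(c(transitions$from, transitions$to), states$state)
  if (length(miss)) stop("transition references unknown state(s): ",
                         paste(miss, collapse = ", "))

  m <- structure(list(params = p, states = states, transitions = transitions),
                 class = "crossbridge_model")
  m$scheme <- expand_scheme(m)
  m
}

# Expand the canonical scheme over binding sites within a target zone.
# For sites_per_zone = 3 every attached state is triplicated (one copy per
# site, offsets -site_sep, 0, +site_sep from the zone centre); a head can
# occupy at most one site, which resolves intra-zone competition by mutual
# exclusion. Each directed transition carries a precomputed scale constant c0
# and a kind:
#   kind 0 "const": rate(x) = c0 (within window)
#   kind 2 "db":    rate(x) = c0 * exp(q * dG(x)), dG = G_gi(x) - G_gj(x)
# where (gi, gj) is the forward orientation of the reversible pair and
# q = split for the forward row, split - 1 for the reverse row, so the ratio
# is exp(dG(x)) at every x (detailed balance) for any split.
expand_scheme <- function(m) {
  p <- m$params
  st <- m$states
  tr <- m$transitions
  offs <- if (p$sites_per_zone == 3L) c(-p$site_sep, 0, p$site_sep) else 0
  n_sites <- length(offs)

  det <- st[!st$attached, , drop = FALSE]
  att <- st[st$attached, , drop = FALSE]
  exp_states <- data.frame(
    name = det$state, canon = det$state, site = NA_integer_,
    attached = FALSE, xshift = NA_real_, g = det$g,
    stringsAsFactors = FALSE
  )
  for (j in if (nrow(att)) seq_len(n_sites) else integer()) {
    nm <- if (n_sites == 1) att$state else paste0(att$state, "@", j)
    exp_states <- rbind(exp_states, data.frame(
      name = nm, canon = att$state, site = j, attached = TRUE,
      xshift = offs[j] + vapply(att$xmin, resolve_x, numeric(1), p = p),
      g = att$g, stringsAsFactors = FALSE
    ))
  }
  idx_of <- function(canon, site) {
    if (is.na(site)) which(exp_states$canon == canon & !exp_states$attached)
    else which(exp_states$canon == canon & exp_states$site == site)
  }

  if (is.null(tr$split)) tr$split <- 1
  G_at <- function(idx, x) {
    if (!exp_states$attached[idx]) return(exp_states$g[idx])
    exp_states$g[idx] + elastic_energy_num(x - exp_states$xshift[idx], p) / p$kBT
  }
  rows <- list()
  add_row <- function(from, to, kind, c0, q, gi, gj, pair, wlo, whi, label,
                      rf_c = 0, rf_i2 = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      from = from, to = to, kind = kind, c0 = c0, q = q, gi = gi, gj = gj,
      pair = pair, window_lo = wlo, window_hi = whi, label = label,
      rf_c = rf_c, rf_i2 = rf_i2,
      stringsAsFactors = FALSE
    )
  }
  for (i in seq_len(nrow(tr))) {
    ti <- tr[i, ]
    a_att <- st$attached[st$state == ti$from]
    b_att <- st$attached[st$state == ti$to]
    sites_i <- if (a_att || b_att) seq_len(n_sites) else NA_integer_
    for (j in sites_i) {
      from_idx <- idx_of(ti$from, if (a_att) j else NA_integer_)
      to_idx <- idx_of(ti$to, if (b_att) j else NA_integer_)
      shift <- if (is.na(j)) 0 else offs[j]
      wlo <- ti$window_lo + if (is.finite(ti$window_lo)) shift else 0
      whi <- ti$window_hi + if (is.finite(ti$window_hi)) shift else 0
      lab <- paste0(ti$from, "->", ti$to, if (!is.na(j) && n_sites > 1) paste0("@", j) else "")
      if (ti$type == "irrev") {
        add_row(from_idx, to_idx, 0L, ti$k0, 0, from_idx, to_idx,
                NA_integer_, wlo, whi, lab)
      } else {
        spl <- if (is.na(ti$split)) 1 else ti$split
        if (ti$type == "detached") {
          dG_ref <- G_at(from_idx, 0) - G_at(to_idx, 0) # x-independent
          cf <- ti$k0 * exp(-spl * dG_ref)
        } else {
          xr <- resolve_x(ti$xref, p) + shift
          dG_ref <- G_at(from_idx, xr) - G_at(to_idx, xr)
          cf <- ti$k0 * exp(-spl * dG_ref)
        }
        # finite head reach: symmetric factor on both directions of the
        # attachment step (ratio, hence detailed balance, preserved)
        rf_c <- 0; rf_i2 <- 0
        if (ti$type == "attach" && is.finite(p$attach_reach)) {
          rf_c <- exp_states$xshift[to_idx]
          rf_i2 <- 1 / (2 * p$attach_reach^2)
        }
        k <- length(rows)
        add_row(from_idx, to_idx, 2L, cf, spl, from_idx, to_idx,
                k + 2L, wlo, whi, lab, rf_c, rf_i2)
        add_row(to_idx, from_idx, 2L, cf, spl - 1, from_idx, to_idx,
                k + 1L, wlo, whi, paste0(lab, ".rev"), rf_c, rf_i2)
      }
    }
  }
  trans <- do.call(rbind, rows)
  canon_idx <- match(exp_states$canon, m$states$state)
  list(states = exp_states, trans = trans, canon_idx = canon_idx,
       n_states = nrow(exp_states), n_det = sum(!exp_states$attached),
       site_offsets = offs)
}

# parameter pack handed to the C++ engine
xb_pack <- function(m) {
  sc <- m$scheme
  p <- m$params
  list(
    n = sc$n_states,
    attached = as.integer(sc$states$attached),
    xshift = ifelse(is.na(sc$states$xshift), 0, sc$states$xshift),
    g = sc$states$g,
    canon = as.integer(sc$canon_idx),
    n_canon = nrow(m$states),
    ks = p$ks, kBT = p$kBT,
    w = if (p$elasticity == "nonlinear") p$buckling_w else Inf,
    cap = p$rate_cap,
    from = as.integer(sc$trans$from), to = as.integer(sc$trans$to),
    kind = as.integer(sc$trans$kind),
    c0 = sc$trans$c0, q = sc$trans$q,
    gi = as.integer(sc$trans$gi), gj = as.integer(sc$trans$gj),
    pair = as.integer(ifelse(is.na(sc$trans$pair), 0L, sc$trans$pair)),
    wlo = sc$trans$window_lo, whi = sc$trans$window_hi,
    rf_c = sc$trans$rf_c, rf_i2 = sc$trans$rf_i2
  )
}

#' @export
print.crossbridge_model <- function(x, ...) {
  p <- x$params
  cat("Actomyosin cross-bridge model\n")
  cat(sprintf("  states: %d (%s)\n", nrow(x$states),
              paste(x$states$state, collapse = ", ")))
  cat(sprintf("  elasticity: %s (ks = %.2f pN/nm%s)\n", p$elasticity, p$ks,
              if (p$elasticity == "nonlinear")
                sprintf(", buckling length %.1f nm", p$buckling_w) else ""))
  cat(sprintf("  free-energy minima: x1 = %.2f, x11 = %.2f, x2 = %.2f nm\n",
              p$x1, p$x11, p$x2))
  cat(sprintf("  kBT = %.2f pN nm, dG_ATP = %g kBT, target-zone spacing d = %g nm\n",
              p$kBT, p$dG_ATP, p$d))
  cat(sprintf("  sites per target zone: %d, rate cap %g /s\n",
              p$sites_per_zone, p$rate_cap))
  invisible(x)
}

#' @export
coef.crossbridge_model <- function(object, ...) {
  p <- object$params
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1, logical(1))
  k0 <- setNames(object$transitions$k0,
                 paste0("k0.", object$transitions$from, ".", object$transitions$to))
  c(unlist(p[num]), k0)
}

#' @export
summary.crossbridge_model <- function(object, ...) {
  print(object)
  cat("\nZero-strain transition rates (at each transition's reference strain):\n")
  tr <- object$transitions
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("  %-9s -> %-9s %-9s k0 = %g /s%s\n", tr$from[i], tr$to[i],
                paste0("(", tr$type[i], ")"), tr$k0[i],
                if (tr$reversible[i]) "" else "  [one-way]"))
  }
  cat(sprintf("\nCycle free-energy drop: %g kBT\n", cycle_free_energy_drop(object)))
  invisible(object)
}

#' Free-energy drop over one complete cross-bridge cycle
#'
#' The basal (chemical) free-energy levels around one full cycle drop by the
#' free energy of MgATP turnover; with the default parameterization this is
#' exactly 25 kBT.
#'
#' @param model a [crossbridge_model()].
#' @return numeric, drop in kBT.
#' @export
cycle_free_energy_drop <- function(model) {
  g <- model$states$g
  g[match("MT", model$states$state)] - g[match("AM", model$states$state)]
}

#' Write / read model parameters to a declarative YAML file
#'
#' @param model a [crossbridge_model()].
#' @param file path to write to.
#' @return `file`, invisibly.
#' @export
write_params <- function(model, file) {
  y <- list(
    params = model$params,
    states = lapply(seq_len(nrow(model$states)), function(i) as.list(model$states[i, ])),
    transitions = lapply(seq_len(nrow(model$transitions)), function(i)
      as.list(model$transitions[i, intersect(
        c("from", "to", "type", "k0", "xref", "split", "reversible",
          "window_lo", "window_hi"),
        names(model$transitions))]))
  )
  yaml::write_yaml(y, file)
  invisible(file)
}
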