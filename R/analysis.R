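# Post-processing: step detection and clustering in displacement records,
# mechanical work per step, isometric force-rise fitting, exact small-sample
# Spearman correlation.

#' Detect displacement steps in a Monte Carlo trace
#'
#' Every event-to-event change in filament displacement with magnitude at or
#' above the threshold is emitted as a signed step. The default threshold
#' (0.5 nm) sits below the smallest step amplitudes the model produces
#' (~1 nm) so genuine sub-steps are retained while numerically null
#' rebalancing moves are discarded.
#'
#' @param trace an event-recorded `xb_trace` (zero-load or constant-load
#'   simulation), or a list with elements `time` and `position`.
#' @param min_amplitude_nm detection threshold, nm.
#' @return data frame of class `xb_steps` with columns `time` (s),
#'   `amplitude` (nm, signed) and `cluster` (NA until [cluster_steps()]).
#' @export
detect_steps <- function(trace, min_amplitude_nm = 0.5) {
  if (length(trace$time) == 0) stop("empty trace")
  dp <- diff(trace$position)
  tt <- trace$time[-1]
  keep <- abs(dp) >= min_amplitude_nm
  out <- data.frame(time = tt[keep], amplitude = dp[keep],
                    cluster = rep(NA_integer_, sum(keep)))
  class(out) <- c("xb_steps", "data.frame")
  out
}

#' Cluster steps into short time windows
#'
#' Greedy windowing of time-sorted steps: a cluster is a maximal run of
#' consecutive steps all falling within one window of the stated width from
#' the first step of the run.
#'
#' @param steps a data frame from [detect_steps()] (time-sorted).
#' @param window_ms window width, ms (default 0.4).
#' @return `steps` with the `cluster` column filled; the per-cluster summary
#'   (size, span, summed amplitude) is attached as `attr(, "clusters")`.
#' @export
cluster_steps <- function(steps, window_ms = 0.4) {
  w <- window_ms / 1000
  n <- nrow(steps)
  cl <- integer(n)
  cur <- 0L
  start <- -Inf
  for (i in seq_len(n)) {
    if (steps$time[i] - start > w) {
      cur <- cur + 1L
      start <- steps$time[i]
    }
    cl[i] <- cur
  }
  steps$cluster <- cl
  if (n) {
    summ <- do.call(rbind, lapply(split(seq_len(n), cl), function(ii)
      data.frame(cluster = cl[ii[1]], n_steps = length(ii),
                 t_start = steps$time[ii[1]],
                 span_ms = 1000 * (steps$time[ii[length(ii)]] - steps$time[ii[1]]),
                 total_amplitude = sum(steps$amplitude[ii]))))
    rownames(summ) <- NULL
  } else summ <- data.frame(cluster = integer(), n_steps = integer(),
                            t_start = numeric(), span_ms = numeric(),
                            total_amplitude = numeric())
  attr(steps, "clusters") <- summ
  steps
}

#' Mechanical work of a displacement step against a load
#'
#' `work = step x load`, reported both in pN nm and in thermal units; flags
#' work exceeding the free energy of MgATP turnover (25 kBT), the signature
#' used to argue that large steps under high load cannot be powered by a
#' single ATP.
#'
#' @param step_nm step amplitude, nm.
#' @param load_pN load, pN.
#' @param kBT thermal energy, pN nm (default 4).
#' @param dG_ATP free energy of MgATP turnover in kBT (default 25).
#' @return list with `work_pNnm`, `work_kBT`, `exceeds_ATP`.
#' @export
#' @examples
#' mechanical_work(4, 30)  # 120 pN nm = 30 kBT, more than one ATP provides
mechanical_work <- function(step_nm, load_pN, kBT = 4, dG_ATP = 25) {
  stopifnot(is.finite(step_nm), is.finite(load_pN))
  w <- step_nm * load_pN
  list(work_pNnm = w, work_kBT = w / kBT, exceeds_ATP = (w / kBT) > dG_ATP)
}

#' Fit the rate of isometric force development
#'
#' Least-squares fit of a single-exponential rise
#' `F(t) = F_inf - A exp(-k t)` to an isometric force transient. With
#' `window = "upper_half"` the fit is restricted to times after the force
#' first crosses half its plateau value, the range over which a
#' single-exponential description of force development is most defensible.
#'
#' @param trace an isometric `xb_trace`, or a list with `time` and `force`.
#' @param window `"full"` or `"upper_half"`.
#' @param plateau_frac trailing fraction of the trace used to estimate the
#'   plateau for the `"upper_half"` window.
#' @return list with `k` (1/s), `se` (standard error of `k`), `F_inf`, `A`,
#'   the window used, and the [stats::nls] fit object.
#' @export
fit_force_rise <- function(trace, window = c("full", "upper_half"),
                           plateau_frac = 0.2) {
  window <- match.arg(window)
  df <- data.frame(t = trace$time, f = trace$force)
  if (nrow(df) < 4) stop("too few points for an exponential fit")
  plateau <- mean(df$f[df$t >= (1 - plateau_frac) * max(df$t)])
  if (window == "upper_half") {
    i0 <- which(df$f >= 0.5 * plateau)[1]
    if (is.na(i0)) stop("force never reaches half its plateau; cannot fit upper_half")
    df <- df[seq(i0, nrow(df)), ]
    df$t <- df$t - df$t[1]
  }
  k0 <- {
    i63 <- which(df$f >= df$f[1] + 0.63 * (plateau - df$f[1]))[1]
    if (is.na(i63) || df$t[i63] <= 0) 10 else 1 / df$t[i63]
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ Finf - A * exp(-k * t), data = df,
                      start = list(Finf = plateau, A = plateau - df$f[1], k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("force-rise fit did not converge: ",
                             conditionMessage(e)))
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  list(k = unname(cf["k"]), se = se, F_inf = unname(cf["Finf"]),
       A = unname(cf["A"]), window = window, fit = fit)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rank correlation (mid-ranks for ties) and its
#' two-sided p-value: for `n <= exact_n_max` the p-value is obtained by full
#' enumeration of all permutations of one margin, otherwise by the
#' large-sample approximation of [stats::cor.test].
#'
#' @param xs,ys numeric vectors of equal length (>= 3).
#' @param exact_n_max largest n for exact permutation enumeration
#'   (default 10).
#' @return list with `r`, `p`, and `method` (`"exact"` or `"approximate"`).
#' @export
#' @examples
#' spearman(1:5, 1:5)  # r = 1, exact two-sided p = 2/120
spearman <- function(xs, ys, exact_n_max = 10) {
  n <- length(xs)
  stopifnot(n == length(ys), n >= 3, all(is.finite(xs)), all(is.finite(ys)))
  if (length(unique(xs)) < 2 || length(unique(ys)) < 2)
    stop("constant input: correlation undefined")
  rx <- rank(xs)
  ry <- rank(ys)
  if (n <= exact_n_max) {
    res <- cpp_spearman_perm(rx, ry)
    list(r = res$r, p = res$p, method = "exact")
  } else {
    ct <- suppressWarnings(cor.test(xs, ys, method = "spearman", exact = FALSE))
    list(r = unname(ct$estimate), p = ct$p.value, method = "approximate")
  }
}
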