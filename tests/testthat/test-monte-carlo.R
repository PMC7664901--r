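# Event-driven (Gillespie) Monte Carlo engine and quasi-static mechanics

test_that("waiting times between events are exponential with the total propensity", {
  # two-state flip-flop at equal constant rates: every waiting time is
  # Exp(k) distributed regardless of the state occupied
  k <- 1000
  states <- data.frame(state = c("S0", "S1"), attached = c(FALSE, FALSE),
                       xmin = c(NA, NA), g = c(0, 0))
  transitions <- data.frame(from = c("S0", "S1"), to = c("S1", "S0"),
                            type = "irrev", k0 = k, xref = NA, split = NA,
                            reversible = FALSE)
  m <- crossbridge_model(states = states, transitions = transitions,
                         check_cycle = FALSE)
  tr <- simulate(m, mode = "zero_load", n_heads = 1, duration = 100, seed = 21)
  waits <- diff(tr$time)
  waits <- waits[seq_len(min(1e5, length(waits)))]
  expect_gt(length(waits), 5e4)
  expect_lt(abs(mean(waits) - 1 / k) / (1 / k), 0.01)
  ks <- stats::ks.test(waits[seq_len(1e4)], "pexp", rate = k)
  expect_gt(ks$p.value, 0.01)
})

test_that("competing transitions with equal rates are selected equally often", {
  # S0 branches to S1 or S2 at equal rates; fast return to S0
  states <- data.frame(state = c("S0", "S1", "S2"), attached = FALSE,
                       xmin = NA, g = 0)
  transitions <- data.frame(from = c("S0", "S0", "S1", "S2"),
                            to = c("S1", "S2", "S0", "S0"),
                            type = "irrev", k0 = c(500, 500, 5000, 5000),
                            xref = NA, split = NA, reversible = FALSE)
  m <- crossbridge_model(states = states, transitions = transitions,
                         check_cycle = FALSE)
  tr <- simulate(m, mode = "zero_load", n_heads = 2, duration = 60, seed = 8)
  d1 <- diff(tr$counts[, "S1"])
  n1 <- sum(d1 == 1)
  n <- n1 + sum(diff(tr$counts[, "S2"]) == 1)
  expect_gt(n, 5e4)
  expect_lt(abs(n1 / n - 0.5), 3 * 0.5 / sqrt(n))  # binomial 3 sigma
})

test_that("ensemble propensities match per-head per-transition enumeration", {
  m <- default_model()
  sc <- m$scheme
  set.seed(4)
  states <- c(2L, 3L, 5L, 6L, 7L)          # mixed 5-head fixture
  xs <- runif(5, -10, 12)
  pr <- gillespie_propensities(m, states, xs)
  # brute force: every transition of every head, from the rate law directly
  manual <- list()
  for (h in 1:5) {
    r <- xbridge:::xb_rates_at(m, xs[h])
    for (t in seq_len(nrow(sc$trans))) {
      if (sc$trans$from[t] == states[h] && r[t] > 0)
        manual[[length(manual) + 1L]] <- c(h, states[h], sc$trans$to[t], r[t])
    }
  }
  manual <- do.call(rbind, manual)
  expect_equal(nrow(pr), nrow(manual))
  expect_equal(pr$rate, manual[, 4])
  expect_equal(pr$to, as.integer(manual[, 3]))
  # and the C++ engine evaluates the identical propensities
  pk <- xbridge:::xb_pack(m)
  for (h in 1:5) {
    rc <- xbridge:::cpp_rates_all(pk, xs[h])
    idx <- which(sc$trans$from == states[h] & rc > 0)
    expect_equal(pr$rate[pr$head == h], rc[idx])
  }
})

test_that("a single Gillespie step draws a valid event and updates one head", {
  m <- default_model()
  set.seed(2)
  st <- list(states = c(2L, 2L, 7L), x = c(7.9, 8.3, 2.0), t = 0)
  out <- gillespie_step(m, st)
  expect_gt(out$waiting_time, 0)
  expect_equal(sum(out$states != st$states), 1)
  expect_equal(out$states[out$event$head], out$event$to)
  # absorbing configuration signals cleanly
  states <- data.frame(state = c("A", "B"), attached = FALSE, xmin = NA, g = 0)
  transitions <- data.frame(from = "A", to = "B", type = "irrev", k0 = 10,
                            xref = NA, split = NA, reversible = FALSE)
  ma <- crossbridge_model(states = states, transitions = transitions,
                          check_cycle = FALSE)
  out2 <- gillespie_step(ma, list(states = 2L, x = 0, t = 0))
  expect_null(out2$event)
})

test_that("filament rebalancing solves the quasi-static force balance", {
  m <- default_model()
  iAM <- which(m$scheme$states$canon == "AM")
  # one attached head with strain s, zero load: filament moves by s
  expect_equal(rebalance_filament(m, x_attached = 3.2, states = iAM), 3.2,
               tolerance = 1e-9)
  # two equal linear springs, zero load: displacement (s1 + s2)/2
  expect_equal(rebalance_filament(m, c(4, 1), rep(iAM, 2)), 2.5,
               tolerance = 1e-9)
  # no attached heads under load: unchanged, flagged
  r <- rebalance_filament(m, numeric(0), integer(0), load = 5)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "unsupported"))
  # nonlinear elasticity, 10 heads: C++ Newton vs R root-finding oracle
  mn <- nonlinear_model()
  set.seed(31)
  xs <- runif(10, -6, 12)
  sts <- sample(which(mn$scheme$states$attached), 10, replace = TRUE)
  for (load in c(0, 8)) {
    dR <- rebalance_filament(mn, xs, sts, load = load)
    dC <- xbridge:::cpp_rebalance(xbridge:::xb_pack(mn), xs, sts, load, 1e-9)
    expect_lt(abs(dR - dC), 1e-6)
    f <- sum(xbridge:::elastic_force_num((xs - dR) - mn$scheme$states$xshift[sts],
                                         mn$params))
    expect_lt(abs(f - load), 1e-6)
  }
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  m <- default_model()
  t1 <- simulate(m, mode = "zero_load", n_heads = 18, duration = 0.02, seed = 5)
  t2 <- simulate(m, mode = "zero_load", n_heads = 18, duration = 0.02, seed = 5)
  expect_identical(t1$time, t2$time)
  expect_identical(t1$position, t2$position)
  expect_identical(t1$counts, t2$counts)
  t3 <- simulate(m, mode = "zero_load", n_heads = 18, duration = 0.02, seed = 6)
  expect_false(identical(t1$position, t3$position))
})

test_that("occupancy counts are conserved at every event", {
  m <- default_model()
  tr <- simulate(m, mode = "zero_load", n_heads = 18, duration = 0.03, seed = 9)
  expect_true(all(rowSums(tr$counts) == 18))
  expect_true(all(diff(tr$time) >= 0))
  tri <- simulate(m, mode = "isometric", n_heads = 40, duration = 0.05, seed = 9)
  expect_true(all(rowSums(tri$counts) == 40))
})

test_that("zero-duration simulation returns only the initial record", {
  m <- default_model()
  tr <- simulate(m, mode = "zero_load", n_heads = 5, duration = 0, seed = 1)
  expect_equal(length(tr$time), 1)
  expect_equal(tr$position, 0)
})

test_that("occupancy decays exponentially for a single irreversible transition", {
  # uniform initial population, one decay channel at rate k: the set of
  # per-head transition times is an iid Exp(k) sample
  k <- 80
  states <- data.frame(state = c("U", "V"), attached = FALSE, xmin = NA, g = 0)
  transitions <- data.frame(from = "U", to = "V", type = "irrev", k0 = k,
                            xref = NA, split = NA, reversible = FALSE)
  m <- crossbridge_model(states = states, transitions = transitions,
                         check_cycle = FALSE)
  tr <- simulate(m, mode = "zero_load", n_heads = 1e4, duration = 1, seed = 13)
  times <- tr$time[-1]
  expect_gt(length(times), 9900)
  ks <- stats::ks.test(times, "pexp", rate = k)
  expect_gt(ks$p.value, 0.01)
})

test_that("small-ensemble zero-load sliding moves in the shortening direction", {
  exps <- step_experiments()
  vels <- vapply(exps, function(e) e$mean_velocity, numeric(1))
  vmax <- model_vmax()
  # a rare seed places no head within attachment reach of a binding site and
  # the record stalls; the rest shorten at a substantial fraction of the
  # large-ensemble unloaded velocity
  expect_gte(sum(vels > 0), 17)
  expect_lt(mean(vels), vmax)
  expect_gt(mean(vels), 0.05 * vmax)
})
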