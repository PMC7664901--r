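# Kinetic scheme, free-energy diagrams, elasticity and strain-dependent rates

test_that("elastic energy is the parabola (or its nonlinear analogue) about each minimum", {
  m <- default_model()
  x1 <- m$params$x1
  expect_equal(elastic_energy(m, "AMDP_PP", x1), 0)
  expect_equal(elastic_energy(m, "AMDP_PP", x1 + 1), 2.8 / 2)      # ks/2
  expect_equal(elastic_energy(m, "AM", -2), 2.8 * 4 / 2)           # x_i = 0
  expect_true(all(elastic_energy(m, "AMD_H", seq(-15, 15, 0.5)) >= 0))
  # nonlinear mode: still zero exactly at the minimum, non-negative elsewhere
  mn <- nonlinear_model()
  expect_equal(elastic_energy(mn, "AMDP_PP", x1), 0)
  expect_true(all(elastic_energy(mn, "AM", seq(-20, 15, 0.25)) >= 0))
})

test_that("cross-bridge force is the exact x-derivative of the elastic energy", {
  set.seed(11)
  xs <- runif(100, -15, 15)
  h <- 1e-5
  for (m in list(default_model(), nonlinear_model())) {
    for (s in c("AMDP_PP", "AMD_L", "AMD_H", "AM")) {
      f <- cross_bridge_force(m, s, xs)
      fd <- (elastic_energy(m, s, xs + h) - elastic_energy(m, s, xs - h)) / (2 * h)
      expect_lt(max(abs(f - fd) / pmax(1, abs(f))), 1e-6)
    }
  }
  expect_equal(cross_bridge_force(default_model(), "AMD_H",
                                  default_model()$params$x2), 0)
  expect_equal(cross_bridge_force(default_model(), "AM", 1), 2.8)
})

test_that("free energy equals the basal level at each state's minimum and is stationary there", {
  m <- default_model()
  sc <- m$scheme
  for (i in which(sc$states$attached)) {
    st <- sc$states$canon[i]
    xi <- sc$states$xshift[i]
    expect_equal(free_energy(m, st, xi), sc$states$g[i])
    h <- 1e-6
    dG <- (free_energy(m, st, xi + h) - free_energy(m, st, xi - h)) / (2 * h)
    expect_lt(abs(dG), 1e-6)
  }
  # detached states carry no x dependence
  expect_equal(free_energy(m, "MDP", c(-5, 0, 5)), rep(23.5, 3))
})

test_that("detailed balance holds for every reversible pair at random strains to 1e-9", {
  set.seed(42)
  xs <- runif(50, -17.9, 17.9)
  for (m in list(default_model(), nonlinear_model(),
                 cached("model_3site", crossbridge_model(sites_per_zone = 3)))) {
    tr <- m$scheme$trans
    st <- m$scheme$states
    for (x in xs) {
      r <- xbridge:::xb_rates_at(m, x)
      for (t in seq_len(nrow(tr))) {
        pr <- tr$pair[t]
        if (is.na(pr) || pr < t || r[pr] == 0) next
        Gf <- st$g[tr$from[t]] +
          if (st$attached[tr$from[t]])
            xbridge:::elastic_energy_num(x - st$xshift[tr$from[t]], m$params) / m$params$kBT else 0
        Gt <- st$g[tr$to[t]] +
          if (st$attached[tr$to[t]])
            xbridge:::elastic_energy_num(x - st$xshift[tr$to[t]], m$params) / m$params$kBT else 0
        expect_lt(abs(r[t] / r[pr] - exp(Gf - Gt)) / exp(Gf - Gt), 1e-9)
      }
    }
  }
})

test_that("equilibrium constants around the cycle multiply to exp(dG_ATP)", {
  m <- default_model()
  # at x = 0 the rigor elastic energy vanishes, so the product of the six
  # reversible forward/reverse ratios telescopes to exp(G_MT - G_AM(0))
  r <- xbridge:::xb_rates_at(m, 0)
  tr <- m$scheme$trans
  fwd <- which(!grepl(".rev", tr$label, fixed = TRUE) & !is.na(tr$pair))
  K <- prod(r[fwd] / r[tr$pair[fwd]])
  expect_equal(log(K), 25, tolerance = 1e-12)
  expect_equal(cycle_free_energy_drop(m), 25)
})

test_that("nonlinear elasticity in the linear limit reproduces linear mode bit-for-bit", {
  m_lin <- default_model()
  m_inf <- crossbridge_model(elasticity = "nonlinear", buckling_w = Inf)
  xs <- seq(-17.9, 17.9, by = 0.37)
  for (s in c("AMDP_PP", "AM")) {
    expect_identical(elastic_energy(m_lin, s, xs), elastic_energy(m_inf, s, xs))
    expect_identical(cross_bridge_force(m_lin, s, xs), cross_bridge_force(m_inf, s, xs))
  }
  for (x in c(-9.1, 0, 6.3)) {
    expect_identical(xbridge:::xb_rates_at(m_lin, x),
                     xbridge:::xb_rates_at(m_inf, x))
  }
})

test_that("C++ engine rates agree with the R reference at random strains", {
  set.seed(7)
  for (m in list(default_model(), nonlinear_model(),
                 cached("model_3site", crossbridge_model(sites_per_zone = 3)))) {
    pk <- xbridge:::xb_pack(m)
    for (x in runif(25, -30, 17.9)) {
      rc <- xbridge:::cpp_rates_all(pk, x)
      rr <- xbridge:::xb_rates_at(m, x)
      expect_lt(max(abs(rc - rr) / pmax(abs(rr), 1e-290)), 1e-12)
    }
  }
})

test_that("state aliases resolve and misuse raises errors", {
  m <- default_model()
  expect_identical(canonical_state(c("AMD_PP", "AMD_PiR")), c("AMDP_PP", "AMDP_PiR"))
  expect_equal(free_energy(m, "AMD_PP", 8), free_energy(m, "AMDP_PP", 8))
  expect_error(elastic_energy(m, "MDP", 0), "detached")
  expect_error(cross_bridge_force(m, "MT", 0), "detached")
  expect_error(elastic_energy(m, "NOSUCH", 0), "unknown state")
  expect_error(transition_rate(m, "MT", "AM", 0), "no transition")
  # zero-strain table values are reproduced at each transition's reference
  expect_equal(transition_rate(m, "MDP", "AMDP_PP", m$params$x1), 200)
  expect_equal(transition_rate(m, "AMD_L", "AMD_H", m$params$x11), 50)
  expect_equal(transition_rate(m, "MT", "MDP", 3.2), 100)
})

test_that("model validation enforces the stated invariants", {
  expect_error(crossbridge_model(x1 = 5, x11 = 7.5), "x2 < x11 < x1")
  expect_error(crossbridge_model(ks = -1))
  expect_error(crossbridge_model(elasticity = "cubic"), "linear")
  expect_error(crossbridge_model(sites_per_zone = 2), "1 or 3")
  st <- xbridge:::xb_default_states()
  st$g[1] <- 24  # cycle drop no longer 25 kBT
  expect_error(crossbridge_model(states = st, check_cycle = TRUE), "dG_ATP")
})

test_that("the packaged parameter file reproduces the built-in defaults", {
  f <- system.file("extdata", "default_params.yaml", package = "xbridge")
  mf <- crossbridge_model(file = f)
  m <- default_model()
  expect_equal(mf$params, m$params)
  expect_equal(mf$scheme$trans, m$scheme$trans)
  expect_equal(mf$scheme$states, m$scheme$states)
  # write_params round-trips
  tmp <- tempfile(fileext = ".yaml")
  write_params(m, tmp)
  m2 <- crossbridge_model(file = tmp)
  expect_equal(m2$scheme$trans, m$scheme$trans)
})
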