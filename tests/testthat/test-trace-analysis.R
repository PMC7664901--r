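# Step detection, clustering, work, force-rise fitting, Spearman statistics

test_that("step detection is exact on noiseless staircases", {
  tr <- list(time = seq(0, 0.5, by = 0.1),
             position = c(0, cumsum(rep(4, 5))))
  st <- detect_steps(tr)
  expect_equal(nrow(st), 5)
  expect_equal(st$amplitude, rep(4, 5))
  expect_equal(st$time, seq(0.1, 0.5, by = 0.1))
  flat <- list(time = 0:10 / 10, position = rep(2, 11))
  expect_equal(nrow(detect_steps(flat)), 0)
  expect_error(detect_steps(list(time = numeric(), position = numeric())),
               "empty")
  # signed amplitudes and thresholding
  tr2 <- list(time = c(0, 1, 2, 3), position = c(0, 2, 1.7, -3))
  st2 <- detect_steps(tr2, min_amplitude_nm = 0.5)
  expect_equal(st2$amplitude, c(2, -4.7))
})

test_that("greedy windowing clusters steps as a brute-force scan does", {
  s3 <- data.frame(time = c(0, 1e-4, 2e-4), amplitude = 1)
  expect_equal(cluster_steps(s3)$cluster, rep(1L, 3))
  s2 <- data.frame(time = c(0, 1e-3), amplitude = 1)
  expect_equal(cluster_steps(s2)$cluster, 1:2)
  # brute-force oracle: walk times, open a new cluster when the gap from the
  # cluster's first step exceeds the window
  brute <- function(times, w) {
    cl <- integer(length(times)); cur <- 0L; t0 <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - t0 > w) { cur <- cur + 1L; t0 <- times[i] }
      cl[i] <- cur
    }
    cl
  }
  set.seed(17)
  for (rep in 1:5) {
    tms <- sort(cumsum(stats::rexp(200, 2000)))
    df <- data.frame(time = tms, amplitude = 1)
    expect_equal(cluster_steps(df, 0.4)$cluster, brute(tms, 4e-4))
  }
  # cluster summary sizes are consistent
  cl <- cluster_steps(data.frame(time = c(0, 1e-4, 5e-3, 5.2e-3), amplitude = 1))
  expect_equal(attr(cl, "clusters")$n_steps, c(2, 2))
})

test_that("mechanical work converts step x load to thermal units and flags ATP excess", {
  w <- mechanical_work(4, 30)
  expect_equal(w$work_pNnm, 120)
  expect_equal(w$work_kBT, 30)
  expect_true(w$exceeds_ATP)                       # 30 kBT > 25 kBT per ATP
  expect_equal(mechanical_work(0, 50)$work_pNnm, 0)
  expect_false(mechanical_work(3, 30)$exceeds_ATP) # 22.5 kBT
  # bilinear and symmetric under unit rescaling
  expect_equal(mechanical_work(8, 30)$work_pNnm, 2 * 120)
  expect_equal(mechanical_work(4, 60)$work_pNnm, 2 * 120)
  expect_equal(mechanical_work(2, 60)$work_pNnm, mechanical_work(4, 30)$work_pNnm)
})

test_that("force-rise fit recovers an exact exponential to 1e-6", {
  t <- seq(0, 0.2, by = 5e-4)
  tr <- list(time = t, force = 300 * (1 - exp(-50 * t)))
  fit <- fit_force_rise(tr)
  expect_equal(fit$k, 50, tolerance = 1e-6)
  expect_equal(fit$F_inf, 300, tolerance = 1e-6)
})

test_that("force-rise rate recovery is unbiased under 5% noise", {
  t <- seq(0, 0.2, by = 1e-3)
  truth <- 50
  set.seed(77)
  ks <- replicate(100, {
    f <- 300 * (1 - exp(-truth * t)) + stats::rnorm(length(t), 0, 15)
    fit_force_rise(list(time = t, force = f))$k
  })
  expect_lt(abs(mean(ks) - truth) / truth, 0.02)
})

test_that("restricting the fit to the upper half of the rise is a reported sensitivity", {
  t <- seq(0, 0.3, by = 5e-4)
  f <- 300 * (1 - 0.7 * exp(-60 * t) - 0.3 * exp(-15 * t))  # biexponential
  full <- fit_force_rise(list(time = t, force = f), window = "full")
  up <- fit_force_rise(list(time = t, force = f), window = "upper_half")
  expect_true(full$k > 0 && up$k > 0)
  expect_equal(up$window, "upper_half")
  expect_false(isTRUE(all.equal(full$k, up$k)))
})

test_that("Spearman correlation is exact for small samples", {
  s <- spearman(1:5, 1:5)
  expect_equal(s$r, 1)
  expect_equal(s$p, 2 / 120)               # two-sided exact
  expect_equal(spearman(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  expect_error(spearman(1:3, 1:4))
})

test_that("exact Spearman p equals full enumeration for n <= 7", {
  set.seed(23)
  for (n in 4:7) {
    x <- stats::rnorm(n)
    y <- stats::rnorm(n)
    s <- spearman(x, y)
    rx <- rank(x); ry <- rank(y)
    robs <- stats::cor(rx, ry)
    ps <- vapply(perms_of(ry), function(p) stats::cor(rx, p), numeric(1))
    expect_equal(s$p, mean(abs(ps) >= abs(robs) - 1e-12))
  }
  # with ties (mid-ranks)
  x <- c(1, 2, 2, 3, 4); y <- c(2, 1, 3, 3, 5)
  s <- spearman(x, y)
  expect_equal(s$r, stats::cor(rank(x), rank(y)))
  rx <- rank(x); ry <- rank(y)
  ps <- vapply(perms_of(ry), function(p) stats::cor(rx, p), numeric(1))
  expect_equal(s$p, mean(abs(ps) >= abs(stats::cor(rx, ry)) - 1e-12))
})

test_that("exact Spearman p agrees with the independent implementation in stats", {
  set.seed(61)
  for (rep in 1:5) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    s <- spearman(x, y)
    ct <- stats::cor.test(x, y, method = "spearman")
    expect_equal(s$p, ct$p.value, tolerance = 1e-12)
    expect_equal(s$r, unname(ct$estimate), tolerance = 1e-12)
  }
  # large-sample fallback
  set.seed(62)
  x <- stats::rnorm(40); y <- x + stats::rnorm(40)
  s <- spearman(x, y)
  expect_equal(s$method, "approximate")
  expect_lt(s$p, 0.01)
})
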