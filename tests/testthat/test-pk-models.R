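# Forward pharmacokinetic model curves and their mutual consistency.

test_that("exponential-kernel convolution handles the degenerate kernels", {
  t <- seq(0, 100, 0.5)
  cp <- biexp_cp(biexp_aif(), t)
  # kep = 0: kernel is the constant Ktrans -> running trapezoidal integral
  out <- exp_kernel_convolve(t, cp, Ktrans = 0.3, kep = 0)
  tm <- t / 60
  trap <- c(0, cumsum((cp[-1] + cp[-length(cp)]) / 2 * diff(tm)))
  expect_equal(out, 0.3 * trap, tolerance = 1e-12)
  # Ktrans = 0: identically zero
  expect_equal(exp_kernel_convolve(t, cp, 0, 1), rep(0, length(t)))
  expect_error(exp_kernel_convolve(c(0, 1, 3), c(0, 1, 1), 0.1, 1),
               "uniform")
})

test_that("analytic Tofts equals the discrete convolution on a fine grid", {
  aif <- biexp_aif()
  t <- seq(0, 590, 0.5)
  cp <- biexp_cp(aif, t)
  for (p in list(c(0.01, 0.5), c(0.1, 0.2), c(0.35, 0.05))) {
    ca <- tofts_ct_analytic(p[1], p[2], aif, t)
    cn <- exp_kernel_convolve(t, cp, p[1], p[1] / p[2])
    i <- t > 30
    expect_lt(max(abs(cn[i] - ca[i]) / ca[i]), 1e-3)
  }
})

test_that("Tofts-family curves start at zero and stay non-negative", {
  aif <- biexp_aif()
  t <- seq(-30, 300, 1.5)
  set.seed(3)
  for (i in 1:20) {
    K <- runif(1, 0.01, 0.5); ve <- runif(1, 0.05, 0.9)
    vp <- runif(1, 0, 1 - ve)
    ct <- tofts_ct_analytic(K, ve, aif, t)
    cx <- ext_tofts_ct(K, ve, vp, aif, t)
    expect_true(all(ct[t <= 0] == 0))
    expect_true(all(cx[t < 0] == 0))
    expect_true(all(ct >= 0) && all(cx >= 0))
  }
  expect_equal(tofts_ct_analytic(0, 0.3, aif, t), rep(0, length(t)))
})

test_that("extended Tofts reduces to its special cases", {
  aif <- biexp_aif()
  t <- seq(0, 240, 0.5)
  expect_equal(ext_tofts_ct(0.2, 0.3, 0, aif, t),
               tofts_ct_analytic(0.2, 0.3, aif, t), tolerance = 1e-12)
  cp <- biexp_cp(aif, t)
  expect_equal(ext_tofts_ct(0, 0.3, 0.05, aif, t), 0.05 * cp,
               tolerance = 1e-12)
  # sampled-AIF route agrees with the analytic route away from the bolus
  saif <- sampled_aif(t, cp)
  i <- t > 30
  a1 <- ext_tofts_ct(0.1, 0.2, 0.03, aif, t)
  a2 <- ext_tofts_ct(0.1, 0.2, 0.03, saif, t)
  expect_lt(max(abs(a1[i] - a2[i]) / a1[i]), 1e-3)
  expect_error(ext_tofts_ct(0.1, 0.8, 0.3, aif, t), "exceed")
})

test_that("Hoffmann enhancement matches direct evaluation and its limit", {
  # t in seconds; rates per minute: evaluate at 1 min and 2 min
  expect_equal(hoffmann_signal(1, 1, 0.1, 1, 60),
               1 + (exp(-1) - exp(-0.1)) / (0.1 - 1), tolerance = 1e-12)
  expect_equal(hoffmann_signal(1, 1, 0.1, 1, 60), 1.59662, tolerance = 1e-5)
  expect_equal(hoffmann_signal(1, 0.5, 0.5, 1, 120), 1 + 0.5 * 2 * exp(-1),
               tolerance = 1e-12)
  expect_equal(hoffmann_signal(1, 0.5, 0.5, 1, 120), 1.36788,
               tolerance = 1e-5)
  # S(0) = S0 always; pre-injection frames return the baseline
  expect_equal(hoffmann_signal(2, 0.7, 0.05, 123, 0), 123)
  expect_equal(hoffmann_signal(2, 0.7, 0.05, 123, -30), 123)
  # continuity across the removable singularity kel -> kep
  t <- seq(0, 300, 5)
  near <- hoffmann_signal(1.5, 0.8, 0.8 + 1e-9, 100, t)   # limit branch
  off <- hoffmann_signal(1.5, 0.8, 0.8 + 1e-6, 100, t)    # generic branch
  expect_lt(max(abs(near - off) / off), 1e-6)
})

test_that("Hoffmann curve peaks then decays for kel < kep", {
  t <- seq(0, 1200, 2)
  s <- hoffmann_signal(1, 1.2, 0.05, 1, t)
  pk <- which.max(s)
  expect_gt(pk, 1)
  expect_lt(pk, length(s))
  expect_true(all(diff(s[pk:length(s)]) <= 0))
})

test_that("Larsson signal has exactly the declared initial slope", {
  aif <- biexp_aif()
  # second-order one-sided difference at t = 0+ with h = 1e-4 min
  # (the curve is flat for t < 0, so a one-sided stencil is required)
  h <- 1e-4                                   # minutes
  for (p in list(c(0.6, 200, 80), c(2.5, 1000, -40))) {
    f <- function(tmin) larsson_signal(p[1], p[2], p[3], aif$a, aif$m,
                                       tmin * 60)
    slope <- (4 * f(h) - 3 * f(0) - f(2 * h)) / (2 * h)   # signal per min
    expect_equal(slope, p[3], tolerance = 1e-6)
    expect_equal(f(0), p[2])
  }
})

test_that("Larsson with a single-exponential plasma curve matches direct form", {
  kep <- 0.9; m1 <- 0.2; S0 <- 150; Sd <- 30
  t <- seq(0, 360, 3)
  tm <- t / 60
  direct <- S0 + Sd * (exp(-kep * tm) - exp(-m1 * tm)) / (m1 - kep)
  expect_equal(larsson_signal(kep, S0, Sd, a = 1, m = m1, t), direct,
               tolerance = 1e-12)
})

test_that("reference-region model satisfies its algebraic identities", {
  aif <- biexp_aif()
  t <- seq(-10, 600, 1)
  ctr <- tofts_ct_analytic(0.14, 0.3, aif, t)
  # tissue identical to reference: curve reproduced exactly
  expect_equal(rr_ct(0.14, 0.3, 0.14, 0.3, t, ctr), ctr, tolerance = 1e-12)
  # no uptake: zero
  expect_equal(rr_ct(0, 0.3, 0.14, 0.3, t, ctr), rep(0, length(t)))
  # linearity in the reference curve
  expect_equal(rr_ct(0.3, 0.45, 0.14, 0.3, t, 2 * ctr),
               2 * rr_ct(0.3, 0.45, 0.14, 0.3, t, ctr), tolerance = 1e-12)
})

test_that("reference-region model reproduces a Tofts-generated tissue curve", {
  aif <- biexp_aif()
  t <- seq(-10, 600, 1)
  for (p in list(c(0.3, 0.45), c(0.05, 0.15))) {
    ctr <- tofts_ct_analytic(0.12, 0.25, aif, t)
    ct <- tofts_ct_analytic(p[1], p[2], aif, t)
    pred <- rr_ct(p[1], p[2], 0.12, 0.25, t, ctr)
    i <- t > 30
    expect_lt(max(abs(pred[i] - ct[i]) / ct[i]), 0.01)
  }
})
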