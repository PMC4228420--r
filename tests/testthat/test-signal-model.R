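# MR signal equations and their inversions to concentration.

test_that("spin-echo signal follows the saturation-recovery form", {
  expect_equal(spin_echo_signal(1, T1 = 1000, TR = 200), 1 - exp(-0.2),
               tolerance = 1e-12)
  expect_equal(spin_echo_signal(1, T1 = 1000, TR = 200), 0.18127,
               tolerance = 1e-4)
  # T1 -> Inf kills the signal; TR >> T1 saturates it
  expect_lt(spin_echo_signal(1, T1 = 1e12, TR = 200), 1e-9)
  expect_equal(spin_echo_signal(1, T1 = 1, TR = 1000), 1, tolerance = 1e-12)
  # monotone increasing in TR, decreasing in T1
  trs <- seq(10, 2000, length.out = 25)
  expect_true(all(diff(spin_echo_signal(1, 800, trs)) > 0))
  t1s <- seq(200, 3000, length.out = 25)
  expect_true(all(diff(spin_echo_signal(1, t1s, 300)) < 0))
  expect_error(spin_echo_signal(1, -5, 100), "T1")
  expect_error(spin_echo_signal(1, 100, 0), "TR")
})

test_that("SPGR signal reduces to known limits and matches the closed form", {
  # alpha = 90 deg: saturation recovery
  expect_equal(spgr_signal(2, 1000, 200, 90),
               spin_echo_signal(2, 1000, 200), tolerance = 1e-12)
  # TR -> Inf: S0 sin(alpha)
  expect_equal(spgr_signal(1, 1000, 1e9, 30), sin(30 * pi / 180),
               tolerance = 1e-9)
  # direct evaluation at the single-compartment phantom sequence settings
  E <- exp(-5 / 1000)
  a <- 30 * pi / 180
  expect_equal(spgr_signal(1, 1000, 5, 30),
               (1 - E) * sin(a) / (1 - E * cos(a)), tolerance = 1e-14)
  expect_error(spgr_signal(1, 1000, 5, 0), "alpha")
  expect_error(spgr_signal(1, 1000, 5, 120), "alpha")
})

test_that("relaxation-rate calibration is linear and self-inverse", {
  rp <- relaxation_params(r1 = 4.5, T10 = 1000)
  expect_equal(t1_from_concentration(0, rp), 1000)
  # 1/T1 = 1/1.0s + 4.5*0.5 = 3.25 s^-1 -> 307.69 ms
  expect_equal(t1_from_concentration(0.5, rp), 1000 / 3.25,
               tolerance = 1e-12)
  expect_equal(t1_from_concentration(0.5, rp), 307.69, tolerance = 1e-4)
  ct <- seq(0, 5, by = 0.25)
  expect_equal(concentration_from_t1(t1_from_concentration(ct, rp), rp),
               ct, tolerance = 1e-12)
  # T1 above T10 implies negative concentration, flagged
  out <- concentration_from_t1(1200, rp)
  expect_lt(as.numeric(out), 0)
  expect_true(any(attr(out, "invalid")))
  expect_error(t1_from_concentration(-1, rp), "non-negative")
})

test_that("spin-echo concentration inversion is exact against its forward model", {
  rp <- relaxation_params(4.5, 1000)
  acq <- acquisition_params("spin_echo", TR = 200, frame_interval = 51.2,
                            injection_frame = 5)
  A <- 1500                                   # equilibrium amplitude
  s0b <- spin_echo_signal(A, 1000, 200)
  # baseline maps to exactly zero
  expect_equal(as.numeric(concentration_from_spinecho(s0b, s0b, acq, rp)),
               0, tolerance = 1e-12)
  # forward-model round trip across the physiologic range
  set.seed(42)
  for (i in 1:50) {
    ct <- runif(1, 0, 4)
    T10 <- runif(1, 300, 2500)
    TR <- runif(1, 50, 800)
    rpi <- relaxation_params(4.5, T10)
    acqi <- acquisition_params("spin_echo", TR = TR, frame_interval = 1,
                               injection_frame = 1)
    s0 <- spin_echo_signal(A, T10, TR)
    st <- spin_echo_signal(A, t1_from_concentration(ct, rpi), TR)
    est <- concentration_from_spinecho(st, s0, acqi, rpi)
    expect_equal(as.numeric(est), ct, tolerance = 1e-9)
    expect_false(any(attr(est, "invalid")))
  }
})

test_that("noise beyond the invertible spin-echo range is clamped and flagged", {
  rp <- relaxation_params(4.5, 1000)
  acq <- acquisition_params("spin_echo", TR = 200, frame_interval = 1,
                            injection_frame = 1)
  s0b <- spin_echo_signal(1000, 1000, 200)
  bad <- s0b / (1 - exp(-0.2)) * 1.05        # pushes log argument negative
  out <- concentration_from_spinecho(c(s0b, bad), s0b, acq, rp)
  expect_identical(attr(out, "invalid"), c(FALSE, TRUE))
  expect_true(all(is.finite(out)))
})

test_that("SPGR inversion recovers T1 exactly and degrades monotonically", {
  rp <- relaxation_params(4.5, 1000)
  acq <- acquisition_params("spgr", TR = 5, flip_angle = 25,
                            frame_interval = 0.5, injection_frame = 10)
  A <- 250
  s0b <- spgr_signal(A, 1000, 5, 25)
  out <- t1_from_spgr(s0b, s0b, acq, rp)
  expect_equal(as.numeric(out), 1000, tolerance = 1e-9)
  # round trip over random physiologic parameters, including the calibration
  set.seed(7)
  for (i in 1:50) {
    ct <- runif(1, 0, 4)
    T10 <- runif(1, 300, 2500)
    alpha <- runif(1, 5, 90)
    rpi <- relaxation_params(4.5, T10)
    acqi <- acquisition_params("spgr", TR = 5, flip_angle = alpha,
                               frame_interval = 1, injection_frame = 1)
    s0 <- spgr_signal(A, T10, 5, alpha)
    st <- spgr_signal(A, t1_from_concentration(ct, rpi), 5, alpha)
    expect_equal(as.numeric(t1_from_spgr(st, s0, acqi, rpi)),
                 t1_from_concentration(ct, rpi), tolerance = 1e-9 * T10)
    expect_equal(as.numeric(concentration_from_spgr(st, s0, acqi, rpi)),
                 ct, tolerance = 1e-9)
  }
  # enhancement above baseline shortens T1
  sts <- s0b * seq(1, 1.8, by = 0.1)
  t1s <- as.numeric(t1_from_spgr(sts, s0b, acq, rp))
  expect_true(all(diff(t1s) < 0))
  # out-of-range fraction is clamped + flagged
  far <- s0b * 50
  out2 <- t1_from_spgr(far, s0b, acq, rp)
  expect_true(any(attr(out2, "invalid")))
})

test_that("calibration depends only on signal ratios", {
  rp <- relaxation_params(4.5, 1000)
  for (kind in c("spin_echo", "spgr")) {
    acq <- acquisition_params(kind, TR = if (kind == "spgr") 5 else 200,
                              flip_angle = 30, frame_interval = 1,
                              injection_frame = 1)
    conv <- function(st, s0) as.numeric(
      if (kind == "spgr") concentration_from_spgr(st, s0, acq, rp)
      else concentration_from_spinecho(st, s0, acq, rp))
    st <- 120; s0 <- 100
    for (scale in c(0.01, 1, 37.5))
      expect_equal(conv(st * scale, s0 * scale), conv(st, s0),
                   tolerance = 1e-10)
  }
})

test_that("variable-TR T10 estimation recovers noise-free truth", {
  T10 <- 1000; A <- 800
  TRs <- c(200, 1200)
  imgs <- lapply(TRs, function(tr)
    matrix(spin_echo_signal(A, T10, tr), 2, 2))
  est <- estimate_t10(imgs, TRs, method = "two_point_ratio")
  expect_equal(as.vector(est$T10), rep(T10, 4), tolerance = 1e-6)
  expect_false(any(est$invalid))
  # three images, per-pixel least squares: exact (S0, T10) recovery
  T10map <- matrix(c(400, 800, 1200, 2000), 2, 2)
  TRs3 <- c(150, 600, 2400)
  imgs3 <- lapply(TRs3, function(tr) spin_echo_signal(A, T10map, tr))
  est3 <- estimate_t10(imgs3, TRs3, method = "least_squares")
  expect_equal(est3$T10, T10map, tolerance = 1e-6)
})

test_that("T10 estimation rejects degenerate inputs and flags bad ratios", {
  img <- matrix(1, 2, 2)
  expect_error(estimate_t10(list(img), 200), "at least two")
  expect_error(estimate_t10(list(img, img), c(200, 200)), "distinct")
  expect_error(estimate_t10(list(img, matrix(1, 3, 2)), c(200, 400)),
               "same shape")
  # ratio above 1 is unattainable for TR1 < TR2
  est <- estimate_t10(list(matrix(2, 1, 1), matrix(1, 1, 1)), c(200, 800))
  expect_true(est$invalid[1, 1])
  expect_true(is.na(est$T10[1, 1]))
})
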