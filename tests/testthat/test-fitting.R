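# Curve fitting, binning and map assembly.

test_that("bin_signals at k = 1 returns per-pixel curves unchanged", {
  s <- tiny_series()
  roi <- full_roi(s)
  b <- bin_signals(s, roi)
  expect_equal(nrow(b$curves), 8 * 6)
  expect_equal(b$grid_dim, c(6, 8))
  # spot-check a pixel: cell (row=2, col=3) is pixel y=3, x=4 (0-based 2,3)
  i <- which(b$cells$row == 2 & b$cells$col == 3)
  expect_equal(b$curves[i, ], s$data[4, 3, 1, ])
})

test_that("bin_signals averages k x k blocks anchored at the mask bounding box", {
  s <- tiny_series(nx = 9, ny = 7)
  m <- matrix(FALSE, 7, 9)
  m[2:7, 3:8] <- TRUE                        # 6 x 6 box offset from origin
  roi <- dce_roi(m, bin_factor = 2L)
  b <- bin_signals(s, roi)
  expect_equal(b$grid_dim, c(3, 3))
  expect_equal(unname(b$origin), c(1L, 2L))
  # first cell = pixels (y 2:3, x 3:4)
  i <- which(b$cells$row == 0 & b$cells$col == 0)
  manual <- apply(s$data[3:4, 2:3, 1, , drop = FALSE], 4, mean)
  expect_equal(b$curves[i, ], manual)
  expect_equal(b$cells$n_pixels[i], 4L)
  # a cell with no masked pixels is skipped entirely
  m2 <- m; m2[4:5, 5:6] <- FALSE
  b2 <- bin_signals(s, dce_roi(m2, bin_factor = 2L))
  expect_lt(nrow(b2$cells), nrow(b$cells))
})

test_that("block-averaging i.i.d. noise scales sigma by 1/k", {
  n <- 240
  arr <- array(1000, dim = c(n, n, 1, 12))
  s <- dce_series(arr, acquisition_params("spin_echo", 200,
                                          frame_interval = 1,
                                          injection_frame = 6))
  noisy <- add_gaussian_noise(s, 0.2, seed = 99)
  for (k in c(2L, 5L)) {
    roi <- full_roi(noisy); roi$bin_factor <- k
    b <- bin_signals(noisy, roi)
    dev <- b$curves - 1000
    expect_equal(stats::sd(dev), 0.2 * 1000 / k, tolerance = 0.02)
  }
})

test_that("noise-free curves are recovered to numerical precision", {
  t <- (0:40) * 51.2 - 5 * 51.2
  y <- hoffmann_signal(1.2, 0.8, 0.05, 500, t)
  f <- dce_fit(t, y, "hoffmann")
  expect_true(f$converged)
  expect_equal(unname(coef(f)), c(1.2, 0.8, 0.05), tolerance = 1e-6)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-8)
  # stderr present on convergence, near zero for a perfect fit
  expect_false(is.null(f$stderr))
  expect_true(all(f$stderr < 1e-6))

  aif <- biexp_aif()
  t2 <- seq(-60, 540, 0.5)
  y2 <- tofts_ct_analytic(0.2, 0.5, aif, t2)
  f2 <- dce_fit(t2, y2, "tofts", aif = aif)
  expect_lt(max(abs(coef(f2) - c(0.2, 0.5)) / c(0.2, 0.5)), 0.02)

  y3 <- larsson_signal(0.9, 400, 150, aif$a, aif$m, t)
  f3 <- dce_fit(t, y3, "larsson", aif = aif)
  expect_lt(max(abs(coef(f3) - c(0.9, 150)) / c(0.9, 150)), 1e-6)
})

test_that("flat curves are flagged degenerate, NaN frames are dropped", {
  t <- (0:40) * 51.2 - 5 * 51.2
  f <- dce_fit(t, rep(100, 41), "hoffmann")
  expect_false(f$converged)
  expect_identical(f$reason, "degenerate")
  expect_true(all(is.na(coef(f))))
  expect_null(f$stderr)

  y <- hoffmann_signal(1.2, 0.8, 0.05, 500, t)
  y[c(10, 20)] <- NaN
  f2 <- dce_fit(t, y, "hoffmann")
  expect_true(f2$converged)
  expect_equal(f2$dropped_frames, 2L)
  expect_equal(unname(coef(f2)), c(1.2, 0.8, 0.05), tolerance = 1e-6)
  expect_error(dce_fit(t, c(y[1:3], rep(NaN, 38)), "hoffmann"),
               "finite observations")
})

test_that("missing model inputs raise configuration errors", {
  t <- 0:20
  expect_error(dce_fit(t, t * 0.01, "tofts"), "requires an AIF")
  expect_error(dce_fit(t, t * 0.01, "rr"), "Ct_r")
  expect_error(dce_fit(t, t * 0.01, "hoffmann"), "S0")
  s <- tiny_series()
  expect_error(fit_roi(s, full_roi(s), "tofts", aif = biexp_aif()),
               "relaxation")
  expect_error(fit_roi(s, full_roi(s), "tofts",
                       relax = relaxation_params(4.5, 1000)), "AIF")
  expect_error(fit_roi(s, full_roi(s), "rr",
                       relax = relaxation_params(4.5, 1000)), "rr")
})

test_that("fitting a homogeneous patch's binned mean equals any member pixel", {
  ph <- tofts_phantom()
  roi10 <- ph$tissue_roi; roi10$bin_factor <- 10L
  map10 <- patch_map(ph, "tofts")
  # pick the (ve = 0.2, Ktrans = 0.1) patch: row 4, col 4 on the patch grid
  est_binned <- c(map10$params$Ktrans[4, 4], map10$params$ve[4, 4])
  acq <- ph$series$acq
  tmod <- ph$series$frame_times - ph$series$frame_times[acq$injection_frame + 1]
  px <- ph$series$data[35, 35, 1, ]          # a pixel inside that patch
  ct <- concentration_from_spgr(px, mean(px[1:acq$injection_frame]), acq,
                                ph$relax)
  f <- dce_fit(tmod, as.numeric(ct), "tofts", aif = ph$spec$aif)
  expect_equal(est_binned, unname(coef(f)), tolerance = 1e-9)
})

test_that("fit_roi maps are deterministic and carry flags", {
  ph <- tofts_phantom()
  m <- matrix(FALSE, 60, 60)
  m[12:18, 22:31] <- TRUE
  roi <- dce_roi(m, bin_factor = 3L)
  m1 <- fit_roi(ph$series, roi, "tofts", relax = ph$relax,
                aif = ph$spec$aif)
  m2 <- fit_roi(ph$series, roi, "tofts", relax = ph$relax,
                aif = ph$spec$aif)
  expect_identical(m1$params, m2$params)     # bit-identical rerun
  expect_identical(m1$stderr, m2$stderr)
  expect_true(all(is.na(m1$params$Ktrans[!m1$converged])))
  expect_true(all(!is.na(m1$params$Ktrans[m1$converged])))
})

test_that("roi_statistics summarises converged cells with sd conventions", {
  ph <- tofts_phantom()
  map <- patch_map(ph, "tofts")
  st <- roi_statistics(map)
  expect_setequal(st$parameter, c("Ktrans", "ve"))
  expect_equal(st$n, c(30, 30))
  expect_equal(st$mean[st$parameter == "Ktrans"],
               mean(truth_patches(ph, "Ktrans")), tolerance = 1e-6)
  # single-cell map: sd = 0 by convention
  m <- matrix(FALSE, 60, 60); m[3, 3] <- TRUE
  one <- fit_roi(ph$series, dce_roi(m), "tofts", relax = ph$relax,
                 aif = ph$spec$aif)
  st1 <- roi_statistics(one)
  expect_equal(st1$sd, c(0, 0))
  expect_equal(st1$n, c(1, 1))
})

test_that("dce_fit methods expose the fit consistently", {
  aif <- biexp_aif()
  t <- seq(-30, 300, 2)
  y <- tofts_ct_analytic(0.25, 0.4, aif, t)
  f <- dce_fit(t, y, "tofts", aif = aif)
  expect_s3_class(f, "dce_fit")
  expect_named(coef(f), c("Ktrans", "ve"))
  expect_equal(fitted(f) + residuals(f), y)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, t = 120), tofts_ct_analytic(0.25, 0.4, aif, 120),
               tolerance = 1e-6)
  s <- summary(f)
  expect_s3_class(s, "summary.dce_fit")
  expect_output(print(f), "Ktrans")
  expect_output(print(s), "converged")
})
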