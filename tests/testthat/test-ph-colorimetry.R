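rgb_frame <- function(r, g, b, n = 4) {
  arr <- array(0, c(n, n, 3))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  arr
}

test_that("mean hue reproduces the primary hue angles", {
  expect_equal(as.numeric(mean_hue(rgb_frame(1, 0, 0))), 0)
  expect_equal(as.numeric(mean_hue(rgb_frame(0, 1, 0))), 120)
  expect_equal(as.numeric(mean_hue(rgb_frame(0, 0, 1))), 240)
})

test_that("hue is invariant to uniform brightness scaling", {
  set.seed(5)
  arr <- array(runif(3 * 64), c(8, 8, 3))
  h1 <- as.numeric(mean_hue(arr))
  for (cscale in c(0.2, 0.5, 0.9)) {
    expect_equal(as.numeric(mean_hue(arr * cscale)), h1, tolerance = 1e-9)
  }
})

test_that("achromatic and empty-mask cases are handled", {
  grey <- rgb_frame(0.5, 0.5, 0.5)
  h <- mean_hue(grey)
  expect_equal(as.numeric(h), 0)
  expect_true(attr(h, "achromatic"))
  expect_error(mean_hue(grey, matrix(FALSE, 4, 4)),
               class = "woundfield_domain_error")
})

test_that("bi-dose-response has the right asymptotes and reductions", {
  pars <- default_ph_curve_params()
  expect_equal(bidose_response(-1e6, pars), pars$A1)
  expect_equal(bidose_response(1e6, pars), pars$A2)
  # p = 1 collapses to a single logistic in (logx01, h1)
  p1 <- modifyList(pars, list(p = 1))
  single <- pars$A1 + (pars$A2 - pars$A1) /
    (1 + 10^(pars$h1 * (pars$logx01 - 7)))
  expect_equal(bidose_response(7, p1), single)
})

test_that("calibration fit recovers generating parameters from noisy hues", {
  truep <- default_ph_curve_params()
  for (s in c(1, 7, 13)) {
    set.seed(s)
    ph <- seq(2.7, 11.3, length.out = 15)
    hue <- bidose_response(ph, truep) + rnorm(15, 0, 2)
    fit <- fit_calibration(data.frame(ph = ph, hue = hue))
    est <- fit$params
    for (nm in c("A1", "A2", "logx01", "logx02")) {
      expect_lt(abs(est[[nm]] - truep[[nm]]) / abs(truep[[nm]]), 0.10)
    }
  }
})

test_that("noiseless calibration data is fitted essentially exactly", {
  ph <- seq(2.7, 11.3, length.out = 15)
  hue <- bidose_response(ph, default_ph_curve_params())
  fit <- fit_calibration(data.frame(ph = ph, hue = hue))
  expect_lt(fit$rmse_deg, 1e-6)
})

test_that("too few calibration points raise a fit error", {
  expect_error(fit_calibration(data.frame(ph = c(3, 5, 7), hue = c(80, 150, 250))),
               class = "woundfield_fit_error")
})

test_that("hue inversion round-trips and respects the domain", {
  cv <- ph_curve()
  for (ph in c(3.5, 7, 10.5)) {
    expect_equal(as.numeric(hue_to_ph(bidose_response(ph, cv$params), cv)),
                 ph, tolerance = 1e-3)
  }
  # domain-edge hue returns the edge pH
  edge_hue <- bidose_response(cv$domain[1], cv$params)
  expect_equal(as.numeric(hue_to_ph(edge_hue, cv)), cv$domain[1],
               tolerance = 1e-6)
  # out-of-range hue is clamped, flagged and warned about
  expect_warning(res <- hue_to_ph(edge_hue - 10, cv))
  expect_true(attr(res, "extrapolated"))
  expect_equal(as.numeric(res), cv$domain[1], tolerance = 1e-6)
})

test_that("non-monotone curves are refused for inversion", {
  bad <- ph_curve(params = list(A1 = 80, A2 = 280, logx01 = 5, logx02 = 9,
                                h1 = 2, h2 = -2, p = 0.7))
  expect_error(hue_to_ph(150, bad), class = "woundfield_domain_error")
})

test_that("ROI traces track the imposed pH fields", {
  cv <- ph_curve()
  # constant pH everywhere: flat traces at 7.4
  stk <- synthetic_ph_stack(replicate(6, matrix(7.4, 30, 30), simplify = FALSE),
                            cv, noise_sigma_deg = 2, seed = 2)
  rois <- data.frame(label = c("anode", "centre"), x0 = c(1, 16),
                     x1 = c(15, 30), y0 = 1, y1 = 30,
                     in_channel = c(FALSE, TRUE))
  tr <- roi_ph_traces(stk, rois, cv, frame_interval_min = 10)
  expect_true(all(abs(tr$ph - 7.4) < 0.05))
  expect_true("wound_mean" %in% tr$roi)
  expect_equal(tr$time_h[tr$roi == "centre"], (0:5) * 10 / 60)

  # acidifying anode ROI: monotone decreasing recovered trace
  fields <- lapply(seq(7.4, 5.4, length.out = 8), function(v) {
    f <- matrix(7.4, 30, 30); f[, 1:15] <- v; f
  })
  stk2 <- synthetic_ph_stack(fields, cv, noise_sigma_deg = 0, seed = 2)
  tr2 <- roi_ph_traces(stk2, rois, cv)
  anode <- tr2$ph[tr2$roi == "anode"]
  expect_true(all(diff(anode) < 0))
  expect_equal(anode[1], 7.4, tolerance = 5e-3)
  expect_equal(anode[8], 5.4, tolerance = 5e-3)

  # empty ROI list and out-of-frame ROI
  expect_equal(nrow(roi_ph_traces(stk, rois[0, ], cv)), 0)
  badroi <- data.frame(label = "x", x0 = 1, x1 = 99, y0 = 1, y1 = 5)
  expect_error(roi_ph_traces(stk, badroi, cv),
               class = "woundfield_geometry_error")
})
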