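test_that("segmentation finds a smooth band in a textured frame", {
  frame <- noise_gap_stack(n_frames = 1, size = 200, gap0 = 80)[[1]]
  mask <- segment_wound(frame)
  truth <- matrix(FALSE, 200, 200)
  truth[, 61:140] <- TRUE
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gt(iou, 0.9)
  expect_equal(attr(mask, "flag"), "ok")
})

test_that("degenerate frames are flagged", {
  smooth <- matrix(0.5, 100, 100)
  m <- segment_wound(smooth)
  expect_equal(attr(m, "flag"), "degenerate")
  expect_true(all(m))
})

test_that("fully textured frames yield an empty wound", {
  set.seed(9)
  tex <- matrix(0.5 + runif(200 * 200, -0.25, 0.25), 200, 200)
  m <- segment_wound(tex)
  expect_lt(attr(m, "area_px2") / length(tex), 0.05)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  frame <- noise_gap_stack(n_frames = 1, size = 150, gap0 = 60)[[1]]
  m1 <- segment_wound(frame)
  m2 <- segment_wound(0.4 * frame + 0.3)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("closure curves are normalised to the first frame", {
  stk <- noise_gap_stack(n_frames = 24, size = 200, gap0 = 100, close_by = 24)
  cc <- closure_curve(stk, frame_interval_min = 30)
  expect_equal(cc$norm_area[1], 1)
  expect_equal(cc$closure_pct[1], 0)
  expect_true(all(diff(cc$time_h) > 0))
  # gap closes linearly to zero by the last frame
  expect_gte(max(cc$closure_pct), 99)
  expect_error(closure_curve(stk[1], frame_interval_min = 30),
               class = "woundfield_domain_error")
})

test_that("closure rate is the OLS slope of closure percent", {
  line <- tibble::tibble(time_h = 0:11, closure_pct = 3 * (0:11))
  expect_equal(closure_rate(line)$rate_pct_h, 3)
  flat <- tibble::tibble(time_h = 0:11, closure_pct = rep(20, 12))
  expect_equal(closure_rate(flat)$rate_pct_h, 0)
  expect_error(closure_rate(line[1:2, ]), class = "woundfield_fit_error")
  # explicit window restricts the fit
  bent <- tibble::tibble(time_h = 0:11,
                         closure_pct = c(2 * (0:5), 10 + 8 * (1:6)))
  expect_equal(closure_rate(bent, window = c(0, 5))$rate_pct_h, 2)
})

test_that("closure rate on rendered stacks recovers the ground truth", {
  fit <- closure_rate(closure_curve(fx_stack(3.5), frame_interval_min = 10))
  expect_lt(abs(fit$rate_pct_h - 3.5), 0.5)
})

test_that("kymograph has one row per frame and averages the ROI lines", {
  stk <- fx_stack(3.5)
  ky <- kymograph(stk, roi = c(29, 228, 79, 178), n_lines = 7)
  expect_equal(nrow(ky$intensity), 72)
  expect_equal(ncol(ky$intensity), 200)
  expect_equal(length(ky$line_rows), 7)

  # temporally constant stack: all rows identical
  const <- replicate(5, stk[[1]], simplify = FALSE)
  kc <- kymograph(const, roi = c(1, 100, 1, 50))
  expect_true(all(abs(sweep(kc$intensity, 2, kc$intensity[1, ])) < 1e-12))

  # single bright column maps to a single bright kymograph column
  fr <- matrix(0, 50, 60); fr[, 33] <- 1
  kb <- kymograph(replicate(3, fr, simplify = FALSE), roi = c(1, 60, 1, 50))
  expect_true(all(kb$intensity[, 33] == 1))
  expect_true(all(kb$intensity[, -33] == 0))

  expect_error(kymograph(stk, roi = c(1, 500, 1, 50)),
               class = "woundfield_geometry_error")
  expect_error(kymograph(stk, roi = c(1, 50, 1, 5), n_lines = 7),
               class = "woundfield_geometry_error")
})

test_that("kymograph of an x-mirrored stack is the mirrored kymograph", {
  stk <- fx_stack(3.5)[1:5]
  roi <- c(79, 178, 79, 178)
  k1 <- kymograph(stk, roi)$intensity
  mirrored <- lapply(stk, function(fr) fr[, ncol(fr):1])
  roi_m <- c(256 - roi[2] + 1, 256 - roi[1] + 1, roi[3], roi[4])
  k2 <- kymograph(mirrored, roi_m)$intensity
  expect_equal(k2, k1[, ncol(k1):1], tolerance = 1e-12)
})

test_that("directedness matches hand-computed track geometry", {
  tr <- tibble::tibble(
    frame = rep(1:5, 3),
    cell_id = rep(1:3, each = 5),
    x = c(1:5, 5:1, rep(2, 5)),
    y = c(rep(1, 5), rep(1, 5), 1:5))
  d <- directedness(tr)
  expect_equal(d$mean_step_cos[d$cell_id == 1], 1)
  expect_equal(d$mean_step_cos[d$cell_id == 2], -1)
  expect_equal(d$mean_step_cos[d$cell_id == 3], 0)
  expect_equal(d$net_cos[d$cell_id == 1], 1)

  # stationary track is flagged and excluded from the cohort mean
  tr0 <- rbind(tr, tibble::tibble(frame = 1:5, cell_id = 4, x = 3, y = 3))
  d0 <- directedness(tr0)
  expect_true(d0$flagged[d0$cell_id == 4])
  g <- glance(d0)
  expect_equal(g$n_cells, 3)
  expect_equal(g$n_flagged, 1)
})

test_that("mirror tracks have opposite directedness", {
  sim <- fx_sim(3.5)
  tr <- sim$tracks[sim$tracks$cell_id %in% 1:40, ]
  tr_m <- tr
  tr_m$x <- 256 - tr_m$x
  d <- directedness(tr)$mean_step_cos
  dm <- directedness(tr_m)$mean_step_cos
  expect_equal(d + dm, rep(0, length(d)), tolerance = 1e-12)
})
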