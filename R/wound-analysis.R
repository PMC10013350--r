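#' Segment the wound (cell-free) region of a phase-contrast frame
#'
#' Wounded-monolayer frames are separated into cell-covered and cell-free
#' regions by local texture: cells produce high local intensity variance
#' while the denuded substrate is smooth. The operator computes a
#' sliding-window standard-deviation map, thresholds it by Otsu's method,
#' applies a morphological closing and keeps the largest low-texture
#' connected component that touches the declared wound axis.
#'
#' @param frame Numeric matrix (grayscale image, rows = y).
#' @param window Side of the sliding texture window (px, odd).
#' @param close_radius Radius of the disc structuring element for the
#'   morphological closing (px).
#' @param wound_axis_x Column (px) of the vertical line the wound is
#'   declared to straddle; defaults to the image centre.
#' @param min_contrast Maximum ratio of low-texture to high-texture class
#'   means for the frame to count as containing a wound. If the Otsu split
#'   is weaker than this (a unimodal texture distribution), the frame is
#'   either uniformly smooth (whole-frame wound, flagged `"degenerate"`) or
#'   uniformly textured (no wound, flagged `"empty"`), decided by the
#'   absolute texture level against `flat_texture`.
#' @param flat_texture Texture level (intensity units, images in `[0, 1]`)
#'   below which a unimodal frame counts as bare substrate. Only this
#'   degenerate tie-break uses an absolute scale; frames that contain a
#'   wound are segmented scale-invariantly.
#' @return Logical wound mask with attributes `flag`
#'   (`"ok"`, `"empty"` or `"degenerate"`) and `area_px2`.
#' @export
segment_wound <- function(frame, window = 21, close_radius = 5,
                          wound_axis_x = NULL, min_contrast = 0.5,
                          flat_texture = 0.02) {
  if (!is.matrix(frame)) {
    abort("frame must be a single-channel image matrix",
          class = "woundfield_domain_error")
  }
  wound_axis_x <- wound_axis_x %||% (ncol(frame) %/% 2L)
  tex <- local_sd(frame, window)
  rng <- range(tex)
  if (diff(rng) < 1e-12) {
    # uniformly smooth (or uniformly textured) frame: no contrast to split
    mask <- matrix(TRUE, nrow(frame), ncol(frame))
    return(structure(mask, flag = "degenerate", area_px2 = sum(mask)))
  }
  texn <- (tex - rng[1]) / diff(rng)
  thr <- EBImage::otsu(texn, range = c(0, 1))
  low <- texn < thr
  # a genuine wound separates two texture populations; a unimodal texture
  # distribution means the frame is all-substrate or all-cells
  if (mean(tex[low]) > min_contrast * mean(tex[!low])) {
    if (stats::median(tex) < flat_texture) {
      mask <- matrix(TRUE, nrow(frame), ncol(frame))
      return(structure(mask, flag = "degenerate", area_px2 = sum(mask)))
    }
    mask <- matrix(FALSE, nrow(frame), ncol(frame))
    return(structure(mask, flag = "empty", area_px2 = 0))
  }
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    low <- EBImage::closing(low * 1, brush) > 0.5
  }
  lab <- EBImage::bwlabel(low * 1)
  axis_labels <- unique(lab[, wound_axis_x])
  axis_labels <- axis_labels[axis_labels > 0]
  if (length(axis_labels) == 0) {
    mask <- matrix(FALSE, nrow(frame), ncol(frame))
    return(structure(mask, flag = "empty", area_px2 = 0))
  }
  sizes <- vapply(axis_labels, function(l) sum(lab == l), numeric(1))
  mask <- lab == axis_labels[which.max(sizes)]
  # the sliding window elevates texture within its half-support of any cell;
  # the Otsu split lands partway up that ramp, so the low-texture region is
  # eroded by roughly half the window radius -- dilate that much back
  halo <- window %/% 4L
  if (halo > 0) {
    brush <- EBImage::makeBrush(2 * halo + 1, shape = "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0.5
  }
  structure(mask, flag = "ok", area_px2 = sum(mask))
}

# sliding-window standard deviation via integral images (O(1) per pixel)
local_sd <- function(x, window) {
  stopifnot(window >= 3)
  r <- window %/% 2
  n <- box_sum(matrix(1, nrow(x), ncol(x)), r)
  s1 <- box_sum(x, r)
  s2 <- box_sum(x^2, r)
  v <- s2 / n - (s1 / n)^2
  v[v < 0] <- 0
  sqrt(v)
}

box_sum <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  cs <- apply(x, 2, cumsum)
  cs <- rbind(0, cs)
  hi <- pmin(seq_len(nr) + r, nr) + 1L
  lo <- pmax(seq_len(nr) - r, 1L)
  colpart <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- t(apply(colpart, 1, cumsum))
  cs2 <- cbind(0, cs2)
  hic <- pmin(seq_len(nc) + r, nc) + 1L
  loc <- pmax(seq_len(nc) - r, 1L)
  cs2[, hic, drop = FALSE] - cs2[, loc, drop = FALSE]
}

#' Wound closure curve from a time-lapse stack
#'
#' Segments the wound in every frame and normalises the wound area to the
#' first frame: `closure% = 100 * (1 - A(t) / A(0))`.
#'
#' @param stack List of grayscale matrices (e.g. from [read_stack()] or
#'   [render_stack()]).
#' @param frame_interval_min Time between frames (min).
#' @param ... Passed to [segment_wound()].
#' @return A `closure_curve` tibble: `frame`, `time_h`, `area_px2`,
#'   `norm_area`, `closure_pct`, `flag`.
#' @export
closure_curve <- function(stack, frame_interval_min = 10, ...) {
  stopifnot(is.list(stack))
  if (length(stack) < 2) {
    abort("need at least 2 frames", class = "woundfield_domain_error")
  }
  areas <- purrr::map(stack, function(fr) {
    m <- segment_wound(fr, ...)
    list(area = attr(m, "area_px2"), flag = attr(m, "flag"))
  })
  a <- purrr::map_dbl(areas, "area")
  if (a[1] <= 0) {
    abort("frame-0 wound area is zero; cannot normalise",
          class = "woundfield_normalization_error")
  }
  out <- tibble(
    frame = seq_along(stack),
    time_h = (seq_along(stack) - 1) * frame_interval_min / 60,
    area_px2 = a,
    norm_area = a / a[1],
    closure_pct = 100 * (1 - a / a[1]),
    flag = purrr::map_chr(areas, "flag"))
  if (any(out$closure_pct < 0)) {
    out$flag[out$closure_pct < 0] <- "expansion"
  }
  class(out) <- c("closure_curve", class(out))
  out
}

#' Wound closure rate
#'
#' Ordinary least-squares slope of closure percent against time. The
#' default window runs from the first frame until the first frame at which
#' the wound is at least 95% closed (so a fully closed, flat tail does not
#' dilute the rate), or all frames if closure never reaches 95%.
#'
#' @param curve A [closure_curve()] tibble (columns `time_h`,
#'   `closure_pct`).
#' @param window Optional numeric `c(t_min_h, t_max_h)` fit window.
#' @return A `closure_fit`: list with `rate_pct_h`, `stderr`, `window_h`,
#'   `n` and the `lm` fit. `tidy()`/`glance()` methods are available.
#' @export
closure_rate <- function(curve, window = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("time_h", "closure_pct") %in% names(curve)))
  d <- curve
  if (is.null(window)) {
    closed <- which(d$closure_pct >= 95)
    if (length(closed) > 0) d <- d[seq_len(max(closed[1], 3)), ]
  } else {
    d <- d[d$time_h >= window[1] & d$time_h <= window[2], ]
  }
  if (nrow(d) < 3 || length(unique(d$time_h)) < 2) {
    abort("fit window contains fewer than 3 usable points",
          class = "woundfield_fit_error")
  }
  fit <- lm(closure_pct ~ time_h, data = d)
  # exact synthetic curves fit perfectly; the stderr warning is expected
  sm <- suppressWarnings(summary(fit))
  structure(
    list(rate_pct_h = unname(coef(fit)[2]),
         stderr = sm$coefficients[2, 2],
         window_h = range(d$time_h), n = nrow(d), fit = fit),
    class = "closure_fit")
}

#' @export
print.closure_fit <- function(x, ...) {
  cat(sprintf("<closure_fit: %.3g %%/h (se %.2g) over %.1f-%.1f h, n = %d>\n",
              x$rate_pct_h, x$stderr, x$window_h[1], x$window_h[2], x$n))
  invisible(x)
}

#' @method tidy closure_fit
#' @export
tidy.closure_fit <- function(x, ...) {
  tibble(term = c("intercept_pct", "rate_pct_h"),
         estimate = unname(coef(x$fit)),
         std.error = suppressWarnings(summary(x$fit))$coefficients[, 2])
}

#' @method glance closure_fit
#' @export
glance.closure_fit <- function(x, ...) {
  tibble(rate_pct_h = x$rate_pct_h, std.error = x$stderr,
         window_start_h = x$window_h[1], window_end_h = x$window_h[2],
         n = x$n, r.squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' Kymograph of the wound region of interest
#'
#' For each frame, a fixed number of evenly spaced horizontal line profiles
#' spanning the ROI are averaged into a single row; rows are stacked in
#' time order, so wound edges appear as converging fronts. Lines are placed
#' with half-spacing margins at the ROI top and bottom.
#'
#' @param stack List of grayscale matrices.
#' @param roi Numeric `c(x0, x1, y0, y1)` pixel bounds (inclusive);
#'   default the full frame.
#' @param n_lines Number of averaged lines (default 7).
#' @return A `kymograph` object: matrix `intensity` with `length(stack)`
#'   rows and `x1 - x0 + 1` columns, plus `roi`, `n_lines` and the line
#'   rows used.
#' @export
kymograph <- function(stack, roi = NULL, n_lines = 7) {
  stopifnot(is.list(stack), length(stack) >= 1)
  dm <- dim(stack[[1]])
  roi <- roi %||% c(1, dm[2], 1, dm[1])
  if (roi[1] < 1 || roi[2] > dm[2] || roi[3] < 1 || roi[4] > dm[1] ||
      roi[1] > roi[2] || roi[3] > roi[4]) {
    abort("ROI outside frame bounds", class = "woundfield_geometry_error")
  }
  roi_h <- roi[4] - roi[3] + 1
  if (n_lines > roi_h) {
    abort("n_lines exceeds ROI height", class = "woundfield_geometry_error")
  }
  # evenly spaced with half-spacing margins
  ys <- roi[3] - 1 + round((seq_len(n_lines) - 0.5) / n_lines * roi_h + 0.5)
  ys <- pmin(pmax(ys, roi[3]), roi[4])
  rows <- t(vapply(stack, function(fr) {
    colMeans(fr[ys, roi[1]:roi[2], drop = FALSE])
  }, numeric(roi[2] - roi[1] + 1)))
  structure(list(intensity = rows, roi = roi, n_lines = n_lines,
                 line_rows = ys),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph: %d time rows x %d positions, %d averaged lines>\n",
              nrow(x$intensity), ncol(x$intensity), x$n_lines))
  invisible(x)
}

#' Directedness statistics of cell tracks
#'
#' For each track, every frame-to-frame step contributes the cosine of its
#' displacement angle to the field axis (+x): `cos(theta) = dx /
#' sqrt(dx^2 + dy^2)`. Zero-displacement steps are skipped. +1 is directed
#' migration to the right (cathodal in the canonical orientation), -1 to
#' the left, 0 undirected. The per-cell summary reports the mean per-step
#' cosine (headline value), the net-displacement cosine, path length and
#' mean speed.
#'
#' @param tracks Data frame with columns `frame`, `cell_id`, `x`, `y`
#'   (e.g. from [read_tracks()] or [simulate_collective()]).
#' @param frame_interval_min Time between frames (min), for speeds.
#' @return A `track_stats` tibble (one row per cell): `cell_id`, `n_steps`,
#'   `mean_step_cos`, `net_cos`, `path_length_px`, `mean_speed_px_h`,
#'   `flagged` (all steps zero). Cohort statistics via [glance()].
#' @export
directedness <- function(tracks, frame_interval_min = 10) {
  stopifnot(is.data.frame(tracks),
            all(c("frame", "cell_id", "x", "y") %in% names(tracks)))
  dt_h <- frame_interval_min / 60
  out <- tracks |>
    arrange(.data$cell_id, .data$frame) |>
    group_by(.data$cell_id) |>
    summarise(
      n_steps = n() - 1L,
      dx = list(diff(.data$x)), dy = list(diff(.data$y)),
      net_dx = last(.data$x) - first(.data$x),
      net_dy = last(.data$y) - first(.data$y),
      .groups = "drop") |>
    filter(.data$n_steps >= 1L) |>
    mutate(
      step_len = purrr::map2(.data$dx, .data$dy, ~ sqrt(.x^2 + .y^2)),
      mean_step_cos = purrr::pmap_dbl(
        list(.data$dx, .data$step_len),
        function(dx, sl) {
          ok <- sl > 0
          if (!any(ok)) return(NA_real_)
          mean(dx[ok] / sl[ok])
        }),
      path_length_px = purrr::map_dbl(.data$step_len, sum),
      net_len = sqrt(.data$net_dx^2 + .data$net_dy^2),
      net_cos = ifelse(.data$net_len > 0, .data$net_dx / .data$net_len,
                       NA_real_),
      mean_speed_px_h = .data$path_length_px / (.data$n_steps * dt_h),
      flagged = is.na(.data$mean_step_cos)) |>
    select("cell_id", "n_steps", "mean_step_cos", "net_cos",
           "path_length_px", "mean_speed_px_h", "flagged")
  class(out) <- c("track_stats", class(out))
  out
}

#' Cohort-level directedness summary
#'
#' @param x A [directedness()] tibble.
#' @param ... Unused.
#' @return One-row tibble with cohort mean and sd of the per-cell mean step
#'   cosine and of the net-displacement cosine.
#' @method glance track_stats
#' @export
glance.track_stats <- function(x, ...) {
  ok <- !x$flagged
  tibble(n_cells = sum(ok),
         n_flagged = sum(!ok),
         directedness_mean = mean(x$mean_step_cos[ok]),
         directedness_sd = sd(x$mean_step_cos[ok]),
         net_cos_mean = mean(x$net_cos[ok], na.rm = TRUE),
         speed_mean_px_h = mean(x$mean_speed_px_h[ok]))
}
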