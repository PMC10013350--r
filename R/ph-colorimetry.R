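#' Mean hue of a masked image region
#'
#' Averages the R, G and B channels over the mask first and converts the
#' mean colour to a hue angle, mirroring colorimetric readout of
#' polyaniline-coated channels where the reported value is the hue of the
#' region's average colour (not the average of per-pixel hues).
#'
#' @param image Numeric array `height x width x 3` with values in `[0, 1]`
#'   (or 0-255; rescaled automatically).
#' @param mask Optional logical matrix selecting pixels; default whole frame.
#' @return Hue in degrees `[0, 360)`. An achromatic mean colour
#'   (max = min) returns 0 with attribute `achromatic = TRUE`.
#' @examples
#' img <- array(0, c(2, 2, 3)); img[, , 1] <- 1 # pure red
#' mean_hue(img) # 0
#' @export
mean_hue <- function(image, mask = NULL) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    abort("image must be a height x width x 3 RGB array",
          class = "woundfield_domain_error")
  }
  if (max(image, na.rm = TRUE) > 1) image <- image / 255
  if (is.null(mask)) mask <- matrix(TRUE, dim(image)[1], dim(image)[2])
  if (!any(mask)) {
    abort("mask selects no pixels", class = "woundfield_domain_error")
  }
  m <- vapply(1:3, function(k) mean(image[, , k][mask]), numeric(1))
  if (max(m) == min(m)) {
    return(structure(0, achromatic = TRUE))
  }
  h <- rgb2hsv(m[1], m[2], m[3], maxColorValue = 1)["h", 1] * 360
  structure(as.numeric(h), achromatic = FALSE)
}

#' Bi-dose-response (dual logistic) hue model
#'
#' Sum of two logistic transitions between a lower and an upper hue
#' asymptote, the standard sigmoidal form for indicators with two
#' protonation transitions:
#' `hue = A1 + (A2 - A1) * (p / (1 + 10^(h1 (logx01 - pH))) +
#'  (1 - p) / (1 + 10^(h2 (logx02 - pH))))`.
#'
#' @param ph pH value(s).
#' @param params Named list/vector with `A1`, `A2` (hue degrees), `logx01`,
#'   `logx02` (pH transition centres), `h1`, `h2` (slopes) and `p`
#'   (fraction in `[0, 1]`).
#' @return Hue in degrees.
#' @examples
#' bidose_response(7, default_ph_curve_params())
#' @export
bidose_response <- function(ph, params) {
  p <- params
  with(as.list(p), {
    A1 + (A2 - A1) * (p / (1 + 10^(h1 * (logx01 - ph))) +
                        (1 - p) / (1 + 10^(h2 * (logx02 - ph))))
  })
}

#' Default generating parameters for the synthetic hue-pH curve
#'
#' Spans the polyaniline green-to-purple hue range over the acid-to-base
#' transition.
#' @return Named list of bi-dose-response parameters.
#' @export
default_ph_curve_params <- function() {
  list(A1 = 80, A2 = 280, logx01 = 6, logx02 = 9.5, h1 = 1, h2 = 1, p = 0.5)
}

#' Fit a hue-pH calibration curve
#'
#' Nonlinear least-squares fit of the bi-dose-response model to measured
#' `(pH, hue)` calibration points (buffer series imaged on the indicator
#' coating). Initialisation is heuristic: asymptotes from the extreme hues,
#' transition centres from the 25% and 75% crossings, unit slopes and equal
#' weight. The fit is deterministic given the data.
#'
#' @param data Data frame with columns `ph` and `hue` (>= 8 distinct pH
#'   points).
#' @return A `ph_calibration` object: fitted `params`, `rmse_deg`,
#'   `domain` (fitted pH range), `n`, and the underlying `nls` fit.
#' @export
fit_calibration <- function(data) {
  stopifnot(is.data.frame(data), all(c("ph", "hue") %in% names(data)))
  data <- tibble(ph = as.numeric(data$ph), hue = as.numeric(data$hue))
  if (length(unique(data$ph)) < 8) {
    abort("need at least 8 distinct pH calibration points",
          class = "woundfield_fit_error")
  }
  o <- data[order(data$ph), ]
  hue_lo <- mean(o$hue[seq_len(min(2, nrow(o)))])
  hue_hi <- mean(o$hue[seq(nrow(o) - 1, nrow(o))])
  dh <- hue_hi - hue_lo
  cross <- function(f) {
    target <- hue_lo + f * dh
    i <- which(o$hue >= target)[1]
    if (is.na(i) || i == 1) return(stats::quantile(o$ph, f, names = FALSE))
    approx(o$hue[c(i - 1, i)], o$ph[c(i - 1, i)], xout = target)$y
  }
  start <- list(A1 = hue_lo, A2 = hue_hi,
                logx01 = cross(0.25), logx02 = cross(0.75),
                h1 = 1, h2 = 1, p = 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      hue ~ A1 + (A2 - A1) * (p / (1 + 10^(h1 * (logx01 - ph))) +
                                (1 - p) / (1 + 10^(h2 * (logx02 - ph)))),
      data = o, start = start,
      lower = c(A1 = -360, A2 = -360, logx01 = min(o$ph) - 2,
                logx02 = min(o$ph) - 2, h1 = 0.05, h2 = 0.05, p = 0),
      upper = c(A1 = 720, A2 = 720, logx01 = max(o$ph) + 2,
                logx02 = max(o$ph) + 2, h1 = 20, h2 = 20, p = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("calibration fit failed to converge: ", conditionMessage(e)),
            class = "woundfield_fit_error")
    })
  params <- as.list(coef(fit))
  # order the transitions so logx01 <= logx02
  if (params$logx01 > params$logx02) {
    params <- within(params, {
      tmp <- logx01; logx01 <- logx02; logx02 <- tmp
      tmp <- h1; h1 <- h2; h2 <- tmp
      p <- 1 - p
      rm(tmp)
    })
  }
  rmse <- sqrt(mean(stats::residuals(fit)^2))
  structure(
    list(params = params, rmse_deg = rmse,
         domain = range(o$ph), n = nrow(o), fit = fit, data = o),
    class = "ph_calibration")
}

#' @export
print.ph_calibration <- function(x, ...) {
  p <- x$params
  cat("<ph_calibration: bi-dose-response hue(pH)>\n")
  cat(sprintf("  A1 = %.1f, A2 = %.1f deg; centres %.2f / %.2f; slopes %.2f / %.2f; p = %.2f\n",
              p$A1, p$A2, p$logx01, p$logx02, p$h1, p$h2, p$p))
  cat(sprintf("  RMSE %.3g deg over %d points, domain pH %.2f-%.2f\n",
              x$rmse_deg, x$n, x$domain[1], x$domain[2]))
  invisible(x)
}

#' @method tidy ph_calibration
#' @export
tidy.ph_calibration <- function(x, ...) {
  tibble(term = names(x$params), estimate = unlist(x$params))
}

#' @method glance ph_calibration
#' @export
glance.ph_calibration <- function(x, ...) {
  tibble(rmse_deg = x$rmse_deg, n = x$n,
         ph_min = x$domain[1], ph_max = x$domain[2],
         monotone = is_monotone_curve(x))
}

is_monotone_curve <- function(curve, n = 512) {
  ph <- seq(curve$domain[1], curve$domain[2], length.out = n)
  d <- diff(bidose_response(ph, curve$params))
  all(d >= -1e-9) || all(d <= 1e-9)
}

#' Invert a hue to its pH estimate
#'
#' Numeric root of `bidose_response(pH) = hue` by bisection on the
#' calibration domain. The curve must be monotone on its domain. Hues
#' outside the calibrated hue range are clamped to the nearest domain edge,
#' returned with a warning and flagged.
#'
#' @param hue Hue value(s) in degrees.
#' @param curve A [fit_calibration()] object (or a list with `params` and
#'   `domain`).
#' @param tol pH tolerance of the root search.
#' @return pH estimate(s); attribute `extrapolated` is a logical vector
#'   flagging clamped values.
#' @export
hue_to_ph <- function(hue, curve, tol = 1e-4) {
  if (!is_monotone_curve(curve)) {
    abort("calibration curve is not monotone on its domain; cannot invert",
          class = "woundfield_domain_error")
  }
  lo <- curve$domain[1]; hi <- curve$domain[2]
  f_lo <- bidose_response(lo, curve$params)
  f_hi <- bidose_response(hi, curve$params)
  incr <- f_hi >= f_lo
  rng <- sort(c(f_lo, f_hi))
  flag <- hue < rng[1] | hue > rng[2]
  if (any(flag)) {
    warn(sprintf("%d hue value(s) outside calibrated range [%.1f, %.1f]; clamped",
                 sum(flag), rng[1], rng[2]))
  }
  hue_cl <- pmin(pmax(hue, rng[1]), rng[2])
  ph <- vapply(hue_cl, function(hh) {
    if (abs(hh - f_lo) < 1e-12) return(lo)
    if (abs(hh - f_hi) < 1e-12) return(hi)
    uniroot(function(x) bidose_response(x, curve$params) - hh,
            lower = lo, upper = hi, tol = tol)$root
  }, numeric(1))
  structure(ph, extrapolated = flag)
}

#' Region-of-interest pH traces from a colour time-lapse
#'
#' Converts each frame's mean ROI colour to hue and inverts it through the
#' calibration curve, producing one pH trace per ROI. A combined
#' `wound_mean` trace (mean of ROIs flagged `in_channel`) mirrors the usual
#' reporting of the wound-zone pH as the average of the before/centre/after
#' locations.
#'
#' @param stack List of RGB arrays (`height x width x 3`), e.g. from
#'   [read_stack()].
#' @param rois Data frame with columns `label`, `x0`, `x1`, `y0`, `y1`
#'   (pixel bounds, inclusive) and optional logical `in_channel`.
#' @param curve A [fit_calibration()] object.
#' @param frame_interval_min Time between frames (min).
#' @return Tibble with `roi`, `frame`, `time_h`, `hue_deg`, `ph`,
#'   `extrapolated`.
#' @export
roi_ph_traces <- function(stack, rois, curve, frame_interval_min = 10) {
  stopifnot(is.list(stack), length(stack) >= 1, is.data.frame(rois))
  if (nrow(rois) == 0) {
    return(tibble(roi = character(), frame = integer(), time_h = numeric(),
                  hue_deg = numeric(), ph = numeric(), extrapolated = logical()))
  }
  dm <- dim(stack[[1]])
  bad <- rois$x0 < 1 | rois$y0 < 1 | rois$x1 > dm[2] | rois$y1 > dm[1] |
    rois$x0 > rois$x1 | rois$y0 > rois$y1
  if (any(bad)) {
    abort(sprintf("ROI(s) %s outside image bounds",
                  paste(rois$label[bad], collapse = ", ")),
          class = "woundfield_geometry_error")
  }
  out <- purrr::map_dfr(seq_along(stack), function(f) {
    img <- stack[[f]]
    purrr::map_dfr(seq_len(nrow(rois)), function(i) {
      r <- rois[i, ]
      mask <- matrix(FALSE, dm[1], dm[2])
      mask[r$y0:r$y1, r$x0:r$x1] <- TRUE
      hh <- suppressWarnings(mean_hue(img, mask))
      est <- suppressWarnings(hue_to_ph(as.numeric(hh), curve))
      flag <- isTRUE(attr(est, "extrapolated"))
      tibble(roi = r$label, frame = f,
             time_h = (f - 1) * frame_interval_min / 60,
             hue_deg = as.numeric(hh), ph = as.numeric(est),
             extrapolated = flag)
    })
  })
  if (!is.null(rois$in_channel) && any(rois$in_channel)) {
    inch <- rois$label[rois$in_channel]
    wound <- out |>
      filter(.data$roi %in% inch) |>
      group_by(.data$frame, .data$time_h) |>
      summarise(hue_deg = mean(.data$hue_deg), ph = mean(.data$ph),
                extrapolated = any(.data$extrapolated), .groups = "drop") |>
      mutate(roi = "wound_mean")
    out <- bind_rows(out, wound[, names(out)])
  }
  class(out) <- c("ph_traces", class(out))
  out
}
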