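#' Parameters for the collective-migration simulator
#'
#' The simulator is a persistent random walk with drift: two confluent cell
#' sheets flank a central cell-free gap; each cell blends its previous
#' heading, a random turn and a field-bias unit vector, while the sheet
#' fronts advance at the speed implied by the prescribed closure rate
#' (free-edge cells receive a gap-ward protrusion so unstimulated controls
#' also close). It is a ground-truth generator for the analysis pipeline,
#' not a mechanistic model of electrotaxis.
#'
#' @param domain_px Square domain side (px).
#' @param gap_px Initial wound-gap width (px).
#' @param cell_radius_px Cell radius (px).
#' @param spacing_factor Initial lattice spacing in units of cell diameter.
#' @param persistence Heading persistence in `[0, 1)`.
#' @param speed_px_h Intrinsic motile speed (px/h).
#' @param bias Field-bias weight `beta >= 0`, or a signed per-step vector
#'   (see [relay_bias_schedule()]); positive drives +x (cathodal).
#' @param motility Motility factor in `(0, 1]` (inhibited scenarios scale
#'   the intrinsic speed).
#' @param closure_rate_pct_h True closure rate of the gap (%/h).
#' @param protrusion_px_h Gap-ward protrusion speed of free-edge cells.
#' @param frame_interval_min Frame interval (min).
#' @param duration_h Simulated duration (h). A 12 h run at 10 min yields 72
#'   frames at t = 0, 10, ..., 710 min.
#' @param seed RNG seed (mandatory; all generators are seed-deterministic).
#' @return A `sim_params` list.
#' @export
sim_params <- function(domain_px = 512, gap_px = 180, cell_radius_px = 8,
                       spacing_factor = 1.05, persistence = 0.6,
                       speed_px_h = 12, bias = 0, motility = 1,
                       closure_rate_pct_h = 3.5, protrusion_px_h = 2,
                       frame_interval_min = 10, duration_h = 12,
                       seed = 1) {
  stopifnot(domain_px > 4 * cell_radius_px, gap_px > 0,
            gap_px < domain_px, cell_radius_px > 0,
            persistence >= 0, persistence < 1,
            speed_px_h >= 0, all(is.finite(bias)),
            motility > 0, motility <= 1,
            closure_rate_pct_h >= 0, frame_interval_min > 0,
            duration_h >= 0, is.finite(seed))
  structure(as.list(environment()), class = "sim_params")
}

#' Signed relay bias schedule
#'
#' Builds a per-step signed bias vector that flips sign on the relay
#' period, emulating the alternating-anode pseudo-converging drive.
#'
#' @param beta Bias magnitude.
#' @param n_steps Number of simulation steps.
#' @param frame_interval_min Step length (min).
#' @param relay_period_min Relay half-period (min).
#' @return Numeric vector of length `n_steps`.
#' @export
relay_bias_schedule <- function(beta, n_steps, frame_interval_min = 10,
                                relay_period_min = 30) {
  t_min <- (seq_len(n_steps) - 1) * frame_interval_min
  phase <- floor(t_min / relay_period_min)
  beta * ifelse(phase %% 2 == 0, 1, -1)
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate collective wound closure with ground truth
#'
#' @param params A [sim_params()] object.
#' @return A `wound_sim` object: `tracks` tibble (`frame`, `cell_id`, `x`,
#'   `y`), `fronts` tibble (`frame`, `time_h`, `left_px`, `right_px`,
#'   `area_px2`, `closure_pct`), the true closure rate, and the parameters.
#' @export
simulate_collective <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  W <- p$domain_px; H <- p$domain_px
  r <- p$cell_radius_px
  gap0 <- p$gap_px
  L0 <- (W - gap0) / 2
  R0 <- L0 + gap0
  dt_h <- p$frame_interval_min / 60
  n_frames <- max(2L, floor(p$duration_h * 60 / p$frame_interval_min + 1e-9))
  v <- p$closure_rate_pct_h * gap0 / 200  # front speed px/h, per side

  d <- 2 * r * p$spacing_factor
  grid_pts <- function(x_lo, x_hi) {
    if (x_hi - r < x_lo + r || H < 2 * r) {
      abort("sheet too narrow to seed cells; domain overcrowded or too small",
            class = "woundfield_packing_error")
    }
    expand.grid(x = seq(x_lo + r, x_hi - r, by = d),
                y = seq(r, H - r, by = d))
  }
  bias_vec <- if (length(p$bias) == 1) {
    rep(p$bias, n_frames - 1)
  } else if (length(p$bias) == n_frames - 1) {
    p$bias
  } else {
    abort("bias must be scalar or length n_frames - 1",
          class = "woundfield_domain_error")
  }

  with_local_seed(p$seed, {
    left <- grid_pts(0, L0)
    right <- grid_pts(R0, W)
    pos <- rbind(as.matrix(left), as.matrix(right))
    pos <- pos + matrix(runif(length(pos), -0.3 * r, 0.3 * r), ncol = 2)
    n <- nrow(pos)
    sheet <- rep(c(-1, 1), c(nrow(left), nrow(right)))  # -1 left, +1 right
    ang <- runif(n, 0, 2 * pi)
    head_x <- cos(ang); head_y <- sin(ang)

    tracks <- vector("list", n_frames)
    tracks[[1]] <- tibble(frame = 1L, cell_id = seq_len(n),
                          x = pos[, 1], y = pos[, 2])
    front <- matrix(NA_real_, n_frames, 2)
    front[1, ] <- c(L0, R0)

    step_len <- p$speed_px_h * p$motility * dt_h
    for (f in 2:n_frames) {
      t_h <- (f - 1) * dt_h
      Lt <- L0 + v * t_h; Rt <- R0 - v * t_h
      if (Lt >= Rt) { Lt <- Rt <- (L0 + R0) / 2 }
      beta <- bias_vec[f - 1]

      ta <- runif(n, 0, 2 * pi)
      dirx <- p$persistence * head_x + (1 - p$persistence) * cos(ta) + beta
      diry <- p$persistence * head_y + (1 - p$persistence) * sin(ta)
      nrm <- sqrt(dirx^2 + diry^2)
      nrm[nrm == 0] <- 1
      dirx <- dirx / nrm; diry <- diry / nrm
      head_x <- dirx; head_y <- diry

      drift <- ifelse(sheet < 0, v, -v) * dt_h
      # free-edge protrusion: cells near their sheet's front creep gap-ward
      front_x <- ifelse(sheet < 0, Lt, Rt)
      near_front <- abs(pos[, 1] - front_x) < 3 * r
      prot <- ifelse(near_front, sign(front_x - pos[, 1]) *
                       p$protrusion_px_h * p$motility * dt_h, 0)

      pos[, 1] <- pos[, 1] + dirx * step_len + drift + prot
      pos[, 2] <- pos[, 2] + diry * step_len

      # pairwise exclusion: push overlapping neighbours apart (one pass)
      dmat <- as.matrix(stats::dist(pos))
      diag(dmat) <- Inf
      ov <- which(dmat < 2 * r, arr.ind = TRUE)
      ov <- ov[ov[, 1] < ov[, 2], , drop = FALSE]
      if (nrow(ov) > 0) {
        for (k in seq_len(nrow(ov))) {
          i <- ov[k, 1]; j <- ov[k, 2]
          dx <- pos[j, 1] - pos[i, 1]; dy <- pos[j, 2] - pos[i, 2]
          dd <- sqrt(dx^2 + dy^2)
          if (dd < 1e-9) { dx <- 1; dy <- 0; dd <- 1 }
          push <- (2 * r - dd) / 2
          pos[i, 1] <- pos[i, 1] - push * dx / dd
          pos[i, 2] <- pos[i, 2] - push * dy / dd
          pos[j, 1] <- pos[j, 1] + push * dx / dd
          pos[j, 2] <- pos[j, 2] + push * dy / dd
        }
      }

      # cells stay behind their sheet's front and inside the domain
      isL <- sheet < 0
      pos[isL, 1] <- pmin(pos[isL, 1], Lt - r)
      pos[!isL, 1] <- pmax(pos[!isL, 1], Rt + r)
      pos[, 1] <- pmin(pmax(pos[, 1], r), W - r)
      pos[, 2] <- pmin(pmax(pos[, 2], r), H - r)

      front[f, ] <- c(Lt, Rt)
      tracks[[f]] <- tibble(frame = f, cell_id = seq_len(n),
                            x = pos[, 1], y = pos[, 2])
    }

    fronts <- tibble(
      frame = seq_len(n_frames),
      time_h = (seq_len(n_frames) - 1) * dt_h,
      left_px = front[, 1], right_px = front[, 2],
      area_px2 = (front[, 2] - front[, 1]) * H,
      closure_pct = 100 * (1 - (front[, 2] - front[, 1]) / gap0))
    structure(
      list(params = p,
           tracks = bind_rows(tracks),
           fronts = fronts,
           sheet = sheet,
           true_rate_pct_h = p$closure_rate_pct_h,
           domain = c(W = W, H = H)),
      class = "wound_sim")
  })
}

#' @export
print.wound_sim <- function(x, ...) {
  cat(sprintf("<wound_sim: %d cells x %d frames, %d px domain>\n",
              length(unique(x$tracks$cell_id)), max(x$tracks$frame),
              x$params$domain_px))
  cat(sprintf("  true closure rate %.2g %%/h, bias %s, seed %g\n",
              x$true_rate_pct_h,
              paste(signif(range(x$params$bias), 2), collapse = ".."),
              x$params$seed))
  invisible(x)
}

#' True wound mask of a simulated frame
#'
#' @param sim A [simulate_collective()] result.
#' @param frame Frame index.
#' @return Logical matrix (rows = y): the cell-free band between the sheet
#'   fronts.
#' @export
true_wound_mask <- function(sim, frame) {
  stopifnot(inherits(sim, "wound_sim"))
  fr <- sim$fronts[sim$fronts$frame == frame, ]
  if (nrow(fr) != 1) abort("no such frame", class = "woundfield_domain_error")
  W <- sim$domain["W"]; H <- sim$domain["H"]
  xs <- seq_len(W)
  band <- xs > fr$left_px & xs < fr$right_px
  matrix(band, nrow = H, ncol = W, byrow = TRUE)
}

#' Render a simulated wound as a phase-contrast-like image stack
#'
#' Cells are drawn as textured discs (bright rim, speckled interior) over a
#' smooth shaded background with additive Gaussian noise, so the cell-free
#' gap is the only low-texture region. Rendering is deterministic given the
#' simulation seed.
#'
#' @param sim A [simulate_collective()] result.
#' @param bg_level Background intensity in `[0, 1]`.
#' @param bg_noise_sd Additive Gaussian noise sd.
#' @param cell_level Cell interior mean intensity.
#' @param speckle Half-range of the uniform interior speckle.
#' @param rim_level Rim intensity.
#' @return List of grayscale matrices in `[0, 1]`, one per frame.
#' @export
render_stack <- function(sim, bg_level = 0.45, bg_noise_sd = 0.008,
                         cell_level = 0.55, speckle = 0.18,
                         rim_level = 0.85) {
  stopifnot(inherits(sim, "wound_sim"))
  W <- unname(sim$domain["W"]); H <- unname(sim$domain["H"])
  r <- sim$params$cell_radius_px
  # precompute disc pixel offsets
  off <- expand.grid(dy = -r:r, dx = -r:r)
  dd <- sqrt(off$dx^2 + off$dy^2)
  interior <- off[dd <= r - 1.5, ]
  rim <- off[dd > r - 1.5 & dd <= r, ]
  shade <- outer(seq_len(H), seq_len(W),
                 function(i, j) 0.02 * sin(2 * pi * j / W))
  n_frames <- nrow(sim$fronts)
  with_local_seed(sim$params$seed + 7919L, {
    lapply(seq_len(n_frames), function(f) {
      img <- bg_level + shade + matrix(rnorm(H * W, 0, bg_noise_sd), H, W)
      tr <- sim$tracks[sim$tracks$frame == f, ]
      for (i in seq_len(nrow(tr))) {
        cx <- round(tr$x[i]); cy <- round(tr$y[i])
        iy <- cy + interior$dy; ix <- cx + interior$dx
        ok <- iy >= 1 & iy <= H & ix >= 1 & ix <= W
        img[cbind(iy[ok], ix[ok])] <-
          cell_level + runif(sum(ok), -speckle, speckle)
        ry <- cy + rim$dy; rx <- cx + rim$dx
        ok <- ry >= 1 & ry <= H & rx >= 1 & rx <= W
        img[cbind(ry[ok], rx[ok])] <- rim_level
      }
      pmin(pmax(img, 0), 1)
    })
  })
}

# full-precision HSV -> RGB (hue in degrees); avoids 8-bit colour rounding
hsv_to_rgb_float <- function(h_deg, s, v) {
  hp <- (h_deg / 60) %% 6
  c <- v * s
  x <- c * (1 - abs(hp %% 2 - 1))
  m <- v - c
  r <- g <- b <- numeric(length(hp))
  k <- floor(hp)
  r <- ifelse(k %in% c(0, 5), c, ifelse(k %in% c(1, 4), x, 0))
  g <- ifelse(k %in% c(1, 2), c, ifelse(k %in% c(0, 3), x, 0))
  b <- ifelse(k %in% c(3, 4), c, ifelse(k %in% c(2, 5), x, 0))
  cbind(r + m, g + m, b + m)
}

#' Construct a pH calibration curve from known parameters
#'
#' Builds a `ph_calibration` object directly from bi-dose-response
#' parameters (no fitting), for forward-simulating colour stacks or for
#' reusing an externally fitted curve.
#'
#' @param params Bi-dose-response parameters (see [bidose_response()]).
#' @param domain Length-2 pH calibration domain.
#' @return A `ph_calibration` object.
#' @export
ph_curve <- function(params = default_ph_curve_params(),
                     domain = c(2.7, 11.3)) {
  structure(list(params = params, rmse_deg = 0, domain = sort(domain),
                 n = 0L, fit = NULL, data = NULL),
            class = "ph_calibration")
}

#' Synthesise a pH-reporting colour image stack
#'
#' Forward model of an indicator-coated channel: each pixel's hue follows
#' the bi-dose-response curve at the local pH, with Gaussian hue noise and
#' fixed saturation/value.
#'
#' @param ph_fields List of numeric matrices (pH per pixel), one per frame.
#' @param curve A [ph_curve()] or [fit_calibration()] object.
#' @param noise_sigma_deg Hue noise sd (degrees).
#' @param saturation,value Fixed HSV saturation and value.
#' @param seed RNG seed.
#' @return List of RGB arrays (`height x width x 3`, values in `[0, 1]`).
#' @export
synthetic_ph_stack <- function(ph_fields, curve = ph_curve(),
                               noise_sigma_deg = 2, saturation = 0.6,
                               value = 0.85, seed = 1) {
  stopifnot(is.list(ph_fields), length(ph_fields) >= 1)
  rng <- range(unlist(lapply(ph_fields, range)))
  if (rng[1] < curve$domain[1] - 1e-9 || rng[2] > curve$domain[2] + 1e-9) {
    abort(sprintf("pH values [%.2f, %.2f] outside curve domain [%.2f, %.2f]",
                  rng[1], rng[2], curve$domain[1], curve$domain[2]),
          class = "woundfield_domain_error")
  }
  with_local_seed(seed, {
    lapply(ph_fields, function(ph) {
      hue <- bidose_response(ph, curve$params) +
        rnorm(length(ph), 0, noise_sigma_deg)
      rgb <- hsv_to_rgb_float(hue %% 360, saturation, value)
      arr <- array(0, c(nrow(ph), ncol(ph), 3))
      arr[, , 1] <- matrix(rgb[, 1], nrow(ph), ncol(ph))
      arr[, , 2] <- matrix(rgb[, 2], nrow(ph), ncol(ph))
      arr[, , 3] <- matrix(rgb[, 3], nrow(ph), ncol(ph))
      arr
    })
  })
}
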