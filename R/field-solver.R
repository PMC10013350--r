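#' Electrode configuration for galvanostatic stimulation
#'
#' Describes which reservoirs carry electrodes, the stimulation scheme and
#' the injected current. Two schemes are supported: `uni_directional`
#' (one anode, one cathode, constant current) and `pseudo_converging`
#' (two anodes flanking the wound and one cathode, with a relay activating
#' exactly one anode at a time so the idle anode can passively recharge
#' from solution).
#'
#' @param scheme `"uni_directional"` or `"pseudo_converging"`.
#' @param current_uA Injected current magnitude (uA). Defaults follow the
#'   calibrated protocol currents: 25 uA uni-directional, 20 uA
#'   pseudo-converging.
#' @param anodes Character vector of reservoir roles acting as anodes.
#' @param cathode Reservoir role acting as cathode.
#' @param relay_period_min Anode relay half-period (min), pseudo-converging
#'   only.
#' @return An `electrode_config` object.
#' @examples
#' electrode_config("uni_directional")
#' electrode_config("pseudo_converging", relay_period_min = 30)
#' @export
electrode_config <- function(scheme = c("uni_directional", "pseudo_converging"),
                             current_uA = NULL,
                             anodes = NULL,
                             cathode = "cathode",
                             relay_period_min = 30) {
  scheme <- match.arg(scheme)
  if (is.null(current_uA)) {
    current_uA <- if (scheme == "uni_directional") 25 else 20
  }
  if (!is.finite(current_uA) || current_uA <= 0) {
    abort("current_uA must be positive", class = "woundfield_config_error")
  }
  if (is.null(anodes)) {
    anodes <- if (scheme == "uni_directional") "anode" else c("anode", "anode_2")
  }
  n_anodes_needed <- if (scheme == "uni_directional") 1L else 2L
  if (length(anodes) != n_anodes_needed) {
    abort(sprintf("%s scheme needs %d anode(s)", scheme, n_anodes_needed),
          class = "woundfield_config_error")
  }
  if (scheme == "pseudo_converging" &&
      (!is.finite(relay_period_min) || relay_period_min <= 0)) {
    abort("relay_period_min must be positive", class = "woundfield_config_error")
  }
  structure(
    list(scheme = scheme, current_uA = current_uA, anodes = anodes,
         cathode = cathode, relay_period_min = relay_period_min),
    class = "electrode_config")
}

#' @export
print.electrode_config <- function(x, ...) {
  cat(sprintf("<electrode_config: %s, %g uA, anodes [%s] -> cathode [%s]>\n",
              x$scheme, x$current_uA, paste(x$anodes, collapse = ", "),
              x$cathode))
  if (x$scheme == "pseudo_converging") {
    cat(sprintf("  relay period %g min\n", x$relay_period_min))
  }
  invisible(x)
}

# linear index helpers for the [ny, nx] grid matrices
grid_neighbour_edges <- function(conducting) {
  ny <- nrow(conducting); nx <- ncol(conducting)
  idx <- matrix(seq_len(ny * nx), ny, nx)
  # horizontal edges
  hm <- conducting[, -nx, drop = FALSE] & conducting[, -1, drop = FALSE]
  e_h <- cbind(idx[, -nx, drop = FALSE][hm], idx[, -1, drop = FALSE][hm])
  # vertical edges
  vm <- conducting[-ny, , drop = FALSE] & conducting[-1, , drop = FALSE]
  e_v <- cbind(idx[-ny, , drop = FALSE][vm], idx[-1, , drop = FALSE][vm])
  rbind(e_h, e_v)
}

check_connected <- function(map, roles) {
  lab <- EBImage::bwlabel(map$conducting * 1)
  comp <- vapply(roles, function(r) {
    fp <- map$electrodes[[r]]
    if (is.null(fp) || !any(fp & map$conducting)) {
      abort(sprintf("no conducting electrode footprint for role '%s'", r),
            class = "woundfield_connectivity_error")
    }
    as.integer(stats::median(lab[fp & map$conducting]))
  }, integer(1))
  if (length(unique(comp)) > 1) {
    abort("electrode footprints lie in disconnected conducting regions",
          class = "woundfield_connectivity_error")
  }
  invisible(TRUE)
}

#' Solve the quasi-static electric field on a conductivity map
#'
#' Solves steady current conservation `div(sigma*h grad V) = 0` with a
#' five-point finite-difference stencil on the sheet-conductance grid.
#' Channel walls are insulating (zero flux); the injected current is spread
#' uniformly over the active anode footprint and withdrawn uniformly over
#' the cathode footprint; the gauge is fixed by pinning one cathode cell at
#' 0 V. Interface conductances between neighbouring cells use the harmonic
#' mean. The sparse symmetric positive-definite system is solved directly,
#' so the result is deterministic and the relative residual is at
#' floating-point level (far below the 1e-8 contract).
#'
#' @param map A [rasterize_layout()] conductivity map.
#' @param config An [electrode_config()].
#' @param state Which anode is active: a role name, or `"all"` to split the
#'   current equally over the configured anodes (a true simultaneously
#'   converging drive, used for dead-zone characterisation).
#' @param current_uA Optional current override (uA).
#' @return A `field_solution`: matrices `V_mV` (potential, mV), `Ex`, `Ey`,
#'   `E_mag` (mV/mm), `Jx`, `Jy` (A/m^2), `p_areal_W_m2` (areal joule
#'   dissipation), plus `current_uA`, `R_kohm`, and the active `state`.
#' @examples
#' cm <- rasterize_layout(chip_layout("straight"), spacing_mm = 0.1)
#' sol <- solve_field(cm, electrode_config("uni_directional"))
#' sol$R_kohm
#' @export
solve_field <- function(map, config, state = NULL, current_uA = NULL) {
  stopifnot(inherits(map, "conductivity_map"), inherits(config, "electrode_config"))
  I_uA <- current_uA %||% config$current_uA
  state <- state %||% config$anodes[1]
  active <- if (identical(state, "all")) config$anodes else state
  if (!identical(state, "all") && length(active) != 1) {
    abort("exactly one active anode required per state",
          class = "woundfield_config_error")
  }
  roles <- c(active, config$cathode)
  check_connected(map, roles)

  ny <- length(map$y); nx <- length(map$x)
  cond <- map$conducting
  g <- map$g_sheet
  edges <- grid_neighbour_edges(cond)
  ge <- 2 / (1 / g[edges[, 1]] + 1 / g[edges[, 2]])  # harmonic mean, S

  cells <- which(cond)
  unknown_of <- integer(ny * nx)
  unknown_of[cells] <- seq_along(cells)
  n <- length(cells)

  i1 <- unknown_of[edges[, 1]]; i2 <- unknown_of[edges[, 2]]
  L <- sparseMatrix(i = c(i1, i2, i1, i2), j = c(i1, i2, i2, i1),
                    x = c(ge, ge, -ge, -ge), dims = c(n, n))

  I_A <- I_uA * 1e-6
  b <- numeric(n)
  for (a in active) {
    fp <- which(map$electrodes[[a]] & cond)
    b[unknown_of[fp]] <- b[unknown_of[fp]] + (I_A / length(active)) / length(fp)
  }
  cfp <- which(map$electrodes[[config$cathode]] & cond)
  b[unknown_of[cfp]] <- b[unknown_of[cfp]] - I_A / length(cfp)

  # gauge: pin the first cathode cell to 0 V
  pin <- unknown_of[cfp[1]]
  keep <- setdiff(seq_len(n), pin)
  V <- numeric(n)
  if (I_A != 0) {
    Lk <- L[keep, keep, drop = FALSE]
    Vk <- as.numeric(Matrix::solve(Lk, b[keep]))
    V[keep] <- Vk
  }

  Vfull <- matrix(NA_real_, ny, nx)
  Vfull[cells] <- V

  dx_m <- map$spacing_mm * 1e-3
  grad <- masked_gradient(Vfull, cond, dx_m)   # V/m
  Ex <- -grad$gx; Ey <- -grad$gy
  E_mag <- sqrt(Ex^2 + Ey^2)
  sig <- map$sigma_S_m
  Jx <- sig * Ex; Jy <- sig * Ey

  # edge-based dissipation, split between endpoint cells: exactly I^2 R in total
  dV <- V[i1] - V[i2]
  pe <- ge * dV^2  # W per edge
  p_cell <- numeric(ny * nx)
  add1 <- tapply(pe / 2, edges[, 1], sum)
  add2 <- tapply(pe / 2, edges[, 2], sum)
  p_cell[as.integer(names(add1))] <- p_cell[as.integer(names(add1))] + add1
  p_cell[as.integer(names(add2))] <- p_cell[as.integer(names(add2))] + add2
  p_areal <- matrix(p_cell / dx_m^2, ny, nx)

  mean_fp <- function(role) mean(Vfull[map$electrodes[[role]] & cond])
  Va <- mean(vapply(active, mean_fp, numeric(1)))
  Vc <- mean_fp(config$cathode)
  R_kohm <- if (I_A > 0) (Va - Vc) / I_A / 1e3 else NA_real_

  structure(
    list(map = map, config = config, state = state,
         V_mV = Vfull * 1e3,
         Ex = Ex, Ey = Ey, E_mag = E_mag,   # V/m == mV/mm
         Jx = Jx, Jy = Jy,
         p_areal_W_m2 = p_areal,
         current_uA = I_uA, R_kohm = R_kohm),
    class = "field_solution")
}

masked_gradient <- function(Vfull, cond, dx) {
  ny <- nrow(Vfull); nx <- ncol(Vfull)
  gx <- matrix(0, ny, nx); gy <- matrix(0, ny, nx)
  Vp <- Vfull; Vp[!cond] <- NA
  shift <- function(m, dr, dc) {
    out <- matrix(NA_real_, ny, nx)
    rs <- seq_len(ny) - dr; cs <- seq_len(nx) - dc
    ok_r <- rs >= 1 & rs <= ny; ok_c <- cs >= 1 & cs <= nx
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  right <- shift(Vp, 0, -1); left <- shift(Vp, 0, 1)
  up <- shift(Vp, -1, 0); down <- shift(Vp, 1, 0)  # up = +y (larger row index)
  ctr <- function(plus, minus, h) {
    g <- (plus - minus) / (2 * h)
    g1 <- (plus - Vp) / h; g2 <- (Vp - minus) / h
    g[is.na(g)] <- g1[is.na(g)]
    g[is.na(g)] <- g2[is.na(g)]
    g[is.na(g)] <- 0
    g
  }
  gx <- ctr(right, left, dx)
  gy <- ctr(up, down, dx)
  gx[!cond] <- 0; gy[!cond] <- 0
  list(gx = gx, gy = gy)
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution: %s, state '%s', I = %g uA>\n",
              x$map$layout$layout_kind, paste(x$state, collapse = "+"),
              x$current_uA))
  wc <- wound_center_value(x)
  cat(sprintf("  R = %.3g kOhm, |E| at wound centre = %.4g mV/mm\n",
              x$R_kohm, wc))
  invisible(x)
}

wound_centroid_cell <- function(map) {
  w <- which(map$wound & map$conducting, arr.ind = TRUE)
  if (nrow(w) == 0) {
    abort("wound zone lies outside the conducting region",
          class = "woundfield_geometry_error")
  }
  cx <- mean(map$x[w[, 2]]); cy <- mean(map$y[w[, 1]])
  iy <- which.min(abs(map$y - cy)); ix <- which.min(abs(map$x - cx))
  # snap to nearest conducting cell if the centroid cell itself is not
  if (!map$conducting[iy, ix]) {
    d2 <- (w[, 2] - ix)^2 + (w[, 1] - iy)^2
    iy <- w[which.min(d2), 1]; ix <- w[which.min(d2), 2]
  }
  c(iy = iy, ix = ix)
}

wound_center_value <- function(sol) {
  cc <- wound_centroid_cell(sol$map)
  sol$E_mag[cc["iy"], cc["ix"]]
}

#' Electric-field profiles through the wound centre
#'
#' Extracts the field-magnitude profile along two orthogonal lines through
#' the wound-zone centroid: across the wound (x direction) and along the
#' wound (y direction). The reported centre value is the field magnitude at
#' the profile intersection.
#'
#' @param sol A [solve_field()] solution.
#' @return A tibble with columns `axis` (`"across_x"`/`"along_y"`),
#'   `position_mm` and `E_mV_mm`, with the centre value in
#'   `attr(, "center_mV_mm")`.
#' @export
wound_profiles <- function(sol) {
  stopifnot(inherits(sol, "field_solution"))
  map <- sol$map
  cc <- wound_centroid_cell(map)
  iy <- cc["iy"]; ix <- cc["ix"]
  ok_x <- map$conducting[iy, ]
  ok_y <- map$conducting[, ix]
  out <- bind_rows(
    tibble(axis = "across_x", position_mm = map$x[ok_x],
           E_mV_mm = sol$E_mag[iy, ok_x]),
    tibble(axis = "along_y", position_mm = map$y[ok_y],
           E_mV_mm = sol$E_mag[ok_y, ix]))
  attr(out, "center_mV_mm") <- sol$E_mag[iy, ix]
  attr(out, "center_xy_mm") <- c(map$x[ix], map$y[iy])
  class(out) <- c("wound_profiles", class(out))
  out
}

#' Calibrate the input current to a target wound-centre field strength
#'
#' The discretised problem is linear in the injected current, so a single
#' solve at a probe current fixes the scale; the returned current is then
#' confirmed by a second solve.
#'
#' @param map A conductivity map.
#' @param config An [electrode_config()].
#' @param target_mV_mm Desired field magnitude at the wound centre (mV/mm).
#' @param state Active-anode state passed to [solve_field()].
#' @param tol Relative tolerance of the confirming solve (default 0.5%).
#' @return Calibrated current (uA), with the confirming solution in
#'   `attr(, "solution")`.
#' @export
calibrate_current <- function(map, config, target_mV_mm, state = NULL,
                              tol = 5e-3) {
  if (!is.finite(target_mV_mm) || target_mV_mm <= 0) {
    abort("target field must be positive", class = "woundfield_calibration_error")
  }
  probe <- solve_field(map, config, state = state, current_uA = config$current_uA)
  e0 <- wound_center_value(probe)
  if (!is.finite(e0) || e0 <= 0) {
    abort("wound centre sits in a true dead zone; cannot calibrate",
          class = "woundfield_calibration_error")
  }
  I <- config$current_uA * target_mV_mm / e0
  confirm <- solve_field(map, config, state = state, current_uA = I)
  err <- abs(wound_center_value(confirm) - target_mV_mm) / target_mV_mm
  if (err > tol) {
    abort(sprintf("calibration did not confirm (relative error %.2g)", err),
          class = "woundfield_calibration_error")
  }
  structure(I, solution = confirm)
}

#' Dead-zone metric at the wound centre
#'
#' Ratio of the field magnitude at the wound centre to the mean field
#' magnitude in a reference branch. Values near 1 indicate the wound sees
#' the full channel field; values well below 1 indicate a current dead
#' zone (current short-cutting a junction before reaching the wound).
#'
#' @param sol A [solve_field()] solution.
#' @param reference_branch Role name of the reference segment (default the
#'   cathode branch).
#' @return Dimensionless ratio.
#' @export
dead_zone_ratio <- function(sol, reference_branch = "cathode_branch") {
  stopifnot(inherits(sol, "field_solution"))
  map <- sol$map
  seg_i <- which(map$layout$segments$role == reference_branch)
  if (length(seg_i) != 1) {
    abort(sprintf("no segment with role '%s'", reference_branch),
          class = "woundfield_geometry_error")
  }
  ref <- map$segment_id == seg_i & map$conducting & !map$in_reservoir
  eref <- mean(sol$E_mag[ref])
  if (!is.finite(eref) || eref <= 0) {
    abort("reference branch carries no field; ratio undefined",
          class = "woundfield_undefined_ratio")
  }
  wound_center_value(sol) / eref
}

#' Relay stimulation sequence for the pseudo-converging scheme
#'
#' Alternates the active anode on the configured relay period over a total
#' stimulation duration, solving the field once per anode state (solutions
#' are reused across intervals; the problem is quasi-static).
#'
#' @param map A conductivity map.
#' @param config A `pseudo_converging` [electrode_config()].
#' @param duration_h Total stimulation duration (h).
#' @return A tibble with `interval`, `t_start_h`, `t_end_h`, `state` and a
#'   `solution` list-column.
#' @export
relay_sequence <- function(map, config, duration_h) {
  stopifnot(inherits(config, "electrode_config"))
  if (config$scheme != "pseudo_converging") {
    abort("relay_sequence requires the pseudo_converging scheme",
          class = "woundfield_config_error")
  }
  if (config$relay_period_min <= 0) {
    abort("relay_period_min must be positive", class = "woundfield_config_error")
  }
  period_h <- config$relay_period_min / 60
  n <- floor(duration_h / period_h + 1e-9)
  if (n == 0) {
    return(tibble(interval = integer(), t_start_h = numeric(),
                  t_end_h = numeric(), state = character(),
                  solution = list()))
  }
  sols <- lapply(config$anodes, function(a) solve_field(map, config, state = a))
  names(sols) <- config$anodes
  states <- config$anodes[(seq_len(n) - 1) %% length(config$anodes) + 1]
  tibble(interval = seq_len(n),
         t_start_h = (seq_len(n) - 1) * period_h,
         t_end_h = seq_len(n) * period_h,
         state = states,
         solution = unname(sols[states]))
}

#' Current through a vertical cut (discrete conservation check)
#'
#' Sums the edge currents crossing the vertical line `x = x_mm`; for any cut
#' separating anode from cathode this equals the injected current.
#'
#' @param sol A [solve_field()] solution.
#' @param x_mm Cut position (mm).
#' @return Net current crossing the cut, in uA (positive toward +x).
#' @export
cut_current <- function(sol, x_mm) {
  map <- sol$map
  ix <- max(which(map$x < x_mm))
  if (ix < 1 || ix >= length(map$x)) {
    abort("cut outside grid", class = "woundfield_geometry_error")
  }
  cond <- map$conducting
  ok <- cond[, ix] & cond[, ix + 1]
  g1 <- map$g_sheet[, ix][ok]; g2 <- map$g_sheet[, ix + 1][ok]
  ge <- 2 / (1 / g1 + 1 / g2)
  dV <- (sol$V_mV[, ix][ok] - sol$V_mV[, ix + 1][ok]) * 1e-3
  sum(ge * dV) * 1e6
}

#' Scalar summary of a field solution
#'
#' @param x A `field_solution`.
#' @param ... Unused.
#' @return One-row tibble with current, resistance, wound-centre field and
#'   dead-zone-free maximum field.
#' @method glance field_solution
#' @export
glance.field_solution <- function(x, ...) {
  tibble(current_uA = x$current_uA,
         R_kohm = x$R_kohm,
         E_center_mV_mm = wound_center_value(x),
         E_max_mV_mm = max(x$E_mag),
         state = paste(x$state, collapse = "+"))
}
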