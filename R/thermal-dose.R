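#' Joule energy dissipated during galvanostatic stimulation
#'
#' Total resistive energy `I^2 * R * t` delivered into the electrolyte over
#' a constant-current protocol.
#'
#' @param current_uA Input current (uA).
#' @param resistance_kohm Network resistance (kOhm).
#' @param duration_h Stimulation time (h).
#' @return Energy in joules.
#' @examples
#' joule_energy(25, 101.6, 12) # ~2.74 J
#' joule_energy(20, 108.3, 12) # ~1.87 J
#' @export
joule_energy <- function(current_uA, resistance_kohm, duration_h) {
  if (any(c(current_uA, resistance_kohm, duration_h) < 0) ||
      any(!is.finite(c(current_uA, resistance_kohm, duration_h)))) {
    abort("current, resistance and duration must be non-negative",
          class = "woundfield_domain_error")
  }
  (current_uA * 1e-6)^2 * (resistance_kohm * 1e3) * (duration_h * 3600)
}

#' Current density over a disc electrode
#'
#' @param current_mA Current (mA).
#' @param diameter_mm Disc diameter (mm).
#' @return Current density in mA/cm^2.
#' @examples
#' disc_current_density(0.40, 3)   # ~5.7 mA/cm^2
#' disc_current_density(0.025, 12) # ~0.022 mA/cm^2
#' @export
disc_current_density <- function(current_mA, diameter_mm) {
  if (any(!is.finite(c(current_mA, diameter_mm))) || diameter_mm <= 0) {
    abort("diameter must be positive", class = "woundfield_domain_error")
  }
  area_cm2 <- pi * (diameter_mm / 10 / 2)^2
  current_mA / area_cm2
}

#' Electrode specification with capacitive charge store
#'
#' @param diameter_mm Electrode disc diameter (mm).
#' @param csc_mC_cm2 Charge storage capacity (mC/cm^2). Pseudocapacitive
#'   conducting-polymer electrodes reach roughly 40-50 mC/cm^2.
#' @return An `electrode_spec` with derived stored charge `q_mC`.
#' @examples
#' electrode_spec(12, 40)$q_mC # ~45.2 mC
#' @export
electrode_spec <- function(diameter_mm = 12, csc_mC_cm2 = 40) {
  if (any(!is.finite(c(diameter_mm, csc_mC_cm2))) || diameter_mm <= 0 ||
      csc_mC_cm2 < 0) {
    abort("diameter must be positive and CSC non-negative",
          class = "woundfield_domain_error")
  }
  area_cm2 <- pi * (diameter_mm / 10 / 2)^2
  structure(list(diameter_mm = diameter_mm, csc_mC_cm2 = csc_mC_cm2,
                 area_cm2 = area_cm2, q_mC = csc_mC_cm2 * area_cm2),
            class = "electrode_spec")
}

#' @export
print.electrode_spec <- function(x, ...) {
  cat(sprintf("<electrode_spec: d = %g mm, CSC = %g mC/cm^2, q = %.3g mC>\n",
              x$diameter_mm, x$csc_mC_cm2, x$q_mC))
  invisible(x)
}

#' Capacitive delivery time of an electrode
#'
#' Time `t = q / i` for which a constant current can be supplied from the
#' electrode's stored charge before the drive becomes predominately
#' faradaic.
#'
#' @param spec An [electrode_spec()].
#' @param current_uA Input current (uA), > 0.
#' @return Duration in seconds.
#' @examples
#' capacitive_duration(electrode_spec(12, 40), 25) # ~1810 s
#' @export
capacitive_duration <- function(spec, current_uA) {
  stopifnot(inherits(spec, "electrode_spec"))
  if (!is.finite(current_uA) || current_uA <= 0) {
    abort("current must be positive", class = "woundfield_domain_error")
  }
  (spec$q_mC * 1e-3) / (current_uA * 1e-6)
}

#' Anode state-of-charge ledger under relay stimulation
#'
#' Tracks the stored charge of each anode through an alternating relay
#' protocol: the active anode discharges `I * tau` per phase; the idle
#' anode passively recovers a fraction of the charge it delivered in its
#' preceding active phase (recharging with ions from solution). A
#' faradaic-onset flag is raised for the first phase in which an anode's
#' cumulative net discharge exceeds its stored charge `q`.
#'
#' @param spec An [electrode_spec()].
#' @param current_uA Phase current (uA).
#' @param relay_period_min Active-phase length (min).
#' @param duration_h Total protocol duration (h).
#' @param recharge_fraction Fraction of the just-delivered charge recovered
#'   while idle, in `[0, 1]`.
#' @param n_anodes Number of anodes cycled by the relay.
#' @return A tibble with one row per phase and per anode: `phase`,
#'   `t_start_h`, `anode`, `active`, `soc_mC` (state of charge at phase
#'   end), `net_discharge_mC`, and `faradaic_onset`.
#' @export
relay_charge_budget <- function(spec, current_uA, relay_period_min = 30,
                                duration_h = 12, recharge_fraction = 0.9,
                                n_anodes = 2) {
  stopifnot(inherits(spec, "electrode_spec"))
  if (!is.finite(recharge_fraction) || recharge_fraction < 0 ||
      recharge_fraction > 1) {
    abort("recharge_fraction must lie in [0, 1]",
          class = "woundfield_domain_error")
  }
  if (current_uA < 0 || relay_period_min <= 0 || duration_h < 0) {
    abort("current and duration must be non-negative; period positive",
          class = "woundfield_domain_error")
  }
  per_phase_mC <- current_uA * 1e-6 * relay_period_min * 60 * 1e3
  n_phases <- floor(duration_h * 60 / relay_period_min + 1e-9)
  soc <- rep(spec$q_mC, n_anodes)
  net <- rep(0, n_anodes)
  last_delivered <- rep(0, n_anodes)
  rows <- vector("list", n_phases * n_anodes)
  k <- 0L
  for (ph in seq_len(n_phases)) {
    act <- (ph - 1L) %% n_anodes + 1L
    for (a in seq_len(n_anodes)) {
      if (a == act) {
        soc[a] <- soc[a] - per_phase_mC
        net[a] <- net[a] + per_phase_mC
        last_delivered[a] <- per_phase_mC
      } else if (last_delivered[a] > 0) {
        back <- recharge_fraction * last_delivered[a]
        soc[a] <- min(spec$q_mC, soc[a] + back)
        net[a] <- max(0, net[a] - back)
        last_delivered[a] <- 0
      }
      k <- k + 1L
      rows[[k]] <- tibble(
        phase = ph, t_start_h = (ph - 1) * relay_period_min / 60,
        anode = a, active = a == act,
        soc_mC = soc[a], net_discharge_mC = net[a],
        faradaic_onset = net[a] > spec$q_mC)
    }
  }
  out <- if (k == 0L) {
    tibble(phase = integer(), t_start_h = numeric(), anode = integer(),
           active = logical(), soc_mC = numeric(),
           net_discharge_mC = numeric(), faradaic_onset = logical())
  } else {
    bind_rows(rows)
  }
  attr(out, "onset_phase") <- if (any(out$faradaic_onset)) {
    min(out$phase[out$faradaic_onset])
  } else {
    NA_integer_
  }
  out
}

#' Thermal material properties
#'
#' Defaults follow the materials of the stimulation chip: phosphate-buffered
#' saline electrolyte, acrylic substrate/lid and a conducting-polymer
#' electrode coating. The electrolyte heat capacity defaults to that of
#' water (4184 J/kg/K); the steady-state temperature bound is independent of
#' the heat capacity, which only sets the equilibration time.
#'
#' @param fluid,acrylic,electrode Named lists with `k` (W/m/K), `rho`
#'   (kg/m^3), `Cp` (J/kg/K).
#' @return A `material_props` list.
#' @export
material_props <- function(
    fluid = list(k = 2, rho = 1000, Cp = 4184),
    acrylic = list(k = 0.19, rho = 1190, Cp = 1420),
    electrode = list(k = 0.348, rho = 1060, Cp = 1415)) {
  for (m in list(fluid, acrylic, electrode)) {
    if (any(unlist(m) <= 0)) {
      abort("material properties must be positive",
            class = "woundfield_domain_error")
    }
  }
  structure(list(fluid = fluid, acrylic = acrylic, electrode = electrode),
            class = "material_props")
}

#' Thermal boundary conditions
#'
#' @param T_ext_K External (incubator) temperature.
#' @param h_conv_W_m2K Convective heat-transfer coefficient on the outer
#'   surfaces.
#' @param emissivity Surface emissivity for the optional linearised
#'   radiative term.
#' @param radiative Include the linearised radiative conductance (default
#'   off; negligible for sub-kelvin rises).
#' @param T_init_K Initial temperature.
#' @return A `thermal_bc` list.
#' @export
thermal_bc <- function(T_ext_K = 310.15, h_conv_W_m2K = 5,
                       emissivity = 0.95, radiative = FALSE,
                       T_init_K = T_ext_K) {
  if (h_conv_W_m2K < 0 || emissivity < 0 || emissivity > 1) {
    abort("h must be >= 0 and emissivity in [0, 1]",
          class = "woundfield_domain_error")
  }
  structure(list(T_ext_K = T_ext_K, h_conv_W_m2K = h_conv_W_m2K,
                 emissivity = emissivity, radiative = radiative,
                 T_init_K = T_init_K),
            class = "thermal_bc")
}

#' Transient heat diffusion driven by joule heating
#'
#' Solves the in-plane transient heat equation on the chip grid in a
#' thin-layer (2.5-D) approximation. Every grid cell carries the lumped
#' substrate and lid acrylic layers; conducting cells additionally carry the
#' electrolyte film and receive the areal joule source taken from the field
#' solution. Heat leaves vertically through lid and substrate into the
#' convective environment (conduction and surface convection in series) and
#' spreads laterally through both the electrolyte and the acrylic. Time
#' stepping is backward Euler (unconditionally stable); the constant system
#' matrix is factorised once.
#'
#' @param map A conductivity map.
#' @param sol A [solve_field()] solution on the same grid (or `NULL` when
#'   `source_W_m2` is supplied directly).
#' @param props [material_props()].
#' @param bc [thermal_bc()].
#' @param duration_h Simulated time (h).
#' @param dt_s Time step (s).
#' @param substrate_mm,lid_mm Acrylic layer thicknesses (mm).
#' @param source_W_m2 Optional areal heat-source override (matrix, W/m^2).
#' @return A `heat_solution`: tibble `series` (`time_h`,
#'   `dT_wound_max_C`, `dT_domain_max_C`), matrix `dT_final_C`, scalar
#'   `dT_wound_max_C` (maximum over time within the wound zone), and the
#'   lumped coefficients used.
#' @export
transient_heat <- function(map, sol = NULL, props = material_props(),
                           bc = thermal_bc(), duration_h = 12, dt_s = 120,
                           substrate_mm = 1, lid_mm = 8.5,
                           source_W_m2 = NULL) {
  stopifnot(inherits(map, "conductivity_map"))
  if (duration_h <= 0 || dt_s <= 0) {
    abort("duration and time step must be positive",
          class = "woundfield_domain_error")
  }
  ny <- length(map$y); nx <- length(map$x)
  dx <- map$spacing_mm * 1e-3
  a_cell <- dx^2
  h_fl <- map$channel_height_mm * 1e-3
  t_acr <- (substrate_mm + lid_mm) * 1e-3

  cond <- map$conducting
  # areal in-plane conductances (W/K per square) and heat capacity (J/m^2/K)
  k_s <- matrix(props$acrylic$k * t_acr, ny, nx)
  k_s[cond] <- k_s[cond] + props$fluid$k * h_fl
  C_areal <- matrix(props$acrylic$rho * props$acrylic$Cp * t_acr, ny, nx)
  C_areal[cond] <- C_areal[cond] + props$fluid$rho * props$fluid$Cp * h_fl

  h_eff <- bc$h_conv_W_m2K
  if (bc$radiative) {
    # linearised grey-body conductance at the external temperature
    h_eff <- h_eff + 4 * bc$emissivity * 5.670374e-8 * bc$T_ext_K^3
  }
  u_top <- if (h_eff > 0) 1 / (1 / h_eff + (lid_mm * 1e-3) / props$acrylic$k) else 0
  u_bot <- if (h_eff > 0) 1 / (1 / h_eff + (substrate_mm * 1e-3) / props$acrylic$k) else 0
  U <- u_top + u_bot  # W/m^2/K, uniform

  if (is.null(source_W_m2)) {
    if (is.null(sol)) abort("need a field solution or an explicit source")
    stopifnot(inherits(sol, "field_solution"))
    source_W_m2 <- sol$p_areal_W_m2
  }
  stopifnot(all(dim(source_W_m2) == c(ny, nx)))

  # assemble Laplacian over all cells with harmonic-mean interface k
  all_cells <- matrix(TRUE, ny, nx)
  edges <- grid_neighbour_edges(all_cells)
  ke <- 2 / (1 / k_s[edges[, 1]] + 1 / k_s[edges[, 2]])
  nn <- ny * nx
  Lth <- sparseMatrix(i = c(edges[, 1], edges[, 2], edges[, 1], edges[, 2]),
                      j = c(edges[, 1], edges[, 2], edges[, 2], edges[, 1]),
                      x = c(ke, ke, -ke, -ke), dims = c(nn, nn))
  Ccell <- as.numeric(C_areal) * a_cell
  Ucell <- rep(U * a_cell, nn)
  Pcell <- as.numeric(source_W_m2) * a_cell

  M <- Lth + Diagonal(nn, Ccell / dt_s + Ucell)
  ch <- Cholesky(methods::as(M, "symmetricMatrix"), LDL = FALSE)

  n_steps <- ceiling(duration_h * 3600 / dt_s)
  theta <- rep(bc$T_init_K - bc$T_ext_K, nn)
  wound_idx <- which(map$wound)
  record_every <- max(1L, floor(n_steps / 200))
  times <- numeric(0); wmax <- numeric(0); dmax <- numeric(0)
  peak <- max(0, theta[wound_idx])
  for (s in seq_len(n_steps)) {
    rhs <- Ccell / dt_s * theta + Pcell
    theta <- as.numeric(Matrix::solve(ch, rhs))
    pw <- if (length(wound_idx)) max(theta[wound_idx]) else NA_real_
    peak <- max(peak, pw, na.rm = TRUE)
    if (s %% record_every == 0 || s == n_steps) {
      times <- c(times, s * dt_s / 3600)
      wmax <- c(wmax, pw)
      dmax <- c(dmax, max(theta))
    }
  }
  structure(
    list(series = tibble(time_h = times, dT_wound_max_C = wmax,
                         dT_domain_max_C = dmax),
         dT_final_C = matrix(theta, ny, nx),
         dT_wound_max_C = peak,
         U_W_m2K = U, k_sheet_acrylic = props$acrylic$k * t_acr,
         dt_s = dt_s, duration_h = duration_h),
    class = "heat_solution")
}

#' @export
print.heat_solution <- function(x, ...) {
  cat(sprintf("<heat_solution: %g h at dt = %g s>\n", x$duration_h, x$dt_s))
  cat(sprintf("  max wound-zone temperature rise %.4g degC (U = %.3g W/m^2/K)\n",
              x$dT_wound_max_C, x$U_W_m2K))
  invisible(x)
}

#' @method glance heat_solution
#' @export
glance.heat_solution <- function(x, ...) {
  tibble(dT_wound_max_C = x$dT_wound_max_C,
         dT_domain_max_C = max(x$dT_final_C),
         duration_h = x$duration_h, dt_s = x$dt_s, U_W_m2K = x$U_W_m2K)
}
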