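# shared fixtures, built once per test run and memoised

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

fx_straight_map <- function(spacing = 0.05) {
  fx(paste0("straight_", spacing),
     rasterize_layout(chip_layout("straight"), spacing_mm = spacing))
}

fx_straight_sol <- function(spacing = 0.05, I = 25) {
  fx(paste0("straight_sol_", spacing, "_", I),
     solve_field(fx_straight_map(spacing),
                 electrode_config("uni_directional", current_uA = I)))
}

# analytic mid-channel field for the straight chip defaults, mV/mm
straight_E_oracle <- function(I_uA = 25, sigma = 1.54, w_mm = 0.9, h_mm = 0.08) {
  I_uA * 1e-6 / (sigma * w_mm * 1e-3 * h_mm * 1e-3)
}

# small simulated wound scenario reused across tests (12 h at 10 min = 72 frames)
fx_sim <- function(rate = 3.5, bias = 0, seed = 1, duration_h = 12) {
  fx(sprintf("sim_%g_%g_%d_%g", rate, if (length(bias) == 1) bias else -99,
             seed, duration_h),
     simulate_collective(sim_params(
       domain_px = 256, gap_px = 100, cell_radius_px = 6,
       closure_rate_pct_h = rate, bias = bias, duration_h = duration_h,
       seed = seed)))
}

fx_stack <- function(rate = 3.5, seed = 1) {
  fx(sprintf("stack_%g_%d", rate, seed), render_stack(fx_sim(rate, seed = seed)))
}

# synthetic textured stack with an analytically known, linearly closing gap:
# iid-noise "cells" everywhere except a smooth central band
noise_gap_stack <- function(n_frames = 24, size = 200, gap0 = 100,
                            close_by = n_frames, seed = 11) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(f) {
    img <- matrix(0.5 + runif(size * size, -0.25, 0.25), size, size)
    w <- if (close_by > 1) gap0 * max(0, 1 - (f - 1) / (close_by - 1)) else gap0
    if (w > 0) {
      lo <- round((size - w) / 2) + 1; hi <- round((size + w) / 2)
      if (hi >= lo) img[, lo:hi] <- 0.5 + rnorm(size * (hi - lo + 1), 0, 0.004)
    }
    img
  })
}
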