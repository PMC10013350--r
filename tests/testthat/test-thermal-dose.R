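test_that("joule energy follows I^2 R t in SI units", {
  expect_equal(joule_energy(25, 101.6, 12), 25e-6^2 * 101.6e3 * 12 * 3600)
  expect_equal(joule_energy(0, 101.6, 12), 0)
  expect_error(joule_energy(-1, 1, 1), class = "woundfield_domain_error")
})

test_that("disc current density divides by the disc area", {
  expect_equal(disc_current_density(0.40, 3), 0.40 / (pi * 0.15^2))
  expect_equal(disc_current_density(0, 5), 0)
  expect_error(disc_current_density(1, 0), class = "woundfield_domain_error")
})

test_that("capacitive delivery time is q / i", {
  spec <- electrode_spec(12, 40)
  expect_equal(spec$q_mC, 40 * pi * 0.6^2)
  t1 <- capacitive_duration(spec, 25)
  expect_equal(t1, (40 * pi * 0.6^2) * 1e-3 / 25e-6)
  # doubling the current halves the delivery time
  expect_equal(capacitive_duration(spec, 50), t1 / 2)
  expect_equal(capacitive_duration(electrode_spec(12, 0), 25), 0)
  expect_error(capacitive_duration(spec, 0), class = "woundfield_domain_error")
})

test_that("relay charge budget matches a cumulative-sum oracle", {
  spec <- electrode_spec(12, 40) # q = 45.24 mC
  # oracle: without recharge, anode 1 is active on odd phases and each
  # active phase draws I * tau
  per_phase <- 20e-6 * 30 * 60 * 1e3 # mC
  cum1 <- cumsum(rep(per_phase, 12))
  onset_active_phase <- which(cum1 > spec$q_mC)[1]
  onset_global_phase <- 2 * onset_active_phase - 1
  bud <- relay_charge_budget(spec, 20, 30, 12, recharge_fraction = 0)
  expect_equal(attr(bud, "onset_phase"), onset_global_phase)

  # full passive recharge: state of charge is periodic and never flags
  bud1 <- relay_charge_budget(spec, 20, 30, 12, recharge_fraction = 1)
  expect_false(any(bud1$faradaic_onset))
  a1 <- bud1[bud1$anode == 1 & !bud1$active, ]
  expect_true(all(abs(a1$soc_mC - spec$q_mC) < 1e-9))

  # zero duration: no phases, no flag
  bud0 <- relay_charge_budget(spec, 20, 30, 0, recharge_fraction = 0.9)
  expect_equal(nrow(bud0), 0)
  expect_error(relay_charge_budget(spec, 20, 30, 12, recharge_fraction = 2),
               class = "woundfield_domain_error")
})

make_strip_map <- function(n = 400, spacing_mm = 0.15) {
  # 1-D strip of conducting cells for analytic heat-transfer checks
  structure(
    list(x = seq_len(n) * spacing_mm, y = 0, spacing_mm = spacing_mm,
         conducting = matrix(TRUE, 1, n),
         g_sheet = matrix(1.54 * 0.08e-3, 1, n),
         segment_id = matrix(1L, 1, n),
         wound = matrix(FALSE, 1, n),
         in_reservoir = matrix(FALSE, 1, n),
         electrodes = list(),
         sigma_S_m = 1.54, channel_height_mm = 0.08,
         layout = list(layout_kind = "strip")),
    class = "conductivity_map")
}

test_that("zero source gives zero temperature rise", {
  m <- make_strip_map(50)
  m$wound[1, 20:30] <- TRUE
  hs <- transient_heat(m, source_W_m2 = matrix(0, 1, 50), duration_h = 0.5,
                       dt_s = 60)
  expect_equal(hs$dT_wound_max_C, 0)
})

test_that("uniform source reaches the lumped-loss steady state p/U", {
  m <- make_strip_map(100)
  m$wound[1, 40:60] <- TRUE
  p <- 5 # W/m^2
  hs <- transient_heat(m, source_W_m2 = matrix(p, 1, 100), duration_h = 12,
                       dt_s = 300)
  expect_equal(hs$dT_wound_max_C, p / hs$U_W_m2K, tolerance = 1e-3)
})

test_that("half-heated strip matches the fin-equation closed form", {
  n <- 400; spacing <- 0.15
  m <- make_strip_map(n, spacing)
  p <- 5
  src <- matrix(0, 1, n); src[1, seq_len(n / 2)] <- p
  hs <- transient_heat(m, source_W_m2 = src, duration_h = 12, dt_s = 300)
  # steady solution of k_s T'' = U T - p with no-flux ends:
  # theta = p/U + A cosh(x/lambda) on the heated half, B cosh((L-x)/lambda)
  # on the unheated half, with A = -B = -p / (2U cosh(Lh/lambda))
  props <- material_props()
  k_s <- props$acrylic$k * 9.5e-3 + props$fluid$k * 0.08e-3
  U <- hs$U_W_m2K
  lam <- sqrt(k_s / U)
  x <- (seq_len(n) - 0.5) * spacing * 1e-3
  Lh <- n / 2 * spacing * 1e-3
  Ltot <- n * spacing * 1e-3
  B <- p / (2 * U * cosh(Lh / lam))
  analytic <- ifelse(x <= Lh,
                     p / U - B * cosh(x / lam),
                     B * cosh((Ltot - x) / lam))
  expect_lt(max(abs(hs$dT_final_C - analytic)) / (p / U), 0.02)
})

test_that("steady temperature rise is independent of the heat capacity", {
  m <- make_strip_map(100)
  m$wound[1, 40:60] <- TRUE
  src <- matrix(3, 1, 100)
  h1 <- transient_heat(m, source_W_m2 = src, duration_h = 12, dt_s = 300)
  h2 <- transient_heat(m, source_W_m2 = src, duration_h = 12, dt_s = 300,
                       props = material_props(
                         fluid = list(k = 2, rho = 1000, Cp = 41840)))
  expect_equal(h1$dT_wound_max_C, h2$dT_wound_max_C, tolerance = 1e-3)
})

test_that("temperature rise grows with the injected current", {
  m <- make_strip_map(100)
  m$wound[1, 40:60] <- TRUE
  src <- matrix(3, 1, 100)
  h1 <- transient_heat(m, source_W_m2 = src, duration_h = 2, dt_s = 300)
  h4 <- transient_heat(m, source_W_m2 = 4 * src, duration_h = 2, dt_s = 300)
  # doubling I quadruples the ohmic source
  expect_equal(h4$dT_wound_max_C, 4 * h1$dT_wound_max_C, tolerance = 1e-9)
})
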