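# Forward model builder: prescribes canopy temperature at the unstressed
# Priestley-Taylor value and soil temperature from a wetness fraction of
# the soil available energy, then iterates the radiation budget to its
# fixed point and composites the radiometric temperature. The returned
# truth satisfies every budget identity by construction.
forward_pixels <- function(n, seed, wet_range = c(0.1, 0.9)) {
  set.seed(seed)
  consts <- et_constants()
  Ta <- runif(n, 282, 304)
  Delta <- esat_slope(Ta)
  lai <- runif(n, 0.2, 5)
  fc <- fractional_cover(lai)
  albedo <- runif(n, 0.16, 0.25)
  Sd <- runif(n, 350, 900)
  sza <- runif(n, 0.2, 1.0)
  u <- runif(n, 1, 5)
  res <- aerodynamic_resistances(u, 10, canopy_height_from_lai(lai), lai,
                                 consts)
  emis_s <- surface_emissivity(fc)
  emis_a <- atmospheric_emissivity(Ta, runif(n, 5, 25))
  wet <- runif(n, wet_range[1], wet_range[2])
  rhoCp <- consts$rho * consts$Cp
  trad <- Ta
  for (it in 1:400) {
    Rn <- net_radiation(albedo, Sd, emis_a, emis_s, Ta, trad, consts)
    p <- partition_net_radiation(Rn, lai, sza, consts$k_ext)
    G <- soil_heat_flux(p$Rns, consts$cg)
    Tc <- initial_canopy_temperature(Ta, p$Rnc, res$ra_c, 1.26, 1, Delta,
                                     consts)
    Hs <- (1 - wet) * (p$Rns - G)
    Ts <- Ta + Hs * (res$ra_c + res$ra_s) / rhoCp
    trad_new <- (fc * Tc^4 + (1 - fc) * Ts^4)^0.25
    if (max(abs(trad_new - trad)) < 1e-12) { trad <- trad_new; break }
    trad <- 0.7 * trad + 0.3 * trad_new
  }
  Rn <- net_radiation(albedo, Sd, emis_a, emis_s, Ta, trad, consts)
  p <- partition_net_radiation(Rn, lai, sza, consts$k_ext)
  G <- soil_heat_flux(p$Rns, consts$cg)
  Tc <- initial_canopy_temperature(Ta, p$Rnc, res$ra_c, 1.26, 1, Delta,
                                   consts)
  Hc <- rhoCp * (Tc - Ta) / res$ra_c
  Hs <- (1 - wet) * (p$Rns - G)
  Ts <- Ta + Hs * (res$ra_c + res$ra_s) / rhoCp
  LE <- (p$Rnc - Hc) + wet * (p$Rns - G)
  list(Trad = (fc * Tc^4 + (1 - fc) * Ts^4)^0.25, Ta = Ta, Delta = Delta,
       lai = lai, fc = fc, albedo = albedo, emis_s = emis_s,
       emis_a = emis_a, Sd = Sd, sza = sza, ra_c = res$ra_c,
       ra_s = res$ra_s, LE = LE, Rn = Rn, Tc = Tc, Ts = Ts)
}

solve_forward <- function(fw, consts = et_constants()) {
  tseb_solve(fw$Trad, fw$Ta, fw$Delta, fw$lai, fw$fc, 1, fw$albedo,
             fw$emis_s, fw$emis_a, fw$Sd, fw$sza, fw$ra_c, fw$ra_s,
             consts)
}

test_that("net radiation matches direct evaluations of the budget", {
  expect_equal(net_radiation(0.2, 800, 1, 1, 300, 300), 640)
  expect_equal(net_radiation(0, 0, 0.85, 0.98, 300, 310), -122.78,
               tolerance = 1e-4)
  expect_equal(net_radiation(0.3, 0, 0.9, 0.9, 295, 295), 0)
})

test_that("radiation partition conserves energy and follows Beer's law", {
  p <- partition_net_radiation(100, 3, 30 * pi / 180, 0.45)
  expect_equal(p$Rnc / 100, 1 - exp(-1.35 / (2 * cos(pi / 6))),
               tolerance = 1e-12)
  expect_equal(p$Rnc, 54.13, tolerance = 1e-3)
  bare <- partition_net_radiation(250, 0, 0.3)
  expect_equal(bare$Rnc, 0)
  expect_equal(bare$Rns, 250)
  set.seed(4)
  rn <- runif(50, -50, 700); lai <- runif(50, 0, 6)
  pp <- partition_net_radiation(rn, lai, runif(50, 0, 1.3))
  expect_equal(pp$Rnc + pp$Rns, rn, tolerance = 1e-12)
  expect_error(partition_net_radiation(100, 1, pi / 2), "zenith")
})

test_that("soil heat flux is the fixed fraction of soil net radiation", {
  expect_equal(soil_heat_flux(200, 0.35), 70)
  expect_equal(soil_heat_flux(0), 0)
  expect_equal(soil_heat_flux(-40, 0.35) / -40, 0.35)
})

test_that("aerodynamic resistances follow the neutral log profile", {
  r <- aerodynamic_resistances(2, 10, 1, 2)
  expect_equal(r$ra_c, log(9.35 / 0.125)^2 / (0.41^2 * 2),
               tolerance = 1e-12)
  expect_equal(r$ra_c, 55.4, tolerance = 1e-3)
  u <- c(1, 2, 4, 8)
  rr <- aerodynamic_resistances(u, 10, 1, 2)
  expect_true(all(diff(rr$ra_c) < 0))
  expect_true(all(rr$ra_s > 0 & is.finite(rr$ra_s)))
  # denser canopy attenuates the wind at the soil, raising ra_s
  b0 <- aerodynamic_resistances(3, 10, 1, 0)
  b1 <- aerodynamic_resistances(3, 10, 1, 4)
  expect_gt(b1$ra_s, b0$ra_s)
  # no leaf area: the soil sees the unattenuated canopy-top wind
  co <- et_constants()
  u_h <- 3 * log((1 - 0.65) / 0.125) / log((10 - 0.65) / 0.125)
  expect_equal(b0$ra_s, 1 / (co$ras_a + co$ras_b * u_h), tolerance = 1e-12)
  expect_error(aerodynamic_resistances(0, 10, 1, 2), "wind speed")
})

test_that("Priestley-Taylor canopy temperature matches the closed form", {
  co <- et_constants()
  expect_equal(
    initial_canopy_temperature(298, 300, 30, 1.26, 1, 0.189, co, rho = 1.2),
    298 + (300 * 30 / (1.2 * 1005)) * (1 - 1.26 * 0.189 / 0.255),
    tolerance = 1e-12)
  expect_equal(initial_canopy_temperature(298, 0, 30, 1.26, 1, 0.189, co),
               298)
  # full consumption of available canopy energy returns air temperature
  alpha_eq <- (0.189 + 0.066) / 0.189
  expect_equal(initial_canopy_temperature(300, 400, 25, alpha_eq, 1,
                                          0.189, co), 300)
})

test_that("soil temperature inversion round-trips the composite", {
  expect_equal(soil_temperature_from_composite(305, 305, 0.7), 305)
  expect_equal(soil_temperature_from_composite(301, 322, 0), 301)
  ts <- soil_temperature_from_composite(305, 300, 0.5)
  expect_equal(ts, ((305^4 - 0.5 * 300^4) / 0.5)^0.25, tolerance = 1e-12)
  expect_equal((0.5 * 300^4 + 0.5 * ts^4)^0.25, 305, tolerance = 1e-10)
  # canopy hotter than the composite supports: signalled as NA, not error
  expect_true(is.na(soil_temperature_from_composite(290, 320, 0.9)))
})

test_that("solver closes every energy budget exactly on all paths", {
  fw <- forward_pixels(4000, seed = 8, wet_range = c(0.01, 0.99))
  fx <- solve_forward(fw)
  expect_lt(max(abs(fx$Rn - fx$G - fx$H - fx$LE)), 1e-9)
  expect_lt(max(abs(fx$Rnc - fx$LEc - fx$Hc)), 1e-9)
  expect_lt(max(abs(fx$Rns - fx$LEs - fx$Hs - fx$G)), 1e-9)
  expect_lt(max(abs(fx$Rn - fx$Rnc - fx$Rns)), 1e-9)
  expect_true(all(fx$LEs >= 0))
  expect_true(all(fx$Tc > 150 & fx$Ts > 150))
})

test_that("non-fallback solutions recomposite the radiometric temperature", {
  fw <- forward_pixels(2000, seed = 9)
  fx <- solve_forward(fw)
  i <- !fx$fallback
  expect_gt(sum(i), 1500)
  back <- (fw$fc[i] * fx$Tc[i]^4 + (1 - fw$fc[i]) * fx$Ts[i]^4)^0.25
  expect_lt(max(abs(back - fw$Trad[i])), 1e-6)
})

test_that("solver recovers forward-model fluxes and temperatures", {
  fw <- forward_pixels(500, seed = 10)
  fx <- solve_forward(fw)
  expect_true(all(fx$alpha_pt_final == 1.26))
  expect_true(all(fx$iterations == 1))
  expect_false(any(fx$fallback))
  expect_lt(max(abs(fx$LE - fw$LE)), 1)
  expect_lt(max(abs(fx$Tc - fw$Tc)), 1e-6)
  expect_lt(max(abs(fx$Ts - fw$Ts)), 1e-6)
})

test_that("stressed composites trigger the iteration and the floor fallback", {
  # a hot, dry composite: radiometric temperature far above air
  fx <- tseb_solve(Trad = 325, Ta = 298, Delta = esat_slope(298),
                   lai = 1, fc = fractional_cover(1), fg = 1,
                   albedo = 0.2, emis_surf = 0.96, emis_atm = 0.8,
                   Sd = 800, solar_zenith = 0.4, ra_c = 40, ra_s = 120)
  expect_lt(fx$alpha_pt_final, 1.26)
  expect_gt(fx$iterations, 1)
  expect_lte(fx$iterations, ceiling(1.26 / 0.1) + 1)
  expect_lt(abs(fx$Rn - fx$G - fx$H - fx$LE), 1e-9)

  # extreme case pinned to the floor: soil evaporation zeroed, flagged
  fz <- tseb_solve(Trad = 345, Ta = 290, Delta = esat_slope(290),
                   lai = 0.5, fc = fractional_cover(0.5), fg = 1,
                   albedo = 0.3, emis_surf = 0.95, emis_atm = 0.7,
                   Sd = 900, solar_zenith = 0.3, ra_c = 30, ra_s = 60)
  if (fz$fallback) {
    expect_equal(fz$LEs, 0)
    expect_gte(fz$LEc, 0)
    expect_lt(abs(fz$Rn - fz$G - fz$H - fz$LE), 1e-9)
  }
})

test_that("sensible heat rises with radiometric temperature while the
           resistance network governs the solution", {
  trads <- seq(295, 320, by = 1)
  fx <- lapply(trads, function(tr)
    tseb_solve(tr, 295, esat_slope(295), 2, fractional_cover(2), 1, 0.2,
               0.97, 0.8, 700, 0.4, 45, 110))
  H <- vapply(fx, `[[`, numeric(1), "H")
  fb <- vapply(fx, `[[`, logical(1), "fallback")
  expect_true(all(diff(H[!fb]) > -1e-6))
  # once energy-limited, H tracks the (shrinking) available energy
  expect_true(any(fb))
  i <- which(fb)
  avail_less_le <- vapply(fx[i], function(f) f$Rn - f$G - f$LEc,
                          numeric(1))
  expect_equal(H[i], avail_less_le, tolerance = 1e-6)
})
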