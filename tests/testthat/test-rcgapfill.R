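test_that("Penman-Monteith inversion round-trips the worked example", {
  co <- et_constants(rho = 1206 / 1005)  # rho*Cp = 1206 as in the example
  le <- pm_latent_heat(Rc = 70, Delta = 0.189, Rn = 400, G = 0,
                       VPD = 1.5, ra = 30, consts = co)
  expect_equal(le, 332.27, tolerance = 1e-2)
  rc <- invert_canopy_resistance(le, 400, 0, 0.189, 1.5, 30, co)
  expect_equal(as.numeric(rc), 70, tolerance = 1e-8)
})

test_that("inversion-forward identity holds over the parameter sweep", {
  grid <- expand.grid(Rc = c(10, 50, 200, 800, 2000),
                      ra = c(10, 40, 100, 200),
                      VPD = c(0.1, 0.8, 2, 4),
                      avail = c(100, 400, 650))
  co <- et_constants()
  le <- pm_latent_heat(grid$Rc, 0.15, grid$avail, 0, grid$VPD, grid$ra,
                       co, floor_zero = FALSE)
  keep <- le > 0
  rc <- invert_canopy_resistance(le[keep], grid$avail[keep], 0, 0.15,
                                 grid$VPD[keep], grid$ra[keep], co)
  expect_lt(max(abs(rc - grid$Rc[keep]) / pmax(grid$Rc[keep], 1)), 1e-8)
})

test_that("inversion boundary and monotonicity behave", {
  co <- et_constants()
  le0 <- pm_latent_heat(0, 0.2, 500, 50, 1.2, 40, co)
  expect_equal(as.numeric(invert_canopy_resistance(le0, 500, 50, 0.2, 1.2,
                                                   40, co)), 0,
               tolerance = 1e-8)
  les <- c(100, 200, 300)
  rcs <- invert_canopy_resistance(les, 500, 50, 0.2, 1.2, 40, co)
  expect_true(all(diff(as.numeric(rcs)) < 0))
  expect_true(is.na(invert_canopy_resistance(-5, 500, 50, 0.2, 1.2, 40,
                                             co)[1]))
  # LE above the Rc = 0 bound floors with a flag
  hi <- invert_canopy_resistance(le0 * 1.5, 500, 50, 0.2, 1.2, 40, co)
  expect_equal(as.numeric(hi), 0)
  expect_true(attr(hi, "floored"))
})

test_that("forward PM is monotone in resistance with a closed-stomata limit", {
  co <- et_constants()
  rcs <- c(0, 50, 200, 1000, 1e5, 1e8)
  les <- pm_latent_heat(rcs, 0.18, 450, 40, 1.4, 35, co)
  expect_true(all(diff(les) < 0))
  expect_lt(les[length(les)], 0.1)
})

test_that("stress ramps hit their corners and midpoints", {
  co <- et_constants()
  s <- stress_scalars(co$tmin_open, co$vpd_open, co)
  expect_equal(s$m_tmin, 1)
  expect_equal(s$m_vpd, 1)
  mid <- stress_scalars((co$tmin_open + co$tmin_close) / 2, 10, co)
  expect_equal(mid$m_tmin, (1 + co$stress_floor) / 2, tolerance = 1e-12)
  expect_equal(mid$m_vpd, co$stress_floor)
  cold <- stress_scalars(co$tmin_close - 5, 0.1, co)
  expect_equal(cold$m_tmin, co$stress_floor)
  expect_equal(cold$m_vpd, 1)
  expect_error(stress_scalars(280, 1, et_constants(tmin_open = 260)),
               "ordered")
})

test_that("resistance reconstruction follows the leaf-area/stress scaling", {
  expect_equal(reconstruct_resistance(80, 2.5, 2.5, 1, 1), 80)
  expect_equal(reconstruct_resistance(100, 2, 1, 0.8, 0.5), 500)
  expect_equal(reconstruct_resistance(100, 2, 0.5, 1, 1) /
                 reconstruct_resistance(100, 2, 1, 1, 1), 2)
  expect_true(is.na(reconstruct_resistance(100, 2, 0, 1, 1)))
})

test_that("season filling is a no-op without cloudy days and fills gaps
           from the nearest clear day", {
  ss <- small_season(seed = 21, cloud_prob = 0)
  tr <- ss$truth
  fill <- fill_season(tr$et24, ss$clear, tr$lai, tr$rn24, ss$forcing,
                      tr$ra_c, max_gap = 5)
  expect_equal(fill$et24, tr$et24, tolerance = 1e-12)
  expect_true(all(fill$flag == "clear"))

  sg <- small_season(seed = 22, cloud_prob = 0.2)
  holed <- sg$truth$et24
  holed[!sg$clear, ] <- NA
  fl <- fill_season(holed, sg$clear, sg$truth$lai, sg$truth$rn24,
                    sg$forcing, sg$truth$ra_c, max_gap = 5)
  cl <- !sg$clear
  expect_true(all(is.finite(fl$et24[cl, ])))
  # truth on cloudy days was itself built by this reconstruction rule
  expect_lt(max(abs(fl$et24[cl, ] - sg$truth$et24[cl, ])), 1e-9)
  # provenance: every reconstructed day points at its nearest clear day
  src <- fl$source_day[cl, 1]
  d <- which(cl)
  nearest <- vapply(d, function(x) {
    ci <- which(sg$clear); ci[which.min(abs(ci - x))]
  }, integer(1))
  expect_equal(src, nearest)
})

test_that("gaps beyond the maximum interval stay nodata", {
  ss <- small_season(seed = 23, cloud_prob = 0)
  et <- ss$truth$et24
  clear <- ss$clear
  clear[10:25] <- FALSE   # force a 16-day hole
  et[10:25, ] <- NA
  fl <- fill_season(et, clear, ss$truth$lai, ss$truth$rn24, ss$forcing,
                    ss$truth$ra_c, max_gap = 5)
  expect_true(all(is.na(fl$et24[16:19, ])))       # centre of the hole
  expect_true(all(is.finite(fl$et24[c(11, 24), ])))  # within reach
  expect_true(all(fl$flag[17, ] == "gap"))
})
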