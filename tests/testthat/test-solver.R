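# The nested energy balance solver: Priestley-Taylor initialization,
# radiometric decomposition, and the per-record solution.

test_that("Priestley-Taylor canopy flux arithmetic", {
  # senescent layer transpires nothing
  r0 <- pt_canopy_flux(300, fg_c = 0, alpha_c = 1.26, T_A = 298, p = 100.6)
  expect_equal(r0$LE_c, 0)
  expect_equal(r0$H_c, 300)
  # alpha floored at zero shuts transpiration off
  ra <- pt_canopy_flux(300, 1, 0, 298, 100.6)
  expect_equal(ra$LE_c, 0)
  # at the air temperature where Delta/(Delta+gamma) = 0.7 exactly,
  # Rn = 400 and alpha = 1.26 give LE = 400 * 1.26 * 0.7 = 352.8
  p <- 101.3
  f_pt <- function(T) esat_slope(T) / (esat_slope(T) + psychrometric_gamma(T, p))
  T07 <- uniroot(function(T) f_pt(T) - 0.7, c(270, 320), tol = 1e-12)$root
  r <- pt_canopy_flux(400, 1, 1.26, T07, p)
  expect_equal(r$LE_c, 352.8, tolerance = 1e-6)
  expect_equal(r$H_c, 47.2, tolerance = 1e-6)
})

test_that("radiometric composition and decomposition are exact inverses", {
  expect_equal(compose_trad(0.5, 300, 300), 300)
  # fourth-power mean of 305 and 295 at f = 0.5
  expect_equal(compose_trad(0.5, 305, 295), 300.1, tolerance = 0.05)
  set.seed(11)
  for (i in 1:40) {
    f <- runif(1, 0, 0.95)
    Ta <- runif(1, 270, 330); Tb <- runif(1, 270, 330)
    Tc <- compose_trad(f, Ta, Tb)
    expect_equal(decompose_trad(Tc, f, Ta), Tb, tolerance = 1e-9)
  }
  expect_error(decompose_trad(280, 0.9, 330), "non-physical")
})

test_that("the solver skips nighttime records", {
  met <- midday_met(); met$SW_in <- 80
  r <- solve_3seb(met, 300, midseason_canopy(), 0.4, 172)
  expect_identical(r$flag, "night")
  expect_true(is.na(r$LE_total))
})

test_that("a solved daytime record satisfies all balance identities", {
  cfg <- seb_config()
  met <- midday_met()
  cs <- midseason_canopy(cfg)
  r <- solve_3seb(met, 304, cs, 0.35, 172, cfg)
  expect_true(r$converged)
  expect_equal(r$LE_ov + r$H_ov, r$Rn_ov, tolerance = 1e-9)
  expect_equal(r$LE_un + r$H_un, r$Rn_un, tolerance = 1e-9)
  expect_equal(r$LE_soil + r$H_soil + r$G, r$Rn_soil, tolerance = 1e-9)
  expect_equal(recompose_trad(r), 304, tolerance = 1e-9)
  expect_true(all(c(r$LE_ov, r$LE_un, r$LE_soil) >= 0))
  expect_true(r$alpha_ov <= 1.26 && r$alpha_un <= 1.26)
  expect_equal(r$G, 0.35 * r$Rn_soil, tolerance = 1e-12)
})

test_that("the solver is deterministic", {
  met <- midday_met()
  cs <- midseason_canopy()
  r1 <- solve_3seb(met, 304, cs, 0.35, 172)
  r2 <- solve_3seb(met, 304, cs, 0.35, 172)
  expect_identical(r1, r2)
})

test_that("a hot dry surface drives alpha down but never below zero", {
  cfg <- seb_config()
  met <- midday_met(); met$u <- 1.0
  cs <- midseason_canopy(cfg)
  # radiometric temperature far above air: strong sensible heating, the
  # balance only closes with reduced transpiration
  r <- solve_3seb(met, 316, cs, 0.35, 172, cfg)
  expect_lt(r$alpha_un, 1.26)
  expect_gte(r$alpha_un, 0)
  if (r$converged) {
    expect_gte(r$LE_soil, -1e-6)
    expect_equal(recompose_trad(r), 316, tolerance = 1e-9)
  }
})

test_that("an isothermal surface with no available energy yields no turbulent flux", {
  cfg <- seb_config(canopy = list(albedo_soil = 0, emis_soil = 1,
                                  emis_veg = 1,
                                  absorptivity = c(par = 1, nir = 1)))
  met <- midday_met()
  met$SW_in <- 101
  cs <- canopy_state(0.4, 0, 0, 0, cfg)
  cs$LAI_vine <- 1e-9   # vanishing canopy: pure soil surface
  # choose L_in so that the soil budget at T_soil = T_A is exactly zero
  met$L_in <- seb_constants$sigma * met$T_A^4 - met$SW_in
  r <- solve_3seb(met, met$T_A, cs, 0.3, 172, cfg)
  expect_lt(abs(r$Rn_total), 0.5)
  expect_lt(abs(r$H_total), 0.5)
  expect_lt(abs(r$LE_total), 0.5)
})

test_that("forward scenes are recovered by the inverse solver", {
  cfg <- seb_config()
  sc <- seb_scenario(seed = 21, days = 3)
  met <- generate_met(sc)
  cs <- midseason_canopy(cfg)
  idx <- which(daytime_mask(met$SW_in))
  for (i in idx[c(3, 6, 9)]) {
    fs <- forward_scene(met[i, ], cs, met$theta[i], met$doy[i], sc, cfg)
    expect_true(fs$converged)
    r <- solve_3seb(met[i, ], fs$T_rad, cs, met$theta[i], met$doy[i], cfg)
    expect_true(r$converged)
    expect_equal(r$LE_total, fs$LE_total, tolerance = 5)
    expect_equal(r$LE_ov, fs$LE_ov, tolerance = 10)
    expect_equal(r$LE_un, fs$LE_un, tolerance = 10)
    expect_equal(r$LE_soil, fs$LE_soil, tolerance = 10)
    expect_equal(r$alpha_ov, 1.26)
    expect_equal(r$alpha_un, 1.26)
  }
})

test_that("TSEB is the understory-free limit of the nested network", {
  cfg <- seb_config()
  met <- midday_met()
  cs <- canopy_state(1.4, 0, 1, 0, cfg)
  r3 <- solve_3seb(met, 304, cs, 0.35, 172, cfg)
  rT <- solve_tseb(met, 304, cs, 0.35, 172, cfg)
  for (cn in c("LE_ov", "LE_un", "LE_soil", "H_ov", "H_soil", "LE_total",
               "H_total", "Rn_total", "G"))
    expect_equal(r3[[cn]], rT[[cn]], tolerance = 2)
})

test_that("TSEB with a dormant sparse canopy leaves only the soil balance", {
  cfg <- seb_config()
  met <- midday_met()
  cs <- canopy_state(0.4, 0, 0, 0, cfg)   # woody floor, fg = 0
  r <- solve_tseb(met, 306, cs, 0.35, 172, cfg)
  expect_equal(r$LE_ov, 0)
  expect_equal(r$LE_un, 0)
  expect_equal(r$H_ov, r$Rn_ov)
})

test_that("bulk canopy state combines layers by LAI weighting", {
  cfg <- seb_config()
  cs <- canopy_state(1.0, 0, 1, 0, cfg)
  cs$LAI_cc <- 0.5; cs$fg_cc <- 0.4
  b <- bulk_canopy_state(cs, cfg)
  expect_equal(b$LAI_vine, 1.5)
  expect_equal(b$LAI_cc, 0)
  expect_equal(b$fg_vine, (1 * 1 + 0.5 * 0.4) / 1.5)
})
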