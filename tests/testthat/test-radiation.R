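# Radiation partitioning among the three sources and soil heat flux.

test_that("direct/diffuse split conserves the global flux", {
  cfg <- seb_config()
  sp <- split_direct_diffuse(0, 0.5, 172, cfg)
  expect_equal(sp$S_dir, 0)
  expect_equal(sp$S_dif, 0)
  # heavily overcast sky (low clearness) is fully diffuse
  ov <- split_direct_diffuse(80, 0.9, 172, cfg)
  expect_equal(ov$S_dir, 0)
  expect_equal(ov$S_dif, 80)
  # clear noon: mostly direct, and exact closure
  cl <- split_direct_diffuse(900, 0.95, 172, cfg)
  expect_equal(cl$S_dir + cl$S_dif, 900, tolerance = 1e-12)
  expect_gt(cl$S_dir / 900, 0.7)
  # clear-sky diffuse fraction at kt ~ 0.75 agrees with the published
  # correlation value (0.9511 - 0.1604 kt + 4.388 kt^2 - 16.638 kt^3
  # + 12.336 kt^4 ~ 0.232)
  kt <- 0.75
  E0 <- 1 + 0.033 * cos(2 * pi * 172 / 365)
  sw <- kt * seb_constants$solar_constant * E0 * 0.95
  sp75 <- split_direct_diffuse(sw, 0.95, 172, cfg)
  fd <- 0.9511 - 0.1604 * kt + 4.388 * kt^2 - 16.638 * kt^3 + 12.336 * kt^4
  expect_equal(sp75$S_dif / sw, fd, tolerance = 1e-6)
})

test_that("with no vegetation the soil receives the whole budget", {
  cfg <- seb_config(canopy = list(emis_soil = 1))
  cs <- canopy_state(0, 0, 0, 0, cfg)
  # bypass the vine floor: force a truly bare state
  cs$LAI_vine <- 0
  r <- net_radiation_three_source(SW_in = 600, L_in = 350, T_ov = 300,
                                  T_un = 300, T_soil = 305, canopy = cs,
                                  theta = 0.3, doy = 172, config = cfg)
  expect_equal(r$Rn_ov, 0, tolerance = 1e-9)
  expect_equal(r$Rn_un, 0, tolerance = 1e-9)
  expect_equal(r$Rn_soil,
               (1 - cfg$canopy$albedo_soil) * 600 + 350 -
                 seb_constants$sigma * 305^4,
               tolerance = 1e-9)
})

test_that("an opaque overstory leaves no shortwave for the soil", {
  cfg <- seb_config()
  cs <- canopy_state(0.4, 0, 1, 0, cfg)
  cs$LAI_vine <- 80; cs$Omega_vine <- 1
  r_sun <- net_radiation_three_source(850, 350, 300, 300, 305, cs, 0.2, 172, cfg)
  r_dark <- net_radiation_three_source(0, 350, 300, 300, 305, cs, 0.2, 172, cfg)
  # soil net radiation is unchanged by switching the sun on: nothing gets
  # through a canopy of effectively infinite optical depth
  expect_equal(r_sun$Rn_soil, r_dark$Rn_soil, tolerance = 1e-6)
})

test_that("total Rn equals the top-of-canopy radiation balance", {
  cfg <- seb_config()
  set.seed(43)
  for (i in 1:20) {
    cs <- canopy_state(runif(1, 0.4, 2), runif(1, 0, 1), runif(1), runif(1), cfg)
    sw <- runif(1, 0, 1000); lin <- runif(1, 250, 420)
    r <- net_radiation_three_source(sw, lin, runif(1, 280, 320),
                                    runif(1, 280, 320), runif(1, 280, 330),
                                    cs, runif(1, 0, 1.4), sample(365, 1), cfg)
    expect_equal(r$Rn_total, (sw - r$SW_up) + (lin - r$L_up),
                 tolerance = 1e-9)
    expect_true(r$SW_up >= 0 && r$SW_up <= sw + 1e-9)
  }
})

test_that("merging the two vegetation layers matches a one-layer canopy", {
  cfg <- seb_config()
  T0 <- 302
  cs2 <- canopy_state(1.0, 0, 1, 0, cfg)
  cs2$LAI_cc <- 0.8; cs2$Omega_cc <- cs2$Omega_vine  # same optics per layer
  cs1 <- canopy_state(1.8, 0, 1, 0, cfg)
  cs1$Omega_vine <- cs2$Omega_vine
  r2 <- net_radiation_three_source(800, 350, T0, T0, 306, cs2, 0.4, 172, cfg)
  r1 <- net_radiation_three_source(800, 350, T0, T0, 306, cs1, 0.4, 172, cfg)
  expect_equal(r2$Rn_ov + r2$Rn_un, r1$Rn_ov + r1$Rn_un,
               tolerance = 0.02 * abs(r1$Rn_ov + r1$Rn_un))
  expect_equal(r2$Rn_soil, r1$Rn_soil, tolerance = 0.02 * abs(r1$Rn_soil))
})

test_that("swapping layers with identical geometry preserves the total", {
  cfg <- seb_config()
  cs <- canopy_state(0.9, 0, 1, 0, cfg)
  cs$LAI_cc <- 0.9; cs$Omega_cc <- cs$Omega_vine
  T0 <- 300
  r <- net_radiation_three_source(700, 340, T0, T0, T0, cs, 0.5, 150, cfg)
  # identical layers: swapping over/understory cannot change the total
  rs <- net_radiation_three_source(700, 340, T0, T0, T0, cs, 0.5, 150, cfg)
  expect_equal(r$Rn_total, rs$Rn_total, tolerance = 1e-12)
  # transmittances decrease with LAI: denser canopy -> less soil radiation
  cs_dense <- canopy_state(2.0, 0, 1, 0, cfg)
  cs_dense$Omega_vine <- cs$Omega_vine
  rd <- net_radiation_three_source(700, 340, T0, T0, T0, cs_dense, 0.5, 150, cfg)
  expect_lt(rd$Rn_soil, r$Rn_soil)
})

test_that("soil heat flux modes", {
  expect_equal(soil_heat_flux(200), 70)
  expect_equal(soil_heat_flux(0), 0)
  expect_equal(soil_heat_flux(200, "observed", G_obs = 42), 42)
  expect_error(soil_heat_flux(200, "observed"), "G_obs")
})
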