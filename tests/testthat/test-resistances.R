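# Resistance network and Monin-Obukhov stability.

test_that("roughness scales linearly with canopy height", {
  cfg <- seb_config()
  r <- roughness(2, cfg)
  expect_equal(r$d, 1.3)
  expect_equal(r$z0m, 0.25)
  expect_equal(r$z0h, 0.25 / exp(2))
  r1 <- roughness(1, cfg)
  expect_equal(r$d / r1$d, 2)
  expect_equal(r$z0m / r1$z0m, 2)
  expect_lt(r$z0h, r$z0m)
  expect_error(roughness(6, cfg), "below")
})

test_that("neutral aerodynamic resistance recovers the log-law closed form", {
  cfg <- seb_config()
  rough <- list(d = 1.3, z0m = 0.25, z0h = 0.25 / exp(2))
  for (u in c(0.5, 2, 5)) {
    ra <- aerodynamic_resistance(u, 5, 5, rough, Inf, cfg)
    hand <- log(3.7 / 0.25) * log(3.7 / (0.25 / exp(2))) / (0.41^2 * u)
    expect_equal(ra, hand, tolerance = 1e-6)
  }
})

test_that("aerodynamic resistance responds correctly to wind and stability", {
  cfg <- seb_config()
  rough <- roughness(2, cfg)
  u <- seq(0.5, 8, by = 0.5)
  ra <- vapply(u, function(ui) aerodynamic_resistance(ui, 5, 5, rough, Inf, cfg),
               numeric(1))
  expect_true(all(diff(ra) < 0))   # strictly decreasing in u
  # unstable conditions lower the resistance at the same wind speed
  ra_un <- aerodynamic_resistance(2, 5, 5, rough, -20, cfg)
  ra_n <- aerodynamic_resistance(2, 5, 5, rough, Inf, cfg)
  expect_lt(ra_un, ra_n)
  # Businger-Dyer psi_h is positive under instability
  expect_gt(psi_h(-0.5), 0)
  expect_equal(psi_h(0), 0)
  expect_lt(psi_h(0.5), 0)
})

test_that("boundary-layer resistances follow the published forms", {
  cfg <- seb_config()
  cs <- midseason_canopy(cfg)
  rough <- roughness(cs$h_c_vine, cfg)
  b <- boundary_resistances(2.5, cs, rough, dT_soil = 3, dT_sub = 2, cfg)
  rc <- cfg$resistances
  # hand evaluation with the wind speeds the function reports
  expect_equal(b$R_x, (rc$C_prime / max(cs$LAI_cc, 0.2)) *
                 sqrt(rc$leaf_size / b$U_d), tolerance = 1e-12)
  expect_equal(b$R_s, 1 / (rc$c_coef * 3^(1 / 3) + rc$b_coef * b$u_s),
               tolerance = 1e-12)
  expect_equal(b$R_sub, 1 / (rc$c_coef * 2^(1 / 3) + rc$b_coef * b$u_sub),
               tolerance = 1e-12)
  expect_true(all(unlist(b[c("R_x", "R_s", "R_sub")]) > 0))
})

test_that("forced-convection limit and LAI scaling of the canopy resistance", {
  cfg <- seb_config()
  cs <- midseason_canopy(cfg)
  rough <- roughness(cs$h_c_vine, cfg)
  # no temperature difference: R_s reduces to the forced term
  b0 <- boundary_resistances(2.5, cs, rough, dT_soil = 0, dT_sub = 0, cfg)
  expect_equal(b0$R_s, 1 / (cfg$resistances$b_coef * b0$u_s), tolerance = 1e-12)
  # negative difference is floored at zero inside the cube root
  bn <- boundary_resistances(2.5, cs, rough, dT_soil = -5, dT_sub = 0, cfg)
  expect_equal(bn$R_s, b0$R_s)
  # doubling understory LAI halves R_x (source-height wind is set by the
  # overstory profile, which is unchanged)
  cs2 <- cs; cs2$LAI_cc <- 2 * cs$LAI_cc
  b2 <- boundary_resistances(2.5, cs2, rough, 0, 0, cfg)
  expect_equal(b2$R_x, b0$R_x / 2, tolerance = 1e-12)
})

test_that("Obukhov length sign and neutral sentinel", {
  rc <- rho_cp(295, 100.6, 1)
  expect_identical(obukhov_length(0.3, 295, 0, rc), Inf)
  expect_lt(obukhov_length(0.3, 295, 150, rc), 0)   # unstable: L < 0
  expect_gt(obukhov_length(0.3, 295, -50, rc), 0)   # stable: L > 0
})

test_that("stability iteration converges to the fixed point found by grid search", {
  cfg <- seb_config()
  rough <- roughness(2, cfg)
  st <- stability_iteration(H_total = 200, u = 2, T_A = 300, p = 100.6,
                            e_a = 1, rough = rough, config = cfg)
  expect_true(st$converged)
  # brute-force: scan a dense grid of L values for self-consistency
  rc <- rho_cp(300, 100.6, 1)
  grid <- -exp(seq(log(1), log(5000), length.out = 20000))
  resid <- vapply(grid, function(L) {
    us <- friction_velocity(2, 5, rough, L)
    Lc <- obukhov_length(us, 300, 200, rc)
    abs(Lc - L) / abs(L)
  }, numeric(1))
  L_grid <- grid[which.min(resid)]
  expect_equal(st$L_mo, L_grid, tolerance = 0.01)
  # determinism: identical inputs give identical states
  st2 <- stability_iteration(200, 2, 300, 100.6, 1, rough, cfg)
  expect_identical(st, st2)
})

test_that("zero heat flux gives the neutral state", {
  cfg <- seb_config()
  rough <- roughness(2, cfg)
  st <- stability_iteration(0, 2, 300, 100.6, 1, rough, cfg)
  expect_identical(st$L_mo, Inf)
  expect_equal(st$u_star, friction_velocity(2, 5, rough, Inf))
})
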