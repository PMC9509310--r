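# LAI decomposition, green fractions, extinction, viewed fractions,
# structure and clumping.

make_flat_lai <- function(value = 1.5, days = 365) {
  list(doy = seq_len(days), LAI_eco = rep(value, days))
}

test_that("partition_lai assigns everything to the vine when no cover crop", {
  l <- make_flat_lai(1.5)
  ph <- pheno_config(cc_present = FALSE)
  p <- partition_lai(l$doy, l$LAI_eco, ph)
  expect_equal(p$LAI_cc, rep(0, 365))
  expect_equal(p$LAI_vine, rep(1.5, 365))
})

test_that("winter LAI goes to the cover crop and the vine keeps its woody floor", {
  l <- make_flat_lai(0.6)
  p <- partition_lai(l$doy, l$LAI_eco, pheno_config())
  winter <- p$doy < 80
  expect_equal(p$LAI_cc[winter], rep(0.6, sum(winter)))
  expect_equal(p$LAI_vine[winter], rep(0.4, sum(winter)))
  # the floor holds on every day of the year
  expect_true(all(p$LAI_vine >= 0.4))
})

test_that("cover-crop LAI decays exponentially with the configured e-folding time", {
  l <- make_flat_lai(2.5)
  ph <- pheno_config(budbreak_doy = 80, decay_efolding_days = 30,
                     peak_doy = 200)
  l$LAI_eco[1:79] <- 0.8    # winter level sets the budbreak value
  l$LAI_eco[80] <- 0.8
  p <- partition_lai(l$doy, l$LAI_eco, ph)
  expect_equal(p$LAI_cc[110], 0.8 / exp(1), tolerance = 1e-10)
  expect_equal(p$LAI_cc[140], 0.8 / exp(2), tolerance = 1e-10)
})

test_that("partition respects LAI accounting identities and continuity", {
  sc <- seb_scenario(seed = 5)
  lai <- generate_lai_season(sc)
  p <- partition_lai(lai$doy, lai$LAI_eco, sc$pheno)
  # layers sum to at least the ecosystem LAI, equality when floor inactive
  expect_true(all(p$LAI_vine + p$LAI_cc >= p$LAI_eco - 1e-12))
  inactive <- p$LAI_eco - p$LAI_cc >= 0.4
  expect_equal((p$LAI_vine + p$LAI_cc)[inactive], p$LAI_eco[inactive])
  # cover-crop series has no jumps beyond one daily decay step + LAI noise
  step <- max(abs(diff(p$LAI_cc)))
  daily_decay <- max(p$LAI_cc) * (1 - exp(-1 / sc$pheno$decay_efolding_days))
  lai_step <- max(abs(diff(lai$LAI_eco)))
  expect_lt(step, daily_decay + lai_step + 1e-9)
  expect_error(partition_lai(p$doy, -p$LAI_eco, sc$pheno), ">= 0")
  expect_error(partition_lai(1:100, rep(1, 100), sc$pheno), "outside")
})

test_that("green fractions follow phenology", {
  ph <- pheno_config(budbreak_doy = 80, leafoff_doy = 310,
                     decay_efolding_days = 21)
  expect_equal(green_fraction(200, ph, "vine"), 1, tolerance = 1e-2)
  expect_equal(green_fraction(15, ph, "vine"), 0)
  expect_equal(green_fraction(350, ph, "vine"), 0)
  # cover crop at one e-folding time into senescence
  expect_equal(green_fraction(80 + 21, ph, "cc"), exp(-1), tolerance = 1e-10)
  expect_equal(green_fraction(40, ph, "cc"), 1)
  fg <- green_fraction(1:365, ph, "cc")
  expect_true(all(fg >= 0 & fg <= 1))
})

test_that("beam extinction matches the ellipsoidal form and its limits", {
  # spherical distribution at nadir: ~0.5 (denominator 2.0012)
  expect_equal(beam_extinction_kb(0, 1), 0.4997, tolerance = 1e-4)
  # strictly increasing in zenith angle
  th <- seq(0, 1.5, by = 0.05)
  expect_true(all(diff(beam_extinction_kb(th, 1)) > 0))
  # spherical leaf-angle closed form G = 1/2: kb = 0.5/cos(theta)
  for (t in c(0, pi / 6, pi / 3, 1.3))
    expect_equal(beam_extinction_kb(t, 1), 0.5 / cos(t), tolerance = 0.002)
  expect_error(beam_extinction_kb(pi / 2, 1), "gated")
})

test_that("diffuse transmittance matches adaptive-quadrature oracle", {
  for (x in c(0.5, 1, 2)) {
    for (oF in c(0.2, 0.8, 2.5)) {
      oracle <- stats::integrate(function(th) {
        kb <- sqrt(x^2 + tan(th)^2) / (x + 1.774 * (x + 1.182)^(-0.733))
        2 * exp(-kb * oF) * sin(th) * cos(th)
      }, 0, pi / 2 - 1e-9, rel.tol = 1e-10)$value
      expect_equal(diffuse_transmittance(oF, x), oracle, tolerance = 1e-6)
    }
  }
})

test_that("viewed fraction follows 1 - exp(-kb Omega F)", {
  expect_equal(fraction_viewed(0, 1, 0.5), 0)
  expect_equal(fraction_viewed(2, 1, 0.5), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(fraction_viewed(1e6, 1, 0.5), 1, tolerance = 1e-9)
  # monotone in each argument, always in [0, 1)
  f <- fraction_viewed(seq(0, 10, 0.5), 0.8, 0.5)
  expect_true(all(diff(f) > 0) && all(f >= 0 & f < 1))
})

test_that("vine structure interpolates linearly between dormant and peak bounds", {
  cfg <- seb_config()
  expect_equal(structural_params(0.4, cfg)$h_c, 1.5)
  expect_equal(structural_params(2.0, cfg)$h_c, 2.2)
  expect_equal(structural_params(1.2, cfg)$h_c, 1.85)   # midpoint
  expect_equal(structural_params(5, cfg)$h_c, 2.2)      # clipped
  expect_equal(structural_params(1.2, cfg)$w_c,
               (cfg$canopy$w_c_min + cfg$canopy$w_c_max) / 2)
})

test_that("hedgerow clumping matches the strip gap probability and bounds", {
  # homogeneous cover (w_c = 1) is unclumped
  expect_equal(clumping_hedgerow(1.5, 1), 1, tolerance = 1e-10)
  om <- clumping_hedgerow(1.5, 0.4)
  expect_true(om > 0 && om < 1)
  # reproduces the gap probability by construction
  p_gap <- (1 - 0.4) + 0.4 * exp(-0.5 * 1.5 / 0.4)
  expect_equal(exp(-0.5 * om * 1.5), p_gap, tolerance = 1e-10)
  expect_equal(clumping_hedgerow(0, 0.4), 1)
})
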