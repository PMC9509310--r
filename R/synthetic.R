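# Synthetic flux-tower data generator: diurnal semi-arid meteorology, a
# two-season LAI cycle (vine + cover crop), and radiometric temperature
# consistent with a prescribed flux partition, built by running the
# model's own forward equations. Serves as self-contained, seeded input
# for every stage of the pipeline.

#' Define a synthetic vineyard scenario
#'
#' Bundles the conditions the generator emulates: a semi-arid site with
#' east-west vine rows and an interrow cover crop, clear-sky diurnal
#' forcing, a spring/autumn cover-crop cycle and a summer vine cycle.
#'
#' @param seed integer seed fixing all randomness.
#' @param days number of days generated (starting Jan 1).
#' @param year calendar year of the timestamps.
#' @param lat latitude (degrees north).
#' @param sw_amplitude clear-sky shortwave at solar noon (W m-2).
#' @param ta_mean annual-mean air temperature (K).
#' @param ta_seasonal_amp seasonal half-amplitude of daily-mean air
#'   temperature (K), peaking in late July.
#' @param ta_diurnal_amp diurnal half-amplitude of air temperature (K),
#'   peaking two hours after solar noon.
#' @param e_a mean vapor pressure (kPa).
#' @param u_mean mean wind speed (m s-1).
#' @param p air pressure (kPa).
#' @param lai_vine_max peak vine LAI (m2 m-2).
#' @param lai_cc_winter winter cover-crop LAI (m2 m-2).
#' @param peak_doy day of year ending the cover-crop decay.
#' @param alpha_ov,alpha_un prescribed Priestley-Taylor coefficients of
#'   the forward scenes.
#' @param f_soil prescribed soil evaporative fraction of the available
#'   energy at the soil (unitless in [0, 1]).
#' @param noise list of noise standard deviations: `trad` (K), `u`
#'   (m s-1), `lai` (multiplicative fraction), `met` reserved.
#' @param cc_present is a cover crop present?
#' @param pheno a [pheno_config()] object (its `peak_doy` is set from
#'   `peak_doy`).
#' @return list of class `seb_scenario`.
#' @export
seb_scenario <- function(seed = 1L, days = 365, year = 2019, lat = 36.85,
                         sw_amplitude = 950, ta_mean = 289,
                         ta_seasonal_amp = 9, ta_diurnal_amp = 7,
                         e_a = 1.0, u_mean = 2.5, p = 100.6,
                         lai_vine_max = 1.6, lai_cc_winter = 0.8,
                         peak_doy = 200,
                         alpha_ov = 1.26, alpha_un = 1.26, f_soil = 0.5,
                         noise = list(trad = 0.5, u = 0.3, lai = 0.10),
                         cc_present = TRUE,
                         pheno = pheno_config()) {
  stopifnot(f_soil >= 0, f_soil <= 1, alpha_ov >= 0, alpha_un >= 0)
  pheno$cc_present <- cc_present
  pheno$peak_doy <- peak_doy
  structure(list(seed = as.integer(seed), days = days, year = year,
                 lat = lat, sw_amplitude = sw_amplitude, ta_mean = ta_mean,
                 ta_seasonal_amp = ta_seasonal_amp,
                 ta_diurnal_amp = ta_diurnal_amp, e_a = e_a,
                 u_mean = u_mean, p = p, lai_vine_max = lai_vine_max,
                 lai_cc_winter = lai_cc_winter, peak_doy = peak_doy,
                 alpha_ov = alpha_ov, alpha_un = alpha_un, f_soil = f_soil,
                 noise = noise, cc_present = cc_present, pheno = pheno),
            class = "seb_scenario")
}

# run code with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate hourly synthetic meteorology
#'
#' Clear-sky shortwave follows the solar geometry of the scenario
#' latitude, normalized so the solar-noon value equals the configured
#' amplitude; air temperature is a seasonal plus diurnal sinusoid lagged
#' two hours after solar noon; wind and vapor pressure are constants
#' with Gaussian noise; incoming longwave uses a Brutsaert clear-sky
#' emissivity. Hourly timestamps label interval ends; the solar geometry
#' is evaluated at the interval midpoint.
#'
#' @param scenario a [seb_scenario()] object.
#' @return data.frame of hourly records: `timestamp`, `SW_in`, `L_in`,
#'   `T_A`, `e_a`, `u`, `p`, plus helper columns `doy`, `theta` (solar
#'   zenith, rad).
#' @export
generate_met <- function(scenario) {
  n <- scenario$days * 24
  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", scenario$year), tz = "UTC")
  ts <- t0 + 3600 * seq_len(n)            # interval-end labels
  hour_mid <- (seq_len(n) - 0.5) %% 24
  doy <- ((seq_len(n) - 1) %/% 24) + 1
  sp <- solar_position(doy, hour_mid, scenario$lat)
  # normalize by the day's sampled maximum so the noon value equals the
  # configured amplitude
  cosz <- pmax(sp$cos_zenith, 0)
  cosmax <- stats::ave(cosz, doy, FUN = max)
  sw <- scenario$sw_amplitude * cosz / cosmax
  ta_day <- scenario$ta_mean +
    scenario$ta_seasonal_amp * cos(2 * pi * (doy - 205) / 365.25)
  T_A <- ta_day + scenario$ta_diurnal_amp * cos(2 * pi * (hour_mid - 14) / 24)
  met <- .with_seed(scenario$seed, {
    u <- pmax(scenario$u_mean + stats::rnorm(n, 0, scenario$noise$u), 0.5)
    e_a <- pmax(scenario$e_a + stats::rnorm(n, 0, 0.05), 0.05)
    data.frame(u = u, e_a = e_a)
  })
  emis_sky <- 1.24 * (10 * met$e_a / T_A)^(1 / 7)
  L_in <- pmin(emis_sky, 1) * seb_constants$sigma * T_A^4
  data.frame(timestamp = ts, SW_in = sw, L_in = L_in, T_A = T_A,
             e_a = met$e_a, u = met$u, p = scenario$p,
             doy = doy, theta = sp$zenith)
}

#' Generate a seasonal LAI cycle with ground truth
#'
#' Vine LAI follows a logistic rise after budbreak and a logistic fall
#' into leaf-off; the cover crop carries the ecosystem LAI in winter,
#' decays exponentially from budbreak to peak summer, holds its stubble
#' value, and regrows after leaf-off — the same transition shapes
#' assumed by [partition_lai()], so the decomposition is recoverable
#' under matched decay constants. Multiplicative Gaussian noise is
#' applied to the observed ecosystem LAI only; the truth columns stay
#' noiseless.
#'
#' @param scenario a [seb_scenario()] object.
#' @return data.frame with `doy`, `LAI_eco` (noisy observation),
#'   `LAI_vine_true`, `LAI_cc_true`.
#' @export
generate_lai_season <- function(scenario) {
  ph <- scenario$pheno
  # always cover a full phenological year so the decomposition is defined
  # even for short met scenarios
  doy <- seq_len(max(scenario$days, 365))
  tau <- ph$decay_efolding_days
  rise <- 1 / (1 + exp(-(doy - (ph$budbreak_doy + 25)) / 10))
  fall <- 1 / (1 + exp((doy - (ph$leafoff_doy - 10)) / 8))
  vine <- scenario$lai_vine_max * rise * fall
  vine[doy < ph$budbreak_doy | doy >= ph$leafoff_doy] <- 0
  cc <- numeric(length(doy))
  if (scenario$cc_present) {
    w <- scenario$lai_cc_winter
    cc_bud <- w + 0.1    # mild spring growth peaking at budbreak
    pre <- doy < ph$budbreak_doy
    cc[pre] <- w + 0.1 * doy[pre] / ph$budbreak_doy
    dec <- doy >= ph$budbreak_doy & doy < scenario$peak_doy
    cc[dec] <- cc_bud * exp(-(doy[dec] - ph$budbreak_doy) / tau)
    hold_val <- cc_bud * exp(-(scenario$peak_doy - ph$budbreak_doy) / tau)
    hold <- doy >= scenario$peak_doy & doy < ph$leafoff_doy
    cc[hold] <- hold_val
    post <- doy >= ph$leafoff_doy
    cc[post] <- w - (w - hold_val) * exp(-(doy[post] - ph$leafoff_doy) / tau)
  }
  eco <- vine + cc
  eco_obs <- .with_seed(scenario$seed + 1L,
                        pmax(eco * (1 + stats::rnorm(length(eco), 0, scenario$noise$lai)), 0))
  data.frame(doy = doy, LAI_eco = eco_obs,
             LAI_vine_true = vine, LAI_cc_true = cc)
}

#' Forward scene: radiometric temperature from a prescribed partition
#'
#' Runs the model's own forward equations: given meteorology, canopy
#' state and prescribed Priestley-Taylor coefficients and soil
#' evaporative fraction, it iterates the radiation budget, resistance
#' network and stability to a consistent set of component temperatures,
#' then composes the radiometric temperature and emits the outgoing
#' longwave. Per-source energy balances hold identically by
#' construction, which makes the scene an exact recovery target for
#' [solve_3seb()].
#'
#' @param met one-row list/data.frame with `SW_in`, `L_in`, `T_A`,
#'   `e_a`, `u`, `p`.
#' @param canopy a [canopy_state()] object.
#' @param theta solar zenith (rad).
#' @param doy day of year.
#' @param scenario a [seb_scenario()] object (prescribed partition).
#' @param config a [seb_config()] object.
#' @return named list with `T_rad`, `L_out`, per-source `Rn`/`H`/`LE`,
#'   `G`, component temperatures, and `converged`.
#' @export
forward_scene <- function(met, canopy, theta, doy, scenario,
                          config = seb_config()) {
  sv <- config$solver
  rhocp <- rho_cp(met$T_A, met$p, met$e_a)
  kb_view <- beam_extinction_kb(sv$view_zenith, config$canopy$x_lad)
  f_un <- if (canopy$LAI_cc > 0)
    fraction_viewed(canopy$LAI_cc, canopy$Omega_cc, kb_view) else 0
  f_ov <- fraction_viewed(canopy$LAI_vine, canopy$Omega_vine, kb_view)
  rough <- roughness(canopy$h_c_vine, config)
  pre <- rad_precompute(met$SW_in, canopy, theta, doy, config)

  T_ov <- T_un <- T_soil <- T_sub <- met$T_A
  T_AC <- met$T_A
  L_mo <- Inf
  converged <- FALSE
  for (iter in seq_len(200)) {
    rad <- rad_budget(pre, met$L_in, T_ov, T_un, T_soil, config)
    G <- config$radiation$g_ratio * rad$Rn_soil
    R_A <- aerodynamic_resistance(met$u, config$site$z_u, config$site$z_T,
                                  rough, L_mo, config)
    bres <- boundary_resistances(met$u, canopy, rough,
                                 dT_soil = T_soil - T_AC,
                                 dT_sub = T_sub - met$T_A, config)
    pt_ov <- pt_canopy_flux(rad$Rn_ov, canopy$fg_vine, scenario$alpha_ov,
                            met$T_A, met$p)
    pt_un <- pt_canopy_flux(rad$Rn_un, canopy$fg_cc, scenario$alpha_un,
                            met$T_A, met$p)
    LE_ov <- pt_ov$LE_c; H_ov <- pt_ov$H_c
    LE_un <- pt_un$LE_c; H_un <- pt_un$H_c
    AE_soil <- rad$Rn_soil - G
    LE_soil <- scenario$f_soil * max(AE_soil, 0)
    H_soil <- AE_soil - LE_soil

    T_ov_new <- met$T_A + H_ov * R_A / rhocp
    H_sub32 <- rhocp * (T_sub - met$T_A) / (R_A + bres$R_sub)
    T_AC_new <- met$T_A + H_sub32 * R_A / rhocp
    T_un_new <- T_AC_new + H_un * bres$R_x / rhocp
    T_soil_new <- T_AC_new + H_soil * bres$R_s / rhocp
    T_sub_new <- compose_trad(f_un, T_un_new, T_soil_new)
    if (any(c(T_ov_new, T_un_new, T_soil_new) <= 0))
      stop("inconsistent flux prescription: negative component temperature")

    u_star <- friction_velocity(met$u, config$site$z_u, rough, L_mo)
    L_new <- obukhov_length(u_star, met$T_A, H_ov + H_un + H_soil, rhocp,
                            config$resistances$L_min)
    dmax <- max(abs(T_ov_new - T_ov), abs(T_un_new - T_un),
                abs(T_soil_new - T_soil), abs(T_sub_new - T_sub))
    # under-relaxed iteration (as in the solver); the reported state is
    # the last consistently computed one
    T_ov_rep <- T_ov_new; T_un_rep <- T_un_new; T_soil_rep <- T_soil_new
    T_sub_rep <- T_sub_new; T_AC_rep <- T_AC_new
    w <- sv$relax
    T_ov <- T_ov + w * (T_ov_new - T_ov)
    T_un <- T_un + w * (T_un_new - T_un)
    T_soil <- T_soil + w * (T_soil_new - T_soil)
    T_sub <- T_sub + w * (T_sub_new - T_sub)
    T_AC <- T_AC + w * (T_AC_new - T_AC)
    L_mo <- L_new
    if (dmax < sv$tol_T) { converged <- TRUE; break }
  }
  T_ov <- T_ov_rep; T_un <- T_un_rep; T_soil <- T_soil_rep
  T_sub <- T_sub_rep; T_AC <- T_AC_rep
  T_rad <- compose_trad(f_ov, T_ov, T_sub)
  list(T_rad = T_rad,
       L_out = emit_lout(T_rad, met$L_in, config$radiation$emis_trad),
       Rn_ov = rad$Rn_ov, Rn_un = rad$Rn_un, Rn_soil = rad$Rn_soil,
       Rn_total = rad$Rn_total, G = G,
       H_ov = H_ov, H_un = H_un, H_soil = H_soil,
       LE_ov = LE_ov, LE_un = LE_un, LE_soil = LE_soil,
       LE_total = LE_ov + LE_un + LE_soil,
       T_ov = T_ov, T_un = T_un, T_soil = T_soil, T_sub = T_sub,
       T_AC = T_AC, converged = converged)
}

#' Generate a complete synthetic tower dataset
#'
#' Hourly meteorology, daily LAI, per-timestamp canopy states, forward
#' scenes on every daytime hour (radiometric temperature plus the true
#' flux partition) and tower-style "observed" fluxes. Optional Gaussian
#' noise on the emitted radiometric temperature.
#'
#' @param scenario a [seb_scenario()] object.
#' @param config a [seb_config()] object.
#' @param noisy apply the scenario's radiometric-temperature noise?
#' @return list with `met` (hourly data.frame incl. `T_rad`, `L_out` and
#'   observed `Rn`, `G`, `H`, `LE`), `lai` (daily data.frame), `truth`
#'   (hourly true partition columns, NA at night).
#' @export
generate_scene_series <- function(scenario, config = seb_config(),
                                  noisy = FALSE) {
  met <- generate_met(scenario)
  lai <- generate_lai_season(scenario)
  part <- partition_lai(lai$doy, lai$LAI_eco, scenario$pheno)
  n <- nrow(met)
  truth_cols <- c("Rn_ov", "Rn_un", "Rn_soil", "Rn_total", "G",
                  "H_ov", "H_un", "H_soil", "LE_ov", "LE_un", "LE_soil",
                  "LE_total", "T_ov", "T_un", "T_soil", "T_sub", "T_AC")
  truth <- as.data.frame(matrix(NA_real_, n, length(truth_cols),
                                dimnames = list(NULL, truth_cols)))
  T_rad <- met$T_A   # nighttime radiometric temperature ~ air temperature
  day <- daytime_mask(met$SW_in, config$daytime_sw_min)
  for (i in which(day)) {
    d <- met$doy[i]
    cs <- canopy_state(part$LAI_vine[d], part$LAI_cc[d],
                       green_fraction(d, scenario$pheno, "vine"),
                       green_fraction(d, scenario$pheno, "cc"), config)
    fs <- forward_scene(met[i, ], cs, met$theta[i], d, scenario, config)
    # a scene that did not settle is not a valid truth target; its
    # radiometric temperature is still emitted so the forcing is gapless
    if (fs$converged) for (cn in truth_cols) truth[[cn]][i] <- fs[[cn]]
    T_rad[i] <- fs$T_rad
  }
  if (noisy)
    T_rad <- .with_seed(scenario$seed + 2L,
                        T_rad + stats::rnorm(n, 0, scenario$noise$trad))
  met$T_rad <- T_rad
  met$L_out <- emit_lout(T_rad, met$L_in, config$radiation$emis_trad)
  met$Rn <- ifelse(day, truth$Rn_total, NA_real_)
  met$G <- truth$G
  met$H <- truth$H_ov + truth$H_un + truth$H_soil
  met$LE <- truth$LE_total
  list(met = met, lai = lai, truth = truth)
}
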