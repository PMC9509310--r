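# Radiation partitioning among overstory (vine), understory (cover crop)
# and soil with a two-layer Campbell-Norman-style scheme, plus the ground
# heat flux.

#' Split global shortwave into direct-beam and diffuse components
#'
#' Uses the clearness index `kt = SW_in / (S0 * E0 * cos(theta))` and the
#' Erbs diffuse-fraction correlation, with the overcast branch
#' (`kt <= kt_overcast`) treated as fully diffuse. At night both
#' components are zero.
#'
#' @param SW_in global shortwave irradiance (W m-2).
#' @param cos_theta cosine of the solar zenith angle.
#' @param doy day of year (for the sun-earth distance factor).
#' @param config a [seb_config()] object.
#' @return list with `S_dir` and `S_dif` (W m-2), `S_dir + S_dif = SW_in`.
#' @export
split_direct_diffuse <- function(SW_in, cos_theta, doy, config = seb_config()) {
  E0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
  pot <- seb_constants$solar_constant * E0 * pmax(cos_theta, 0)
  kt <- ifelse(pot > 1, pmin(SW_in / pot, 1), 0)
  fd <- ifelse(kt <= config$radiation$kt_overcast, 1,
        ifelse(kt <= config$radiation$kt_clear,
               0.9511 - 0.1604 * kt + 4.388 * kt^2 - 16.638 * kt^3 + 12.336 * kt^4,
               0.165))
  fd <- pmin(pmax(fd, 0), 1)
  night <- SW_in <= 0 | cos_theta <= 0
  fd[night] <- 1
  S_dif <- fd * pmax(SW_in, 0)
  list(S_dir = pmax(SW_in, 0) - S_dif, S_dif = S_dif)
}

# per-band, per-stream interaction of one vegetation layer:
# of incident I, absorbed = (1-rho)(1-tau) I, reflected = rho (1-tau) I,
# transmitted = tau I -- exact closure by construction. Scattering enters
# through the sqrt(absorptivity) scaling of the optical depth
# (Campbell-Norman) and the deep-canopy reflectance rho_h adjusted by the
# stream's extinction coefficient.
.layer_sw <- function(I, omega_F, k_stream, absorp) {
  sa <- sqrt(absorp)
  tau <- exp(-sa * k_stream * omega_F)
  rho_h <- (1 - sa) / (1 + sa)
  rho <- rho_h * 2 * k_stream / (k_stream + 1)
  list(absorbed = (1 - rho) * (1 - tau) * I,
       reflected = rho * (1 - tau) * I,
       transmitted = tau * I)
}

#' Three-source net radiation budget
#'
#' Partitions net radiation among overstory, understory and soil.
#' Shortwave: the incoming beam and diffuse streams are split into PAR
#' and NIR bands and attenuated through the overstory and then the
#' understory by Beer's law with clumping-corrected optical depth; the
#' overstory shadow therefore reduces the direct beam reaching the
#' understory and soil. Soil-reflected shortwave makes a single upward
#' pass. Longwave: a single downward and upward pass of sky, foliage and
#' soil emission through the same gap-fraction transmittances,
#' re-linearized each solver iteration through the current component
#' temperatures. The per-layer budget closes on the total by
#' construction.
#'
#' @param SW_in global shortwave irradiance (W m-2).
#' @param L_in incoming longwave radiation (W m-2).
#' @param T_ov,T_un,T_soil component temperatures (K).
#' @param canopy a [canopy_state()] object.
#' @param theta solar zenith angle (rad); values past horizon are
#'   treated as all-diffuse.
#' @param doy day of year.
#' @param config a [seb_config()] object.
#' @return list with `Rn_ov`, `Rn_un`, `Rn_soil`, `Rn_total`, `S_dir`,
#'   `S_dif`, `SW_up`, `L_up` (all W m-2).
#' @export
net_radiation_three_source <- function(SW_in, L_in, T_ov, T_un, T_soil,
                                       canopy, theta, doy,
                                       config = seb_config()) {
  pre <- rad_precompute(SW_in, canopy, theta, doy, config)
  rad_budget(pre, L_in, T_ov, T_un, T_soil, config)
}

#' Precompute the temperature-independent part of the radiation budget
#'
#' Shortwave absorption per layer and the longwave gap-fraction
#' transmittances depend only on geometry, not on the component
#' temperatures; the solver computes them once per record and reuses them
#' across iterations via [rad_budget()].
#'
#' @inheritParams net_radiation_three_source
#' @return opaque list consumed by [rad_budget()].
#' @export
rad_precompute <- function(SW_in, canopy, theta, doy, config = seb_config()) {
  cc <- config$canopy
  x <- cc$x_lad
  oF_ov <- canopy$Omega_vine * canopy$LAI_vine
  oF_un <- canopy$Omega_cc * canopy$LAI_cc

  cosz <- cos(theta)
  sun_up <- is.finite(theta) && theta < pi / 2 - 1e-6 && SW_in > 0
  sp <- split_direct_diffuse(SW_in, if (sun_up) cosz else 0, doy, config)
  kb <- if (sun_up) beam_extinction_kb(theta, x) else 1
  kd_ov <- diffuse_extinction_kd(oF_ov, x)
  kd_un <- diffuse_extinction_kd(oF_un, x)

  bands <- c(par = cc$par_fraction, nir = 1 - cc$par_fraction)
  sw_ov <- sw_un <- sw_soil <- sw_up <- 0
  for (b in names(bands)) {
    a <- cc$absorptivity[[b]]
    for (stream in c("dir", "dif")) {
      I0 <- bands[[b]] * (if (stream == "dir") sp$S_dir else sp$S_dif)
      k_ov <- if (stream == "dir") kb else kd_ov
      k_un <- if (stream == "dir") kb else kd_un
      L1 <- .layer_sw(I0, oF_ov, k_ov, a)
      L2 <- .layer_sw(L1$transmitted, oF_un, k_un, a)
      soil_in <- L2$transmitted
      soil_abs <- (1 - cc$albedo_soil) * soil_in
      up <- cc$albedo_soil * soil_in
      # single upward diffuse pass; each layer absorbs (1-tau)(1-rho) of
      # what reaches it, the remainder continues to space
      U2 <- .layer_sw(up, oF_un, kd_un, a)                  # soil reflection, understory
      U1 <- .layer_sw(up - U2$absorbed, oF_ov, kd_ov, a)    # ... then overstory
      R2 <- .layer_sw(L2$reflected, oF_ov, kd_ov, a)        # understory reflection, overstory
      sw_ov <- sw_ov + L1$absorbed + U1$absorbed + R2$absorbed
      sw_un <- sw_un + L2$absorbed + U2$absorbed
      sw_soil <- sw_soil + soil_abs
      sw_up <- sw_up + L1$reflected +
        (up - U2$absorbed - U1$absorbed) +
        (L2$reflected - R2$absorbed)
    }
  }
  list(sw_ov = sw_ov, sw_un = sw_un, sw_soil = sw_soil, sw_up = sw_up,
       S_dir = sp$S_dir, S_dif = sp$S_dif,
       tL_ov = diffuse_transmittance(oF_ov, x),
       tL_un = diffuse_transmittance(oF_un, x))
}

#' Complete a radiation budget from precomputed geometry
#'
#' Adds the linearized longwave exchange for the current component
#' temperatures to a [rad_precompute()] result.
#'
#' @param pre result of [rad_precompute()].
#' @inheritParams net_radiation_three_source
#' @return list as documented in [net_radiation_three_source()].
#' @export
rad_budget <- function(pre, L_in, T_ov, T_un, T_soil, config = seb_config()) {
  cc <- config$canopy
  sig <- seb_constants$sigma
  ev <- cc$emis_veg; es <- cc$emis_soil
  tL_ov <- pre$tL_ov; tL_un <- pre$tL_un
  E_ov <- ev * sig * T_ov^4
  E_un <- ev * sig * T_un^4
  L_d1 <- tL_ov * L_in + (1 - tL_ov) * E_ov
  L_d2 <- tL_un * L_d1 + (1 - tL_un) * E_un
  L_u0 <- es * sig * T_soil^4 + (1 - es) * L_d2
  L_u1 <- tL_un * L_u0 + (1 - tL_un) * E_un
  L_u2 <- tL_ov * L_u1 + (1 - tL_ov) * E_ov
  Rn_ov <- pre$sw_ov + (L_in - L_d1) + (L_u1 - L_u2)
  Rn_un <- pre$sw_un + (L_d1 - L_d2) + (L_u0 - L_u1)
  Rn_soil <- pre$sw_soil + (L_d2 - L_u0)
  list(Rn_ov = Rn_ov, Rn_un = Rn_un, Rn_soil = Rn_soil,
       Rn_total = Rn_ov + Rn_un + Rn_soil,
       S_dir = pre$S_dir, S_dif = pre$S_dif,
       SW_up = pre$sw_up, L_up = L_u2)
}

#' Soil (ground) heat flux
#'
#' Ratio mode estimates G as a fixed fraction (default 0.35) of the net
#' radiation reaching the soil, applied at all hours; observed mode
#' passes tower G through unchanged.
#'
#' @param Rn_soil net radiation at the soil (W m-2).
#' @param mode `"ratio"` or `"observed"`.
#' @param G_obs observed soil heat flux (W m-2), required in observed
#'   mode.
#' @param g_ratio the ratio used in ratio mode.
#' @return soil heat flux (W m-2).
#' @export
soil_heat_flux <- function(Rn_soil, mode = c("ratio", "observed"),
                           G_obs = NULL, g_ratio = 0.35) {
  mode <- match.arg(mode)
  if (mode == "ratio") return(g_ratio * Rn_soil)
  if (is.null(G_obs) || anyNA(G_obs))
    stop("observed mode requires G_obs at every timestamp")
  G_obs
}
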