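# Aerodynamic and boundary-layer resistances of the series/parallel heat
# transport network, under Monin-Obukhov similarity with stability
# iteration.

#' Roughness parameters from canopy height
#'
#' Standard fractions of canopy height: displacement `d = 0.65 h_c`,
#' momentum roughness `z0m = 0.125 h_c`, and thermal roughness
#' `z0h = z0m / exp(kB_inv)` with `kB_inv = 2` by default.
#'
#' @param h_c canopy height (m), must be below the measurement heights.
#' @param config a [seb_config()] object.
#' @return list with `d`, `z0m`, `z0h` (m).
#' @export
roughness <- function(h_c, config = seb_config()) {
  stopifnot(h_c > 0)
  if (h_c >= min(config$site$z_u, config$site$z_T))
    stop("canopy height must be below the measurement heights")
  rc <- config$resistances
  d <- rc$d_ratio * h_c
  z0m <- rc$z0m_ratio * h_c
  list(d = d, z0m = z0m, z0h = z0m / exp(rc$kB_inv))
}

#' Dyer-Businger stability correction functions
#'
#' Integrated similarity functions for momentum (`psi_m`) and heat
#' (`psi_h`) as a function of `zeta = z/L`. Unstable branch uses the
#' Businger-Dyer forms; stable branch is linear, `-5 zeta`.
#'
#' @param zeta dimensionless height z/L.
#' @return the stability correction (unitless, added inside the log law).
#' @export
psi_m <- function(zeta) {
  out <- numeric(length(zeta))
  un <- zeta < 0
  x <- (1 - 16 * pmin(zeta[un], 0))^0.25
  out[un] <- 2 * log((1 + x) / 2) + log((1 + x^2) / 2) - 2 * atan(x) + pi / 2
  out[!un] <- -5 * pmin(zeta[!un], 2)   # clipped for very stable cases
  out
}

#' @rdname psi_m
#' @export
psi_h <- function(zeta) {
  out <- numeric(length(zeta))
  un <- zeta < 0
  x2 <- sqrt(1 - 16 * pmin(zeta[un], 0))
  out[un] <- 2 * log((1 + x2) / 2)
  out[!un] <- -5 * pmin(zeta[!un], 2)
  out
}

#' Friction velocity under the current stability
#'
#' @param u wind speed (m s-1) at height `z_u`.
#' @param z_u wind measurement height (m).
#' @param rough roughness list from [roughness()].
#' @param L_mo Obukhov length (m); `Inf` for neutral.
#' @return friction velocity (m s-1).
#' @export
friction_velocity <- function(u, z_u, rough, L_mo = Inf) {
  k <- seb_constants$karman
  zp <- z_u - rough$d
  denom <- log(zp / rough$z0m) - psi_m(zp / L_mo) + psi_m(rough$z0m / L_mo)
  pmax(k * u / pmax(denom, 0.1), 1e-3)
}

#' Aerodynamic resistance to heat transfer
#'
#' Monin-Obukhov bulk resistance between the surface source height and
#' the measurement heights:
#' `R_A = [ln((z_T-d)/z0h) - Psi_h] [ln((z_u-d)/z0m) - Psi_m] / (k^2 u)`,
#' with the Dyer-Businger corrections evaluated at the current Obukhov
#' length (differences between measurement and roughness level). The
#' neutral limit recovers the log-law form. Wind is floored at the
#' configured minimum.
#'
#' @param u wind speed (m s-1).
#' @param z_u,z_T wind and temperature measurement heights (m).
#' @param rough roughness list from [roughness()].
#' @param L_mo Obukhov length (m); `Inf` for neutral.
#' @param config a [seb_config()] object.
#' @return aerodynamic resistance (s m-1), positive and finite.
#' @export
aerodynamic_resistance <- function(u, z_u, z_T, rough, L_mo = Inf,
                                   config = seb_config()) {
  k <- seb_constants$karman
  u <- pmax(u, config$resistances$u_floor)
  zpu <- z_u - rough$d
  zpt <- z_T - rough$d
  term_m <- log(zpu / rough$z0m) - psi_m(zpu / L_mo) + psi_m(rough$z0m / L_mo)
  term_h <- log(zpt / rough$z0h) - psi_h(zpt / L_mo) + psi_h(rough$z0h / L_mo)
  ra <- pmax(term_h, 0.1) * pmax(term_m, 0.1) / (k^2 * u)
  pmax(ra, 1)
}

#' Wind speed within and below the canopy
#'
#' Neutral log-profile wind at the canopy top, then Goudriaan-type
#' exponential extinction inside the canopy with attenuation coefficient
#' `a = 0.28 LAI^(2/3) h_c^(1/3) s^(-1/3)` (s = leaf size).
#'
#' @param u wind speed at `z_u` (m s-1).
#' @param z_u measurement height (m).
#' @param h_c canopy height (m).
#' @param LAI canopy leaf area index.
#' @param z target height (m), below `h_c`.
#' @param rough roughness list from [roughness()].
#' @param config a [seb_config()] object.
#' @return wind speed at height `z` (m s-1).
#' @export
canopy_wind <- function(u, z_u, h_c, LAI, z, rough, config = seb_config()) {
  rc <- config$resistances
  u <- pmax(u, rc$u_floor)
  u_c <- u * log(pmax(h_c - rough$d, rough$z0m * 1.05) / rough$z0m) /
    log((z_u - rough$d) / rough$z0m)
  u_c <- pmax(u_c, 0.05)
  a <- 0.28 * pmax(LAI, 0.05)^(2 / 3) * h_c^(1 / 3) * rc$leaf_size^(-1 / 3)
  pmax(u_c * exp(-a * (1 - pmin(z, h_c) / h_c)), 0.01)
}

#' Boundary-layer resistances of the canopy, soil and substrate
#'
#' Standard two-source-model formulations from the thermal
#' remote-sensing literature:
#' \itemize{
#'   \item `R_x = (C'/LAI) * (s/U_d)^(1/2)` with `U_d` the wind speed at
#'     the understory source height from the in-canopy profile;
#'   \item `R_s = 1 / (c (T_soil - T_AC)^(1/3) + b u_s)` with `u_s` the
#'     wind just above the soil (free + forced convection);
#'   \item `R_sub`: an `R_s`-type resistance evaluated at the substrate
#'     (understory canopy top) level with the substrate-air temperature
#'     difference.
#' }
#' Temperature differences are floored at zero inside the cube root.
#'
#' @param u wind speed at `z_u` (m s-1).
#' @param canopy a [canopy_state()] object.
#' @param rough roughness list of the overstory.
#' @param dT_soil `T_soil - T_AC` (K) for the free-convection term of `R_s`.
#' @param dT_sub `T_sub - T_A` (K) for the free-convection term of `R_sub`.
#' @param config a [seb_config()] object.
#' @return list with `R_x`, `R_s`, `R_sub` (s m-1) and the wind speeds
#'   `U_d`, `u_s`, `u_sub` used.
#' @export
boundary_resistances <- function(u, canopy, rough, dT_soil = 0, dT_sub = 0,
                                 config = seb_config()) {
  rc <- config$resistances
  h_ov <- canopy$h_c_vine
  z_sub <- max(canopy$h_c_cc, rc$z_soil)
  # wind at the understory canopy top and just above the soil; below the
  # understory top the cover-crop foliage attenuates further
  u_sub <- canopy_wind(u, config$site$z_u, h_ov, canopy$LAI_vine, z_sub,
                       rough, config)
  if (canopy$LAI_cc > 0.01 && rc$z_soil < canopy$h_c_cc) {
    a_un <- 0.28 * canopy$LAI_cc^(2 / 3) * canopy$h_c_cc^(1 / 3) *
      rc$leaf_size^(-1 / 3)
    u_s <- pmax(u_sub * exp(-a_un * (1 - rc$z_soil / canopy$h_c_cc)), 0.01)
  } else {
    u_s <- canopy_wind(u, config$site$z_u, h_ov, canopy$LAI_vine, rc$z_soil,
                       rough, config)
  }
  U_d <- u_sub
  lai_x <- max(canopy$LAI_cc, 0.2)   # keeps R_x finite for sparse cover
  R_x <- (rc$C_prime / lai_x) * sqrt(rc$leaf_size / U_d)
  R_s <- 1 / (rc$c_coef * max(dT_soil, 0)^(1 / 3) + rc$b_coef * u_s)
  R_sub <- 1 / (rc$c_coef * max(dT_sub, 0)^(1 / 3) + rc$b_coef * u_sub)
  list(R_x = R_x, R_s = R_s, R_sub = R_sub,
       U_d = U_d, u_s = u_s, u_sub = u_sub)
}

#' Obukhov length
#'
#' `L = -rho Cp u*^3 T_A / (k g H)`; returns `Inf` (neutral) when `H` is
#' zero and clips `|L|` at the configured minimum.
#'
#' @param u_star friction velocity (m s-1).
#' @param T_A air temperature (K).
#' @param H_total total sensible heat flux (W m-2).
#' @param rhocp volumetric heat capacity (J m-3 K-1).
#' @param L_min minimum |L| (m).
#' @return Obukhov length (m), signed; `Inf` for neutral.
#' @export
obukhov_length <- function(u_star, T_A, H_total, rhocp, L_min = 1) {
  if (!is.finite(H_total) || H_total == 0) return(Inf)
  L <- -rhocp * u_star^3 * T_A /
    (seb_constants$karman * seb_constants$gravity * H_total)
  sign(L) * max(abs(L), L_min)
}

#' Monin-Obukhov stability iteration
#'
#' Fixed-point iteration between the friction velocity and the Obukhov
#' length for a given total sensible heat flux, until the relative change
#' in `L` is below `tol` (default 1e-3) or `max_iter` is reached. On
#' non-convergence the neutral state is returned with a flag.
#'
#' @param H_total total sensible heat flux (W m-2).
#' @param u wind speed (m s-1).
#' @param T_A air temperature (K).
#' @param p air pressure (kPa).
#' @param e_a vapor pressure (kPa).
#' @param rough roughness list from [roughness()].
#' @param config a [seb_config()] object.
#' @param tol relative convergence tolerance on `L`.
#' @param max_iter maximum number of iterations.
#' @return list with `L_mo`, `u_star`, `d`, `z0m`, `z0h`, `converged`,
#'   `n_iter`.
#' @export
stability_iteration <- function(H_total, u, T_A, p, e_a, rough,
                                config = seb_config(), tol = 1e-3,
                                max_iter = 50) {
  stopifnot(is.finite(H_total))
  u <- max(u, config$resistances$u_floor)
  rhocp <- rho_cp(T_A, p, e_a)
  L <- Inf
  converged <- FALSE
  n <- 0
  if (H_total == 0) {
    u_star <- friction_velocity(u, config$site$z_u, rough, Inf)
    converged <- TRUE
  } else {
    for (n in seq_len(max_iter)) {
      u_star <- friction_velocity(u, config$site$z_u, rough, L)
      L_new <- obukhov_length(u_star, T_A, H_total, rhocp,
                              config$resistances$L_min)
      if (is.finite(L) && abs(L_new - L) / abs(L) < tol) {
        L <- L_new
        converged <- TRUE
        break
      }
      L <- L_new
    }
    if (!converged) {
      L <- Inf
      u_star <- friction_velocity(u, config$site$z_u, rough, Inf)
    }
  }
  list(L_mo = L, u_star = u_star, d = rough$d, z0m = rough$z0m,
       z0h = rough$z0h, converged = converged, n_iter = n)
}
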