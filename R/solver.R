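# Nested three-source energy balance solver (3SEB) and its two-source
# configuration (TSEB baseline). Per daytime timestamp: Priestley-Taylor
# canopy initialization, radiometric temperature decomposition, series/
# parallel resistance network, Monin-Obukhov stability, and iterative
# reduction of the Priestley-Taylor coefficient until the balance is
# physically realistic (no daytime condensation / negative latent heat).

#' Priestley-Taylor canopy flux initialization
#'
#' `LE_c = Rn_c * alpha_c * fg_c * Delta / (Delta + gamma)` and
#' `H_c = Rn_c - LE_c`, with Delta the Magnus-type saturation vapor
#' pressure slope at air temperature and gamma the psychrometric
#' constant. Negative canopy net radiation yields `LE_c = 0`.
#'
#' @param Rn_c canopy net radiation (W m-2).
#' @param fg_c green fraction of the layer in [0, 1].
#' @param alpha_c Priestley-Taylor coefficient (>= 0).
#' @param T_A air temperature (K).
#' @param p air pressure (kPa).
#' @return list with `LE_c` and `H_c` (W m-2).
#' @export
pt_canopy_flux <- function(Rn_c, fg_c, alpha_c, T_A, p) {
  stopifnot(alpha_c >= 0, fg_c >= 0, fg_c <= 1)
  delta <- esat_slope(T_A)
  gamma <- psychrometric_gamma(T_A, p)
  LE_c <- ifelse(Rn_c > 0, Rn_c * alpha_c * fg_c * delta / (delta + gamma), 0)
  list(LE_c = LE_c, H_c = Rn_c - LE_c)
}

#' Compose a radiometric temperature from two components
#'
#' Fourth-power (Stefan-Boltzmann) mixing:
#' `T = (f * T_a^4 + (1 - f) * T_b^4)^(1/4)`.
#'
#' @param f viewed fraction of component `a`, in [0, 1).
#' @param T_a,T_b component temperatures (K).
#' @return composite temperature (K).
#' @export
compose_trad <- function(f, T_a, T_b) {
  (f * T_a^4 + (1 - f) * T_b^4)^0.25
}

#' Decompose a radiometric temperature given one component
#'
#' Inverts [compose_trad()] for the unseen component:
#' `T_b = ((T^4 - f * T_a^4) / (1 - f))^(1/4)`. A non-positive radicand
#' means the known component is too hot to be consistent with the
#' composite; this is a hard error here, while the solver handles it by
#' flagging the record.
#'
#' @param T_comp composite radiometric temperature (K).
#' @param f viewed fraction of the known component, in [0, 1).
#' @param T_known known component temperature (K).
#' @return temperature of the remaining component (K).
#' @export
decompose_trad <- function(T_comp, f, T_known) {
  r <- .decompose_guarded(T_comp, f, T_known)
  if (!r$ok)
    stop("non-physical component temperature: T_rad^4 - f*T_known^4 <= 0")
  r$T
}

.decompose_guarded <- function(T_comp, f, T_known, floor_T = 150) {
  if (f <= 0) return(list(T = T_comp, ok = TRUE))
  radicand <- (T_comp^4 - f * T_known^4) / (1 - f)
  if (radicand <= floor_T^4) list(T = floor_T, ok = FALSE)
  else list(T = radicand^0.25, ok = TRUE)
}

# one record, nested network. `met` is a list/one-row data.frame with
# SW_in, L_in, T_A, e_a, u, p; theta is the solar zenith (rad).
solve_seb_record <- function(met, T_rad, canopy, theta, doy,
                             config = seb_config(), g_mode = "ratio",
                             G_obs = NA_real_) {
  sv <- config$solver
  rhocp <- rho_cp(met$T_A, met$p, met$e_a)

  kb_view <- beam_extinction_kb(sv$view_zenith, config$canopy$x_lad)
  f_ov <- fraction_viewed(canopy$LAI_vine, canopy$Omega_vine, kb_view)
  f_un <- if (canopy$LAI_cc > 0)
    fraction_viewed(canopy$LAI_cc, canopy$Omega_cc, kb_view) else 0
  rough <- roughness(canopy$h_c_vine, config)
  pre <- rad_precompute(met$SW_in, canopy, theta, doy, config)

  alpha_ov <- alpha_un <- sv$alpha_pt_max
  understory <- canopy$LAI_cc > 0 && canopy$fg_cc > 0
  T_ov <- T_un <- T_soil <- T_sub <- T_rad
  T_AC <- met$T_A
  L_mo <- Inf
  H_total <- 0
  flag <- ""
  converged <- FALSE
  n_outer <- 0
  u_star <- NA_real_

  for (outer in seq_len(sv$max_iter)) {
    n_outer <- outer
    ok_decomp <- TRUE
    # settle temperatures and stability at the current alpha state
    for (inner in seq_len(sv$inner_max)) {
      rad <- rad_budget(pre, met$L_in, T_ov, T_un, T_soil, config)
      G <- soil_heat_flux(rad$Rn_soil, g_mode, G_obs, config$radiation$g_ratio)
      R_A <- aerodynamic_resistance(met$u, config$site$z_u, config$site$z_T,
                                    rough, L_mo, config)
      bres <- boundary_resistances(met$u, canopy, rough,
                                   dT_soil = T_soil - T_AC,
                                   dT_sub = T_sub - met$T_A, config)
      pt_ov <- pt_canopy_flux(rad$Rn_ov, canopy$fg_vine, alpha_ov,
                              met$T_A, met$p)
      LE_ov <- pt_ov$LE_c; H_ov <- pt_ov$H_c
      T_ov_new <- met$T_A + H_ov * R_A / rhocp

      d1 <- .decompose_guarded(T_rad, f_ov, T_ov_new)
      T_sub_new <- d1$T
      ok_decomp <- d1$ok
      H_sub <- rhocp * (T_sub_new - met$T_A) / (R_A + bres$R_sub)
      T_AC_new <- met$T_A + H_sub * R_A / rhocp

      pt_un <- pt_canopy_flux(rad$Rn_un, canopy$fg_cc, alpha_un,
                              met$T_A, met$p)
      LE_un <- pt_un$LE_c; H_un <- pt_un$H_c
      T_un_new <- T_AC_new + H_un * bres$R_x / rhocp
      d2 <- .decompose_guarded(T_sub_new, f_un, T_un_new)
      T_soil_new <- d2$T
      ok_decomp <- ok_decomp && d2$ok
      H_soil <- rhocp * (T_soil_new - T_AC_new) / bres$R_s
      LE_soil <- rad$Rn_soil - H_soil - G
      H_total <- H_ov + H_un + H_soil

      # one Monin-Obukhov update per pass; the loop iterates u*, L and the
      # temperatures to joint convergence
      u_star <- friction_velocity(met$u, config$site$z_u, rough, L_mo)
      L_new <- obukhov_length(u_star, met$T_A, H_total, rhocp,
                              config$resistances$L_min)
      dmax <- max(abs(T_ov_new - T_ov), abs(T_un_new - T_un),
                  abs(T_soil_new - T_soil))
      # under-relaxation stabilizes the temperature/stability fixed point;
      # the reported state is always the last consistently computed one
      # (T_*_rep), which satisfies the balance and radiometric identities
      # by construction
      T_ov_rep <- T_ov_new; T_un_rep <- T_un_new; T_soil_rep <- T_soil_new
      T_sub_rep <- T_sub_new; T_AC_rep <- T_AC_new
      w <- sv$relax
      T_ov <- T_ov + w * (T_ov_new - T_ov)
      T_un <- T_un + w * (T_un_new - T_un)
      T_soil <- T_soil + w * (T_soil_new - T_soil)
      T_sub <- T_sub + w * (T_sub_new - T_sub)
      T_AC <- T_AC + w * (T_AC_new - T_AC)
      L_ch <- if (is.finite(L_mo) && is.finite(L_new))
        abs(L_new - L_mo) / abs(L_mo) else as.numeric(is.finite(L_mo) != is.finite(L_new))
      L_mo <- L_new
      if (dmax < sv$tol_T && L_ch < sv$tol_L) break
    }

    # realism checks: no daytime condensation / negative LE in any source.
    # The violation threshold matches the energy-balance tolerance
    # (tol_le, 0.1 W m-2): sub-tolerance dips are clamped after
    # convergence instead of triggering a full alpha step.
    # Reducing a layer's alpha only helps while that layer is actually
    # transpiring (warming it lowers the derived soil temperature).
    if (LE_soil < -sv$tol_le) {
      if (understory && alpha_un > 0 && LE_un > 1e-9) {
        alpha_un <- max(alpha_un - sv$alpha_step, 0); next
      }
      if (alpha_ov > 0 && canopy$fg_vine > 0 && LE_ov > 1e-9) {
        alpha_ov <- max(alpha_ov - sv$alpha_step, 0); next
      }
      # soil has no alpha left to reduce: pin evaporation to zero
      LE_soil <- 0
      H_soil <- rad$Rn_soil - G
      H_total <- H_ov + H_un + H_soil
      flag <- "soil_LE_pinned"
      break
    }
    if (LE_un < -sv$tol_le) {
      if (alpha_un > 0) { alpha_un <- max(alpha_un - sv$alpha_step, 0); next }
      LE_un <- 0; H_un <- rad$Rn_un; flag <- "understory_LE_pinned"; break
    }
    if (LE_ov < -sv$tol_le) {
      if (alpha_ov > 0) { alpha_ov <- max(alpha_ov - sv$alpha_step, 0); next }
      LE_ov <- 0; H_ov <- rad$Rn_ov; flag <- "overstory_LE_pinned"; break
    }
    if (!ok_decomp) { flag <- "nonphysical_decomposition"; break }
    converged <- TRUE
    break
  }
  if (!converged && flag == "") flag <- "max_iterations"
  if (converged && LE_soil < 0) {
    # sub-tolerance condensation: fold the residual back into H_soil so
    # the reported partition has no negative daytime LE
    LE_soil <- 0
    H_soil <- rad$Rn_soil - G
    H_total <- H_ov + H_un + H_soil
  }

  list(Rn_ov = rad$Rn_ov, Rn_un = rad$Rn_un, Rn_soil = rad$Rn_soil,
       Rn_total = rad$Rn_total,
       H_ov = H_ov, H_un = H_un, H_soil = H_soil, H_total = H_total,
       LE_ov = LE_ov, LE_un = LE_un, LE_soil = LE_soil,
       LE_total = LE_ov + LE_un + LE_soil,
       G = G,
       T_ov = T_ov_rep, T_un = T_un_rep, T_soil = T_soil_rep,
       T_sub = T_sub_rep, T_AC = T_AC_rep,
       alpha_ov = alpha_ov, alpha_un = alpha_un,
       f_ov_view = f_ov, f_un_view = f_un,
       R_A = R_A, R_x = bres$R_x, R_s = bres$R_s, R_sub = bres$R_sub,
       L_mo = L_mo, u_star = u_star,
       converged = converged, n_iter = n_outer, flag = flag)
}

# an all-NA record for nighttime / unsolvable timestamps
.na_record <- function(flag = "night") {
  out <- as.list(rep(NA_real_, 29))
  names(out) <- c("Rn_ov", "Rn_un", "Rn_soil", "Rn_total",
                  "H_ov", "H_un", "H_soil", "H_total",
                  "LE_ov", "LE_un", "LE_soil", "LE_total", "G",
                  "T_ov", "T_un", "T_soil", "T_sub", "T_AC",
                  "alpha_ov", "alpha_un", "f_ov_view", "f_un_view",
                  "R_A", "R_x", "R_s", "R_sub",
                  "L_mo", "u_star", "n_iter")
  out$converged <- NA
  out$flag <- flag
  out
}

#' Solve the three-source energy balance for one timestamp
#'
#' Solves the nested overstory / understory / soil balance: the surface
#' is first split into a parallel overstory-substrate system using the
#' radiometric temperature, then the substrate is split into its
#' vegetation and soil sources through a series network. Canopy latent
#' heat is initialized with the Priestley-Taylor formulation
#' (alpha = 1.26) and alpha is reduced per layer, in 0.1 steps, until no
#' source shows daytime condensation (negative LE); atmospheric
#' stability is iterated jointly.
#'
#' @param met one-row data.frame or list with `SW_in`, `L_in`, `T_A`,
#'   `e_a`, `u`, `p`.
#' @param T_rad radiometric surface temperature (K).
#' @param canopy a [canopy_state()] object.
#' @param theta solar zenith angle (rad).
#' @param doy day of year.
#' @param config a [seb_config()] object.
#' @param g_mode `"ratio"` (G = 0.35 Rn_soil) or `"observed"`.
#' @param G_obs observed soil heat flux (W m-2) for `g_mode = "observed"`.
#' @return named list (one flux partition): per-source `Rn`, `H`, `LE`,
#'   `G`, component temperatures, final Priestley-Taylor coefficients,
#'   resistances, stability state, convergence flag and iteration count.
#'   Nighttime records (SW_in at or below the daytime threshold) return
#'   all-NA fluxes with flag `"night"`.
#' @export
solve_3seb <- function(met, T_rad, canopy, theta, doy,
                       config = seb_config(), g_mode = "ratio",
                       G_obs = NA_real_) {
  if (is.na(met$SW_in) || met$SW_in <= config$daytime_sw_min || is.na(T_rad))
    return(.na_record("night"))
  solve_seb_record(met, T_rad, canopy, theta, doy, config, g_mode, G_obs)
}

#' Solve the two-source (TSEB) baseline for one timestamp
#'
#' The two-source configuration of the same nested network: a single
#' bulk vegetation layer (vine + cover-crop LAI combined, LAI-weighted
#' green fraction, structure mapped from the bulk LAI) coupled through
#' the aerodynamic resistance, and the soil as the substrate. It is the
#' structural limit of [solve_3seb()] with the understory removed.
#'
#' @inheritParams solve_3seb
#' @return as [solve_3seb()]; understory fields are zero/degenerate.
#' @export
solve_tseb <- function(met, T_rad, canopy, theta, doy,
                       config = seb_config(), g_mode = "ratio",
                       G_obs = NA_real_) {
  bulk <- bulk_canopy_state(canopy, config)
  solve_3seb(met, T_rad, bulk, theta, doy, config, g_mode, G_obs)
}

#' Collapse a three-source canopy state to a single bulk layer
#'
#' Bulk LAI is the sum of the vine and cover-crop LAI; the bulk green
#' fraction is the LAI-weighted mean; structure and clumping are
#' re-derived from the bulk LAI.
#'
#' @param canopy a [canopy_state()] object.
#' @param config a [seb_config()] object.
#' @return a [canopy_state()] object with `LAI_cc = 0`.
#' @export
bulk_canopy_state <- function(canopy, config = seb_config()) {
  lai <- canopy$LAI_vine + canopy$LAI_cc
  fg <- if (lai > 0)
    (canopy$LAI_vine * canopy$fg_vine + canopy$LAI_cc * canopy$fg_cc) / lai
  else 0
  canopy_state(LAI_vine = lai, LAI_cc = 0, fg_vine = fg, fg_cc = 0,
               config = config)
}
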