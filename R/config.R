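# Site, canopy, phenology and solver configuration with field-typical
# defaults for a semi-arid trellised vineyard with an interrow cover crop.

#' Phenology configuration for LAI decomposition
#'
#' Day-of-year anchors and time constants governing how ecosystem LAI is
#' split into vine and cover-crop (CC) components. The CC is assumed to
#' carry the whole ecosystem LAI before vine budbreak and after vine
#' leaf-off; between budbreak and peak summer it decays exponentially
#' (mowing + senescence) and it regrows exponentially after leaf-off.
#'
#' @param budbreak_doy day of year of vine budbreak.
#' @param leafoff_doy day of year of vine leaf-off.
#' @param decay_efolding_days e-folding time (days) of the CC decay,
#'   regrowth and green-fraction transitions.
#' @param lai_vine_floor minimum vine LAI (m2 m-2) kept year-round to
#'   represent woody elements (cordon, trunk, canes).
#' @param cc_present logical; is a cover crop present this season?
#' @param peak_doy day of year ending the CC decay ("peak summer"). `NA`
#'   means: use the day of maximum ecosystem LAI.
#' @return object of class `pheno_config` (a named list).
#' @export
pheno_config <- function(budbreak_doy = 80, leafoff_doy = 310,
                         decay_efolding_days = 21, lai_vine_floor = 0.4,
                         cc_present = TRUE, peak_doy = NA) {
  stopifnot(budbreak_doy >= 1, budbreak_doy <= 366,
            leafoff_doy >= 1, leafoff_doy <= 366,
            budbreak_doy < leafoff_doy,
            decay_efolding_days > 0, lai_vine_floor >= 0)
  structure(list(budbreak_doy = budbreak_doy, leafoff_doy = leafoff_doy,
                 decay_efolding_days = decay_efolding_days,
                 lai_vine_floor = lai_vine_floor, cc_present = cc_present,
                 peak_doy = peak_doy),
            class = "pheno_config")
}

#' Model configuration
#'
#' Builds the nested configuration list used by [threeseb()] and the
#' module-level functions. Any element can be overridden through `...`
#' using nested lists, e.g. `seb_config(site = list(lat = 40))`.
#'
#' Defaults describe a semi-arid trellised vineyard: east-west rows 3.35 m
#' apart, vine canopy 1.5-2.2 m tall, a 0.35 m herbaceous cover crop, and
#' tower instruments at 5 m.
#'
#' @param ... named nested-list overrides merged over the defaults.
#' @param pheno a [pheno_config()] object.
#' @return object of class `seb_config`.
#' @export
seb_config <- function(..., pheno = pheno_config()) {
  cfg <- list(
    site = list(
      lat = 36.85, lon = -120.1, elev = 61,
      z_u = 5, z_T = 5,          # wind / temperature measurement heights (m)
      row_width = 3.35,          # vine row spacing (m)
      timestamp_convention = "end"  # tower half-hour/hour labels mark interval ends
    ),
    canopy = list(
      x_lad = 1,                 # ellipsoidal leaf-angle parameter (spherical)
      leaf_width = 0.1,          # vine leaf width (m), used in R_x
      h_c_min = 1.5, h_c_max = 2.2,     # vine canopy height bounds (m)
      lai_at_hmin = 0.4, lai_at_hmax = 2.0,
      w_c_min = 0.2, w_c_max = 0.45,    # vine canopy-to-row-width fraction
      h_c_cc = 0.35, w_c_cc = 1,        # cover-crop height (m) and width fraction
      emis_veg = 0.98, emis_soil = 0.95,
      albedo_soil = 0.15,
      # leaf absorptivities per broadband: PAR and NIR
      absorptivity = c(par = 0.85, nir = 0.20),
      par_fraction = 0.45        # PAR fraction of global shortwave
    ),
    resistances = list(
      d_ratio = 0.65, z0m_ratio = 0.125, kB_inv = 2,
      C_prime = 90,              # bulk boundary-layer coefficient (s^1/2 m-1)
      leaf_size = 0.01,          # effective leaf size in R_x (m)
      b_coef = 0.012, c_coef = 0.0025,  # soil resistance coefficients
      u_floor = 0.1,             # minimum wind speed (m s-1)
      L_min = 1,                 # minimum |Obukhov length| (m)
      z_soil = 0.05              # reference height for wind just above soil (m)
    ),
    radiation = list(
      g_ratio = 0.35,            # G = g_ratio * Rn_soil
      kt_overcast = 0.22, kt_clear = 0.80,  # clearness-index breakpoints
      emis_trad = 1              # blackbody assumption for T_rad retrieval
    ),
    solver = list(
      alpha_pt_max = 1.26, alpha_step = 0.1,
      max_iter = 35,             # outer iterations (alpha sweep + stability)
      inner_max = 40, tol_T = 1e-3, tol_L = 1e-3,
      relax = 0.5,               # under-relaxation of temperature updates
      tol_le = 0.1,              # condensation threshold (W m-2), matches
                                 # the energy-balance tolerance
      view_zenith = 0            # radiometer view zenith angle (rad)
    ),
    daytime_sw_min = 100         # SW_in threshold (W m-2), strict
  )
  cfg$pheno <- pheno
  overrides <- list(...)
  if (length(overrides)) cfg <- modify_list_deep(cfg, overrides)
  structure(cfg, class = "seb_config")
}

# recursive version of utils::modifyList that keeps nested defaults
modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
        !inherits(base[[nm]], "pheno_config")) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Read a configuration from a YAML file
#'
#' YAML keys mirror the nested structure of [seb_config()]; a `pheno` block
#' is passed through [pheno_config()]. Missing keys keep their defaults.
#'
#' @param path path to a YAML file.
#' @return object of class `seb_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pheno <- if (!is.null(raw$pheno)) do.call(pheno_config, raw$pheno) else pheno_config()
  raw$pheno <- NULL
  do.call(seb_config, c(raw, list(pheno = pheno)))
}
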