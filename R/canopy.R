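# Canopy structure: decomposition of ecosystem LAI into vine and
# cover-crop layers, green fractions, beam/diffuse extinction, viewed
# fractions and structural parameters (height, width, clumping).

#' Decompose ecosystem LAI into vine and cover-crop components
#'
#' The cover crop (CC) is assumed to account for the whole ecosystem LAI
#' before vine budbreak and (asymptotically) after vine leaf-off. Between
#' budbreak and peak summer the CC LAI decays exponentially from its
#' budbreak value with the configured e-folding time (mowing followed by
#' senescence to stubble); between peak summer and leaf-off it holds its
#' senescent value; after leaf-off it regrows exponentially toward the
#' ecosystem LAI. The vine LAI is the remainder,
#' `LAI_vine = LAI_eco - LAI_cc`, floored year-round at
#' `lai_vine_floor` so that woody elements (trunk, cordon, canes) keep
#' acting on radiative and aerodynamic transfer during leaf-off.
#'
#' @param doy integer day-of-year vector (daily cadence, increasing).
#' @param LAI_eco daily ecosystem LAI (m2 m-2), same length as `doy`.
#' @param pheno a [pheno_config()] object.
#' @return data.frame with columns `doy`, `LAI_eco`, `LAI_vine`,
#'   `LAI_cc`.
#' @export
partition_lai <- function(doy, LAI_eco, pheno = pheno_config()) {
  stopifnot(length(doy) == length(LAI_eco))
  if (any(LAI_eco < 0, na.rm = TRUE)) stop("LAI_eco must be >= 0")
  if (pheno$budbreak_doy < min(doy) || pheno$leafoff_doy > max(doy))
    stop("phenology dates fall outside the supplied series")
  tau <- pheno$decay_efolding_days
  peak <- pheno$peak_doy
  if (is.na(peak)) peak <- doy[which.max(LAI_eco)]
  peak <- max(peak, pheno$budbreak_doy + 1)

  LAI_cc <- numeric(length(doy))
  if (pheno$cc_present) {
    at <- function(d) LAI_eco[which.min(abs(doy - d))]
    cc_bud <- at(pheno$budbreak_doy)
    cc_hold <- cc_bud * exp(-(peak - pheno$budbreak_doy) / tau)
    pre  <- doy < pheno$budbreak_doy
    dec  <- doy >= pheno$budbreak_doy & doy < peak
    hold <- doy >= peak & doy < pheno$leafoff_doy
    post <- doy >= pheno$leafoff_doy
    LAI_cc[pre] <- LAI_eco[pre]
    LAI_cc[dec] <- pmin(cc_bud * exp(-(doy[dec] - pheno$budbreak_doy) / tau),
                        LAI_eco[dec])
    LAI_cc[hold] <- pmin(cc_hold, LAI_eco[hold])
    eco_off <- at(pheno$leafoff_doy)
    LAI_cc[post] <- pmax(pmin(
      LAI_eco[post] + (cc_hold - eco_off) * exp(-(doy[post] - pheno$leafoff_doy) / tau),
      LAI_eco[post]), 0)
  }
  LAI_vine <- pmax(LAI_eco - LAI_cc, pheno$lai_vine_floor)
  data.frame(doy = doy, LAI_eco = LAI_eco, LAI_vine = LAI_vine, LAI_cc = LAI_cc)
}

#' Green fraction of a vegetation layer
#'
#' Fraction of a layer's leaf area that is photosynthetically active.
#' Vine foliage: 0 during leaf-off, rising exponentially to 1 after
#' budbreak and decaying exponentially over the last three e-folding
#' times before leaf-off. Cover crop: 1 in spring, decaying exponentially
#' from budbreak through the senescent summer, regrowing toward 1 after
#' vine leaf-off.
#'
#' @param doy day of year (vectorized).
#' @param pheno a [pheno_config()] object.
#' @param layer `"vine"` or `"cc"`.
#' @return green fraction in [0, 1].
#' @export
green_fraction <- function(doy, pheno = pheno_config(), layer = c("vine", "cc")) {
  layer <- match.arg(layer)
  tau <- pheno$decay_efolding_days
  bud <- pheno$budbreak_doy; off <- pheno$leafoff_doy
  if (layer == "vine") {
    fg <- ifelse(doy < bud | doy >= off, 0, 1 - exp(-(doy - bud) / tau))
    sen_start <- off - 3 * tau
    sen <- doy >= sen_start & doy < off
    fg[sen] <- fg[sen] * exp(-(doy[sen] - sen_start) / tau)
  } else {
    fg <- ifelse(doy < bud, 1,
          ifelse(doy < off, exp(-(doy - bud) / tau),
                 1 - (1 - exp(-(off - bud) / tau)) * exp(-(doy - off) / tau)))
  }
  pmin(pmax(fg, 0), 1)
}

#' Beam extinction coefficient of an ellipsoidal canopy
#'
#' Campbell-Norman ellipsoidal leaf-angle-distribution form:
#' `kb = sqrt(x^2 + tan(theta)^2) / (x + 1.774 * (x + 1.182)^(-0.733))`.
#'
#' @param theta beam zenith angle (rad), in [0, pi/2).
#' @param x_lad leaf-angle distribution parameter (1 = spherical).
#' @return extinction coefficient (unitless), vectorized over `theta`.
#' @export
beam_extinction_kb <- function(theta, x_lad = 1) {
  if (any(theta >= pi / 2 | theta < 0))
    stop("theta must be in [0, pi/2): sun below horizon must be gated by the caller")
  sqrt(x_lad^2 + tan(theta)^2) /
    (x_lad + 1.774 * (x_lad + 1.182)^(-0.733))
}

# Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
}
.gl20 <- .gauss_legendre(20)

#' Diffuse transmittance of a canopy layer
#'
#' Hemispherical integration of the beam gap fraction over the sky dome:
#' `tau_d = 2 * int_0^{pi/2} exp(-kb(theta) * OmegaF) sin(theta) cos(theta) dtheta`,
#' evaluated with 20-node Gauss-Legendre quadrature. `OmegaF` is the
#' clumping-corrected leaf area (Omega * F), optionally scaled by
#' `sqrt(absorptivity)` by the caller to account for leaf scattering.
#'
#' @param omega_F clumping-corrected (and possibly scattering-scaled)
#'   leaf area index.
#' @param x_lad leaf-angle distribution parameter.
#' @return diffuse transmittance in (0, 1].
#' @export
diffuse_transmittance <- function(omega_F, x_lad = 1) {
  # substitute mu = cos(theta): tau_d = 2 int_0^1 exp(-kb(mu) oF) mu dmu;
  # the integrand is smooth at the horizon (exp(-c/mu) -> 0), so a fixed
  # Gauss-Legendre rule converges fast
  mu <- (.gl20$x + 1) / 2                 # map [-1,1] -> (0, 1)
  kb <- sqrt(x_lad^2 * mu^2 + 1 - mu^2) /
    (mu * (x_lad + 1.774 * (x_lad + 1.182)^(-0.733)))
  f <- function(oF) sum(.gl20$w * exp(-kb * oF) * mu)
  vapply(omega_F, f, numeric(1))
}

#' Effective diffuse extinction coefficient
#'
#' `kd = -log(tau_d) / omega_F`, with the `omega_F -> 0` limit taken as
#' the hemispherically averaged beam extinction coefficient.
#'
#' @inheritParams diffuse_transmittance
#' @return diffuse extinction coefficient (unitless).
#' @export
diffuse_extinction_kd <- function(omega_F, x_lad = 1) {
  ifelse(omega_F > 1e-8,
         -log(diffuse_transmittance(omega_F, x_lad)) / omega_F,
         -log(diffuse_transmittance(1e-4, x_lad)) / 1e-4)
}

#' Fraction of a layer viewed by a sensor (or sun)
#'
#' `f(theta) = 1 - exp(-kb * Omega * F)`: the probability that a ray at
#' the given zenith angle intersects foliage of the layer.
#'
#' @param F layer leaf area index (m2 m-2).
#' @param Omega clumping index in (0, 1].
#' @param kb beam extinction coefficient at the view zenith.
#' @return viewed fraction in [0, 1).
#' @export
fraction_viewed <- function(F, Omega, kb) {
  stopifnot(all(F >= 0), all(Omega > 0), all(Omega <= 1), all(kb > 0))
  1 - exp(-kb * Omega * F)
}

#' Vine structural parameters from LAI
#'
#' Canopy height and canopy-to-row-width fraction follow a piecewise
#' linear map in vine LAI between the dormant (woody) and peak-season
#' bounds, clipped to those bounds.
#'
#' @param LAI_vine vine LAI (m2 m-2).
#' @param config a [seb_config()] object (its `canopy` block is used).
#' @return list with `h_c` (m) and `w_c` (fraction of row width).
#' @export
structural_params <- function(LAI_vine, config = seb_config()) {
  cc <- config$canopy
  s <- (LAI_vine - cc$lai_at_hmin) / (cc$lai_at_hmax - cc$lai_at_hmin)
  s <- pmin(pmax(s, 0), 1)
  list(h_c = cc$h_c_min + s * (cc$h_c_max - cc$h_c_min),
       w_c = cc$w_c_min + s * (cc$w_c_max - cc$w_c_min))
}

#' Clumping index of a hedgerow canopy
#'
#' Rectangular-hedgerow approximation: foliage is confined to strips
#' covering a fraction `w_c` of the ground, so the nadir gap probability
#' is `(1 - w_c) + w_c * exp(-k0 * LAI / w_c)`. The clumping index is the
#' value that reproduces this gap probability under a homogeneous
#' Beer's-law canopy: `Omega = -log(P_gap) / (k0 * LAI)`.
#'
#' @param LAI layer LAI referenced to ground area (m2 m-2).
#' @param w_c canopy-to-row-width fraction in (0, 1].
#' @param k0 nominal extinction coefficient used in the matching
#'   (default 0.5, spherical leaf angles at nadir).
#' @return clumping index in (0, 1].
#' @export
clumping_hedgerow <- function(LAI, w_c, k0 = 0.5) {
  stopifnot(all(w_c > 0), all(w_c <= 1))
  p_gap <- (1 - w_c) + w_c * exp(-k0 * LAI / w_c)
  omega <- ifelse(LAI > 1e-8, -log(p_gap) / (k0 * LAI), 1)
  pmin(pmax(omega, 1e-3), 1)
}

#' Assemble the canopy state of one timestamp
#'
#' Bundles layer LAI, green fractions, structure and clumping into the
#' list consumed by the radiation and solver functions.
#'
#' @param LAI_vine,LAI_cc layer LAI (m2 m-2).
#' @param fg_vine,fg_cc layer green fractions in [0, 1].
#' @param config a [seb_config()] object.
#' @return list of class `canopy_state`.
#' @export
canopy_state <- function(LAI_vine, LAI_cc, fg_vine, fg_cc,
                         config = seb_config()) {
  stopifnot(LAI_vine >= 0, LAI_cc >= 0,
            fg_vine >= 0, fg_vine <= 1, fg_cc >= 0, fg_cc <= 1)
  st <- structural_params(LAI_vine, config)
  structure(list(
    LAI_vine = LAI_vine, LAI_cc = LAI_cc,
    fg_vine = fg_vine, fg_cc = fg_cc,
    h_c_vine = st$h_c, w_c_vine = st$w_c,
    h_c_cc = config$canopy$h_c_cc, w_c_cc = config$canopy$w_c_cc,
    Omega_vine = clumping_hedgerow(LAI_vine, st$w_c),
    Omega_cc = 1,
    row_width = config$site$row_width
  ), class = "canopy_state")
}
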