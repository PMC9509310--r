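---
title: "Three-source energy balance modelling of vineyard evapotranspiration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-source energy balance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threeseb)
```

# The model

`threeseb` solves the surface energy balance of a clumped vineyard as
three interacting sources: overstory vine foliage, understory cover
crop, and soil. A single directional radiometric temperature `T_rad`
(from a tower radiometer or thermal imagery) and standard meteorology
(shortwave irradiance, air temperature, vapor pressure, wind speed,
pressure) drive the model; latent heat of each source is obtained as the
residual of that source's balance, so evapotranspiration is partitioned
into vine transpiration, cover-crop transpiration and soil evaporation
without any water-budget inputs.

## Nested solution

The solver treats the surface first as a **parallel** two-component
system — overstory against "substrate" (cover crop + soil) — and then
splits the substrate in **series**:

1. Overstory transpiration is initialized with the Priestley–Taylor
   formulation, `LE_ov = α_PT f_g Δ/(Δ+γ) Rn_ov`, giving `H_ov` and,
   through the aerodynamic resistance, the overstory temperature
   `T_ov = T_A + H_ov R_A / ρCp`.
2. The substrate temperature follows from fourth-power decomposition of
   `T_rad` given `T_ov` and the sensor-view vegetation fraction
   `f(θ) = 1 − exp(−k_b Ω F)`. The substrate sensible heat flux flows
   through `R_A + R_sub`, which fixes the in-canopy air temperature
   `T_AC`.
3. The understory repeats the Priestley–Taylor step on its own net
   radiation; its temperature follows from `R_x`, the soil temperature
   from decomposing the substrate temperature, soil sensible heat from
   `R_s`, and finally `LE_soil = Rn_soil − H_soil − G`.

If any source shows negative latent heat at daytime (condensation,
which is not realistic under the daytime filter), the responsible
layer's `α_PT` is reduced in steps of 0.1 from 1.26 toward 0 and the
record re-solved. Atmospheric stability (Obukhov length, friction
velocity) is updated once per pass from the total sensible heat flux,
so temperatures, resistances, stability and the α constraint iterate to
joint convergence.

Three identities hold **by construction** on every converged record and
are asserted in the tests: each source's energy balance closes exactly;
recomposing the solved component temperatures through the view
fractions reproduces the input `T_rad`; and no daytime LE is negative.

## Which layer is blamed for a violation

The model gives the soil no free parameter, so negative `LE_soil` must
be repaired through the vegetation: reducing a transpiring layer's α
warms that layer, which cools the temperature decomposition below it
and lowers the soil sensible heat. The understory α is reduced first
(it is physically closest to the soil), then the overstory; a layer
that is not transpiring (e.g. `f_g = 0`, or negative layer net
radiation) is skipped, since reducing its α cannot change anything.
When both α are exhausted, the record is flagged and soil evaporation
pinned at zero with the residual folded into `H_soil`.

## The TSEB baseline

`solve_tseb()` is the two-source configuration of the same nested
network: the vine and cover-crop LAI are summed into one bulk canopy
(LAI-weighted green fraction, structure re-derived from the bulk LAI)
and the substrate is bare soil. We deliberately implement it as the
exact structural limit of the three-source network rather than as an
independent series formulation: the limit makes "adding an understory
changes nothing when there is no understory" an exact, testable
property (asserted to 2 W m⁻² at every daytime hour), and it isolates
the scientific difference between the models — the explicit understory
— from incidental numerical differences.

# Radiation and ground heat flux

Shortwave is split into direct and diffuse with a clearness-index
correlation (Erbs polynomial; the overcast branch, clearness ≤ 0.22, is
treated as fully diffuse) and into PAR/NIR bands (45/55). Each
vegetation layer attenuates each stream by Beer's law with
clumping-corrected optical depth `√a · k · Ω · LAI` (leaf absorptivity
`a`: PAR 0.85, NIR 0.20), with a deep-canopy reflectance adjusted by
the stream's extinction coefficient. The overstory's transmission
shades the understory and soil; soil-reflected shortwave makes a single
upward pass. Longwave exchange is a single down-and-up pass of sky,
foliage and soil emission through the same gap-fraction transmittances,
re-linearized at the current component temperatures each solver pass
(vegetation emissivity 0.98, soil 0.95; `T_rad` retrieval itself
assumes a blackbody, configurable). Multiple scattering between layers
is neglected beyond these single passes; the bookkeeping is written so
the per-layer budget sums *exactly* to the top-of-canopy balance, which
the tests assert to 10⁻⁹ W m⁻², and a merged two-layer canopy matches a
one-layer computation to 2%.

The diffuse extinction coefficient is the hemispherical integral of the
beam gap fraction, evaluated with a fixed 20-node Gauss–Legendre rule
in the cosine-of-zenith domain, where the integrand is smooth at the
horizon; this matches adaptive quadrature to better than 10⁻⁶ relative.

Ground heat flux uses the fixed ratio `G = 0.35 · Rn_soil`, applied at
all hours (a known simplification — G has a diurnal phase shift that a
constant ratio cannot represent), or observed G can be forced with
`g_mode = "observed"`.

# Resistances

Standard Monin–Obukhov machinery: displacement `0.65 h_c`, momentum
roughness `0.125 h_c`, `kB⁻¹ = 2`; Dyer–Businger stability functions;
wind floored at 0.1 m s⁻¹ and |Obukhov length| at 1 m. In-canopy wind
follows a Goudriaan-type exponential profile with attenuation
`0.28 LAI^(2/3) h_c^(1/3) s^(-1/3)`. The bulk understory resistance is
`R_x = (C'/LAI)(s/U_d)^½` with `C' = 90 s^½ m⁻¹` and `s = 0.01 m`; the
soil resistance `R_s = 1/(c(T_soil − T_AC)^⅓ + b u_s)` with
`b = 0.012`, `c = 0.0025` (free + forced convection, temperature
difference floored at zero). The substrate resistance `R_sub` — whose
published formulation is described only by role — is an `R_s`-type
resistance evaluated at the substrate top (cover-crop canopy height)
with the substrate–air temperature difference; with no understory it
degenerates to the soil form, which is what makes the two-source limit
exact.

# LAI decomposition and phenology

`partition_lai()` turns a daily ecosystem LAI series into vine and
cover-crop layers using day-of-year anchors: before vine budbreak
(default DOY 80) and after leaf-off (default DOY 310) the cover crop
carries everything; from budbreak it decays exponentially (mowing, then
senescence to stubble) until peak summer (default: the day of maximum
ecosystem LAI); after leaf-off it regrows exponentially toward the
ecosystem LAI. Vine LAI is the remainder, floored at 0.4 m² m⁻²
year-round so woody elements keep acting on radiative and aerodynamic
transfer during dormancy. The floor is applied to the LAI used by both
the radiation scheme and the roughness/wind machinery — woody area
intercepts momentum as well as photons.

The e-folding time of all exponential transitions (cover-crop decay and
regrowth, green fractions) defaults to 21 days: fast enough that the
stubble state is reached by mid-summer from a typical spring mowing,
slow enough that the transitions span several weeks, as seasonal
vegetation-index trajectories in row crops typically do. Vine green
fraction is 0 during leaf-off and 1 in full leaf, with exponential
transitions; the cover-crop green fraction mirrors its LAI dynamics.

Vine structure (height 1.5–2.2 m, canopy-to-row-width fraction
0.2–0.45) is mapped piecewise-linearly from vine LAI between its
dormant and peak values — the published empirical relations behind this
mapping are not available in closed form, so a transparent linear
anchor between the tabulated bounds is used instead. The vine clumping
index comes from a rectangular-hedgerow gap-probability match
(`clumping_hedgerow()`); the cover crop is treated as horizontally
homogeneous (Ω = 1).

# The synthetic data generator

`seb_scenario()` + `generate_scene_series()` emulate a semi-arid
vineyard flux tower: clear-sky solar-geometry shortwave normalized to a
950 W m⁻² noon amplitude, seasonal + diurnal air-temperature sinusoids
(annual mean 289 K, seasonal half-amplitude 9 K, diurnal 7 K, lagged
2 h after noon), constant-with-noise wind (2.5 ± 0.3 m s⁻¹) and vapor
pressure (1.0 kPa), Brutsaert clear-sky incoming longwave, and a
two-season LAI cycle (vine peak 1.6, cover-crop winter level 0.8).
Radiometric temperature is produced by the model's **own forward
equations** under a prescribed partition (Priestley–Taylor coefficients
1.26 and a soil evaporative fraction of 0.5 of the soil's available
energy), so per-source balances hold identically by construction and
the scene is an exact recovery target for the solver. Noise defaults:
0.5 K on `T_rad`, 0.3 m s⁻¹ on wind, 10% multiplicative on LAI —
plausible instrument scales.

What this does and does not show: passing the recovery tests
demonstrates that the inverse solver is consistent with the forward
physics and numerically stable — it cannot validate the physics against
nature. The generator's soil is effectively moderately moist
year-round; a real semi-arid interrow dries down in summer, so the
synthetic year shows a larger soil-evaporation share (and larger annual
interrow water use) than dry-field observations. Advection from
neighboring fields, G phase shifts, footprint heterogeneity and sensor
drift are not emulated.

A handful of dusk records per synthetic year (~0.2%) fail to settle in
the forward iteration (the stability state flips around neutral); they
are excluded from the recovery truth but keep their radiometric
temperature so the forcing is gapless.

# Numerical choices

* Fixed-point iteration with under-relaxation 0.5 on all component
  temperatures; inner tolerance 10⁻³ K, Obukhov relative tolerance
  10⁻³, inner cap 40 passes, outer cap 35 (full α sweep plus
  stability). The reported state is always the last consistently
  computed one, so the balance and recomposition identities hold
  exactly regardless of relaxation.
* The condensation check uses a 0.1 W m⁻² threshold — the same
  magnitude as the energy-balance tolerance. A machine-precision
  threshold makes records whose true solution sits exactly on the
  `LE_soil = 0` boundary take a spurious full α step; sub-threshold
  dips are instead folded into `H_soil` after convergence.
* A non-physical radicand in the temperature decomposition (component
  hotter than the composite allows) cannot be repaired by reducing α,
  so the record is flagged rather than forced.
* Nighttime records (shortwave ≤ 100 W m⁻², strict) are skipped and
  reported missing — the model is formulated and evaluated for daytime.
* The closure ensemble for "observed" fluxes is computed per timestamp
  (not on aggregates); a Bowen ratio within 0.05 of −1, or zero LE,
  drops the Bowen member for that timestamp.
* Daily T/ET is the ratio of daily-summed components, not the mean of
  hourly ratios — stabler on low-ET days; annual T/ET weights days
  equally.
* Problem sizes in the automated checks: four full synthetic years
  (8760 h each) for the conservation suite, a 90-day season for the
  structural limit, a 120-day winter-to-summer season for noisy
  recovery.

# Known limitations

The Priestley–Taylor initialization carries no explicit stomatal
control, so strong vapor-pressure-deficit regulation of transpiration
is only captured indirectly through the α reduction; the constant-ratio
G model misses the diurnal phase of soil heat storage; the radiation
scheme is one-dimensional with single-pass scattering, while real vine
rows have strong three-dimensional structure; and the LAI decomposition
relies on calendar anchors rather than observed cover-crop dynamics.
All module-level parameters discussed above are exposed through
`seb_config()` and can be overridden per site.
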