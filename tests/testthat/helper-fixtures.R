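# Shared in-code fixtures for the test suite.

# a clear summer midday met record (scalars, K / kPa / m s-1)
midday_met <- function() {
  list(SW_in = 850, L_in = 350, T_A = 298, e_a = 1.2, u = 2.5, p = 100.6)
}

# a mid-season three-source canopy: leaf-on vine over senescing cover crop
midseason_canopy <- function(config = seb_config()) {
  canopy_state(LAI_vine = 1.4, LAI_cc = 0.3, fg_vine = 1, fg_cc = 0.5,
               config = config)
}

# write a small met CSV and return its path
write_met_csv <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}

met_csv_header <- "timestamp,SW_in,L_in,L_out,T_A,e_a,u,p,Rn,G,H,LE"

# compose the radiometric temperature implied by a solved record
recompose_trad <- function(rec) {
  compose_trad(rec$f_ov_view, rec$T_ov,
               compose_trad(rec$f_un_view, rec$T_un, rec$T_soil))
}

# per-source energy balance residuals of a solved flux table (converged rows)
balance_residuals <- function(fluxes, ok = fluxes$converged %in% TRUE) {
  c(abs(fluxes$LE_ov + fluxes$H_ov - fluxes$Rn_ov)[ok],
    abs(fluxes$LE_un + fluxes$H_un - fluxes$Rn_un)[ok],
    abs(fluxes$LE_soil + fluxes$H_soil + fluxes$G - fluxes$Rn_soil)[ok])
}
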