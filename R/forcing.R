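# Tower forcing I/O: reading time series, radiometric temperature
# retrieval from longwave radiation, the daytime mask, and the
# energy-balance closure ensemble applied to observed turbulent fluxes.

# canonical column names of a met + flux table
.met_columns <- c("timestamp", "SW_in", "L_in", "L_out", "T_A", "e_a",
                  "u", "p")
.flux_columns <- c("Rn", "G", "H", "LE")

#' Read a tower time series from delimited text
#'
#' Reads an hourly (or any regular-cadence) tower file with a header row.
#' Column names can be remapped through `schema` (a named character vector
#' `c(canonical = "file_column")`). Timestamps must parse and be strictly
#' increasing; gaps are preserved as missing values, never interpolated.
#'
#' Canonical met columns: `timestamp`, `SW_in`, `L_in`, `L_out`, `T_A`
#' (K), `e_a` (kPa), `u` (m s-1), `p` (kPa). Observed fluxes `Rn`, `G`,
#' `H`, `LE` (W m-2) are optional and missing-aware.
#'
#' @param path path to a delimited text file with a header.
#' @param schema optional named character vector mapping canonical names
#'   to file column names.
#' @param sep field separator (default comma).
#' @param tz timezone for timestamp parsing (default "UTC").
#' @return data.frame with canonical columns, one row per timestamp, in
#'   time order.
#' @export
read_timeseries <- function(path, schema = NULL, sep = ",", tz = "UTC") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema column '", src, "' (for '", canon, "') not found in ", path)
      names(df)[names(df) == src] <- canon
    }
  }
  mandatory <- c("timestamp", "SW_in", "T_A", "e_a", "u", "p")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  ts <- tryCatch(
    as.POSIXct(df$timestamp, tz = tz,
               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                              "%Y-%m-%d %H:%M", "%Y-%m-%dT%H:%M")),
    error = function(e) rep(as.POSIXct(NA), nrow(df)))
  if (anyNA(ts))
    stop("unparseable timestamp(s): ",
         paste(utils::head(df$timestamp[is.na(ts)], 3), collapse = ", "))
  if (any(diff(as.numeric(ts)) <= 0)) {
    bad <- df$timestamp[c(FALSE, diff(as.numeric(ts)) <= 0)]
    stop("timestamps not strictly increasing (duplicate or out of order): ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  df$timestamp <- ts
  keep <- intersect(c(.met_columns, .flux_columns, "T_rad"), names(df))
  df <- df[, keep, drop = FALSE]
  for (cn in setdiff(keep, "timestamp")) df[[cn]] <- as.numeric(df[[cn]])
  validate_met(df)
  df
}

# invariant checks on a met table; hard error on physically impossible rows
validate_met <- function(df) {
  chk <- function(cond, msg) {
    bad <- which(!cond & !is.na(cond))
    if (length(bad)) stop(msg, " at row(s) ", paste(utils::head(bad, 3), collapse = ", "))
  }
  chk(df$SW_in >= 0, "SW_in must be >= 0")
  chk(df$u >= 0, "wind speed must be >= 0")
  chk(df$T_A > 180 & df$T_A < 340, "air temperature outside 180-340 K")
  chk(df$e_a >= 0, "vapor pressure must be >= 0")
  invisible(df)
}

#' Write a time series as CSV with ISO-8601 timestamps
#'
#' @param df data.frame with a `timestamp` column.
#' @param path output path.
#' @export
write_timeseries <- function(df, path) {
  out <- df
  out$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Retrieve radiometric surface temperature from longwave radiation
#'
#' Inverts the Stefan-Boltzmann law for the surface temperature seen by a
#' four-component net radiometer:
#' `T_rad = ((L_out - (1 - emissivity) * L_in) / (emissivity * sigma))^(1/4)`.
#' With blackbody emissivity (the default) the incoming term drops out.
#'
#' @param L_in incoming longwave radiation (W m-2).
#' @param L_out outgoing longwave radiation (W m-2), must be > 0.
#' @param emissivity broadband surface emissivity in [0.9, 1].
#' @return radiometric temperature (K).
#' @seealso [emit_lout()] for the forward operation.
#' @export
retrieve_trad <- function(L_in, L_out, emissivity = 1) {
  stopifnot(all(emissivity >= 0.9), all(emissivity <= 1))
  if (any(L_out <= 0, na.rm = TRUE)) stop("L_out must be positive")
  radicand <- (L_out - (1 - emissivity) * L_in) / (emissivity * seb_constants$sigma)
  if (any(radicand <= 0, na.rm = TRUE))
    stop("non-positive radicand: outgoing longwave inconsistent with emissivity")
  radicand^0.25
}

#' Emit outgoing longwave radiation from a surface temperature
#'
#' Forward companion of [retrieve_trad()]:
#' `L_out = emissivity * sigma * T^4 + (1 - emissivity) * L_in`.
#'
#' @param T_rad surface temperature (K).
#' @param L_in incoming longwave (W m-2); only used when `emissivity < 1`.
#' @param emissivity broadband surface emissivity.
#' @return outgoing longwave radiation (W m-2).
#' @export
emit_lout <- function(T_rad, L_in = 0, emissivity = 1) {
  emissivity * seb_constants$sigma * T_rad^4 + (1 - emissivity) * L_in
}

#' Daytime mask
#'
#' A record is daytime when shortwave irradiance strictly exceeds the
#' threshold (100 W m-2 by default). The model is solved and evaluated on
#' daytime records only.
#'
#' @param SW_in shortwave irradiance (W m-2), or a data.frame with an
#'   `SW_in` column.
#' @param threshold daytime threshold (W m-2); the comparison is strict.
#' @return logical vector, `NA` where `SW_in` is missing.
#' @export
daytime_mask <- function(SW_in, threshold = 100) {
  if (is.data.frame(SW_in)) SW_in <- SW_in$SW_in
  SW_in > threshold
}

#' Energy-balance closure ensemble for observed turbulent fluxes
#'
#' Eddy-covariance towers rarely close the energy balance
#' (H + LE < Rn - G). Reference "observed" fluxes are built as the
#' average of three common corrections, applied per timestamp:
#' \enumerate{
#'   \item unclosed: H and LE as measured;
#'   \item residual-to-LE: `LE2 = Rn - G - H`, `H2 = H`;
#'   \item Bowen-ratio: with `beta = H/LE`,
#'     `H3 = beta * (Rn - G) / (1 + beta)`, `LE3 = (Rn - G) / (1 + beta)`,
#'     which closes the balance exactly while conserving beta.
#' }
#' When `LE = 0` or `beta` is within 0.05 of -1 the Bowen-ratio member is
#' undefined and skipped; the ensemble then averages the remaining two
#' (the affected timestamps are reported via an attribute).
#'
#' @param H_obs,LE_obs,Rn_obs,G_obs observed fluxes (W m-2), recycled to a
#'   common length. Timestamps with any missing member yield `NA`.
#' @return data.frame with columns `H_ref` and `LE_ref`; attribute
#'   `bowen_skipped` holds the indices where method 3 was dropped.
#' @export
closure_ensemble <- function(H_obs, LE_obs, Rn_obs, G_obs) {
  n <- max(length(H_obs), length(LE_obs), length(Rn_obs), length(G_obs))
  H <- rep_len(H_obs, n); LE <- rep_len(LE_obs, n)
  Rn <- rep_len(Rn_obs, n); G <- rep_len(G_obs, n)
  AE <- Rn - G
  H2 <- H
  LE2 <- AE - H
  beta <- H / LE
  ok3 <- is.finite(beta) & abs(1 + beta) >= 0.05 & LE != 0
  H3 <- ifelse(ok3, beta * AE / (1 + beta), NA_real_)
  LE3 <- ifelse(ok3, AE / (1 + beta), NA_real_)
  H_ref <- ifelse(ok3, (H + H2 + H3) / 3, (H + H2) / 2)
  LE_ref <- ifelse(ok3, (LE + LE2 + LE3) / 3, (LE + LE2) / 2)
  any_na <- is.na(H) | is.na(LE) | is.na(Rn) | is.na(G)
  H_ref[any_na] <- NA_real_
  LE_ref[any_na] <- NA_real_
  out <- data.frame(H_ref = H_ref, LE_ref = LE_ref)
  skipped <- which(!ok3 & !any_na)
  if (length(skipped))
    message(length(skipped), " timestamp(s) had an undefined Bowen ratio; ",
            "closure ensemble averaged two members there")
  attr(out, "bowen_skipped") <- skipped
  out
}
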