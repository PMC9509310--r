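# User-facing model interface: fit the three-source (or two-source)
# energy balance to a tower time series and return a classed object with
# the usual modelling methods.

#' Fit a three-source energy balance model to a tower time series
#'
#' Runs the 3SEB (or TSEB baseline) solver on every daytime record of a
#' meteorological time series, after decomposing the daily ecosystem LAI
#' into vine and cover-crop layers and deriving canopy structure from
#' phenology. Radiometric temperature is taken from a `T_rad` column if
#' present, otherwise retrieved from the longwave components
#' (`L_in`/`L_out`). If observed fluxes (`Rn`, `G`, `H`, `LE`) are
#' present, evaluation statistics against the energy-closure ensemble
#' are computed.
#'
#' @param met data.frame of met forcing (see [read_timeseries()] for the
#'   canonical columns), hourly or finer, regular cadence.
#' @param lai data.frame with daily `doy` and `LAI_eco` columns.
#' @param config a [seb_config()] object.
#' @param model `"3seb"` (three sources) or `"tseb"` (bulk two-source
#'   baseline).
#' @param g_mode `"ratio"` (G = 0.35 Rn_soil) or `"observed"` (force
#'   tower G).
#' @return object of class `threeseb` with elements `fluxes`
#'   (per-timestamp data.frame), `partition` ([partition_series()]),
#'   `stats` (per-flux [compute_metrics()] when observations exist),
#'   `diagnostics`, `canopy` (daily LAI decomposition), `config`,
#'   `model`, `call`.
#' @examples
#' sc <- seb_scenario(seed = 42, days = 8)
#' syn <- generate_scene_series(sc)
#' fit <- threeseb(syn$met, syn$lai, model = "3seb",
#'                 config = seb_config(pheno = sc$pheno))
#' print(fit)
#' @export
threeseb <- function(met, lai, config = seb_config(),
                     model = c("3seb", "tseb"),
                     g_mode = c("ratio", "observed")) {
  model <- match.arg(model)
  g_mode <- match.arg(g_mode)
  stopifnot(is.data.frame(met), is.data.frame(lai))
  validate_met(met)

  if (!"T_rad" %in% names(met)) {
    if (!all(c("L_in", "L_out") %in% names(met)))
      stop("met must contain T_rad or both L_in and L_out")
    met$T_rad <- retrieve_trad(met$L_in, met$L_out,
                               config$radiation$emis_trad)
  }
  if (!"doy" %in% names(met))
    met$doy <- as.integer(format(met$timestamp, "%j"))
  if (!"theta" %in% names(met)) {
    dt <- stats::median(diff(as.numeric(met$timestamp)))
    shift <- if (identical(config$site$timestamp_convention, "end")) dt / 2 else 0
    tt <- met$timestamp - shift
    hour <- as.numeric(format(tt, "%H")) + as.numeric(format(tt, "%M")) / 60
    met$theta <- solar_position(as.integer(format(tt, "%j")), hour,
                                config$site$lat)$zenith
  }
  if (!"LAI_vine" %in% names(lai)) {
    lai <- partition_lai(lai$doy, lai$LAI_eco, config$pheno)
  }
  day <- daytime_mask(met$SW_in, config$daytime_sw_min)
  day[is.na(day)] <- FALSE

  # canopy states are daily; cache per day-of-year
  states <- new.env(parent = emptyenv())
  get_state <- function(d) {
    key <- as.character(d)
    if (is.null(states[[key]])) {
      row <- match(d, lai$doy)
      if (is.na(row)) stop("no LAI available for day of year ", d)
      states[[key]] <- canopy_state(
        lai$LAI_vine[row], lai$LAI_cc[row],
        green_fraction(d, config$pheno, "vine"),
        green_fraction(d, config$pheno, "cc"), config)
    }
    states[[key]]
  }

  solve_fun <- if (model == "3seb") solve_3seb else solve_tseb
  n <- nrow(met)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    if (!day[i]) { recs[[i]] <- .na_record("night"); next }
    G_obs <- if (g_mode == "observed") met$G[i] else NA_real_
    recs[[i]] <- solve_fun(met[i, ], met$T_rad[i], get_state(met$doy[i]),
                           met$theta[i], met$doy[i], config, g_mode, G_obs)
  }
  fields <- names(recs[[which.max(day)]])
  fluxes <- data.frame(timestamp = met$timestamp)
  for (fn in setdiff(fields, c("converged", "flag")))
    fluxes[[fn]] <- vapply(recs, function(r) as.numeric(r[[fn]]), numeric(1))
  fluxes$converged <- vapply(recs, function(r) isTRUE(r$converged), logical(1))
  fluxes$converged[!day] <- NA
  fluxes$flag <- vapply(recs, function(r) as.character(r$flag), character(1))

  stats_out <- NULL
  obs_ref <- NULL
  if (all(c("Rn", "G", "H", "LE") %in% names(met))) {
    ref <- closure_ensemble(met$H, met$LE, met$Rn, met$G)
    ok <- day & fluxes$converged %in% TRUE
    obs_ref <- data.frame(LE = ref$LE_ref, H = ref$H_ref,
                          Rn = met$Rn, G = met$G)
    stats_out <- list(
      LE = compute_metrics(fluxes$LE_total, ref$LE_ref, ok),
      H = compute_metrics(fluxes$H_total, ref$H_ref, ok),
      Rn = compute_metrics(fluxes$Rn_total, met$Rn, ok),
      G = compute_metrics(fluxes$G, met$G, ok))
  }
  part <- partition_series(fluxes, day & fluxes$converged %in% TRUE)

  structure(list(
    fluxes = fluxes,
    partition = part,
    stats = stats_out,
    obs_ref = obs_ref,
    diagnostics = list(
      n_records = n, n_daytime = sum(day),
      n_converged = sum(fluxes$converged, na.rm = TRUE),
      flags = table(fluxes$flag[day & !(fluxes$converged %in% TRUE)])),
    canopy = lai, daytime = day,
    config = config, model = model, g_mode = g_mode,
    call = match.call()),
    class = "threeseb")
}

#' @export
print.threeseb <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("%s energy balance fit: %d records, %d daytime, %d converged (%.1f%%)\n",
              toupper(x$model), d$n_records, d$n_daytime, d$n_converged,
              100 * d$n_converged / max(d$n_daytime, 1)))
  a <- x$partition$annual
  cat(sprintf("annual daily T/ET: %.1f%% +/- %.1f%% (vine %.1f%%, cover crop %.1f%%, soil E %.1f%%)\n",
              100 * a$T_ET_mean, 100 * a$T_ET_sd, 100 * a$f_vine,
              100 * a$f_cc, 100 * a$f_soil))
  invisible(x)
}

#' @export
summary.threeseb <- function(object, ...) {
  structure(list(fit = object), class = "summary.threeseb")
}

#' @export
print.summary.threeseb <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$stats)) {
    cat("\ndaytime evaluation vs closure-ensemble observations (W m-2):\n")
    for (fl in names(x$fit$stats)) {
      s <- x$fit$stats[[fl]]
      cat(sprintf("  %-3s RMSD %6.1f  bias %+6.1f  NSE %6.2f  r %5.2f  n %d\n",
                  fl, s$RMSD, s$bias, s$NSE, s$r, s$n))
    }
  }
  seas <- x$fit$partition$seasonal
  cat("\nseasonal daytime partition (W m-2):\n")
  print(round(seas, 2))
  invisible(x)
}

#' @export
coef.threeseb <- function(object, ...) {
  f <- object$fluxes
  ok <- f$converged %in% TRUE
  c(alpha_ov = mean(f$alpha_ov[ok]), alpha_un = mean(f$alpha_un[ok]))
}

#' @export
fitted.threeseb <- function(object, ...) {
  object$fluxes[, c("timestamp", "Rn_total", "H_total", "LE_total", "G")]
}

#' Residuals of a fitted energy balance
#'
#' Model minus closure-ensemble observation for the requested flux, NA
#' where either is unavailable.
#'
#' @param object a [threeseb()] fit.
#' @param which `"LE"`, `"H"`, `"Rn"` or `"G"`.
#' @param ... unused.
#' @return numeric vector, one value per input record (NA at night or
#'   where observations are missing).
#' @export
residuals.threeseb <- function(object, which = c("LE", "H", "Rn", "G"),
                               ...) {
  which <- match.arg(which)
  if (is.null(object$obs_ref))
    stop("fit has no observed fluxes; refit with Rn/G/H/LE columns present")
  model <- switch(which, LE = object$fluxes$LE_total,
                  H = object$fluxes$H_total,
                  Rn = object$fluxes$Rn_total, G = object$fluxes$G)
  model - object$obs_ref[[which]]
}

#' Predict (solve) on new forcing data
#'
#' @param object a [threeseb()] fit.
#' @param met new met data.frame.
#' @param lai new daily LAI data.frame (defaults to the fitted one).
#' @param ... unused.
#' @return a new `threeseb` object.
#' @export
predict.threeseb <- function(object, met, lai = object$canopy, ...) {
  threeseb(met, lai, config = object$config, model = object$model,
           g_mode = object$g_mode)
}

#' Plot a fitted energy balance partition
#'
#' Daily daytime-mean component latent heat fluxes (stacked view of
#' vine, cover crop and soil) and the daily T/ET ratio.
#'
#' @param x a [threeseb()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.threeseb <- function(x, ...) {
  d <- x$partition$daily
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(d$date, cbind(d$LE_ov, d$LE_un, d$LE_soil),
                    type = "l", lty = 1,
                    col = c("darkgreen", "steelblue", "grey40"),
                    xlab = "", ylab = "daytime LE (W m-2)", ...)
  graphics::legend("topleft", c("vine T", "cover-crop T", "soil E"),
                   col = c("darkgreen", "steelblue", "grey40"),
                   lty = 1, bty = "n", cex = 0.8)
  graphics::plot(d$date, d$T_ET, type = "l", ylim = c(0, 1),
                 xlab = "", ylab = "T/ET")
  invisible(x)
}
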