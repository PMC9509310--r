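# Evaluation statistics and T/ET partitioning aggregation.

#' Model evaluation statistics
#'
#' Root-mean-square deviation, mean bias (model minus observed),
#' Nash-Sutcliffe efficiency and Pearson correlation over a masked
#' window. Pairs with any missing value are dropped. A constant observed
#' series leaves NSE and r undefined (`NA`).
#'
#' @param model modelled series.
#' @param observed observed series, same length.
#' @param mask optional logical mask selecting the evaluation window.
#' @return list of class `eval_stats`: `RMSD`, `bias`, `NSE`, `r`, `n`.
#' @export
compute_metrics <- function(model, observed, mask = NULL) {
  stopifnot(length(model) == length(observed))
  if (is.null(mask)) mask <- rep(TRUE, length(model))
  mask[is.na(mask)] <- FALSE
  keep <- mask & !is.na(model) & !is.na(observed)
  m <- model[keep]; o <- observed[keep]
  n <- length(m)
  if (n < 2) stop("need at least 2 paired non-missing values")
  rmsd <- sqrt(mean((m - o)^2))
  bias <- mean(m - o)
  sso <- sum((o - mean(o))^2)
  nse <- if (sso > 0) 1 - sum((m - o)^2) / sso else NA_real_
  r <- if (sso > 0 && stats::var(m) > 0) stats::cor(m, o)
       else if (sso > 0 && rmsd == 0) 1 else NA_real_
  structure(list(RMSD = rmsd, bias = bias, NSE = nse, r = r, n = n),
            class = "eval_stats")
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf("RMSD %.2f  bias %+.2f  NSE %.3f  r %.3f  (n = %d)\n",
              x$RMSD, x$bias, x$NSE, x$r, x$n))
  invisible(x)
}

#' Daily and seasonal T/ET partitioning series
#'
#' Aggregates a solved flux-partition series to daily daytime means of
#' the component latent heat fluxes and the partitioning ratios. Daily
#' T/ET is the ratio of daily-summed components (not the mean of hourly
#' ratios), which is stable on low-ET days. Seasonal aggregation uses
#' day-of-year windows (defaults: <= 90, 90-150, 150-330, 330-365) and
#' the annual daily-mean T/ET is reported with its standard deviation
#' (equal weight per day).
#'
#' @param fluxes data.frame with columns `timestamp`, `LE_ov`, `LE_un`,
#'   `LE_soil` (typically the `$fluxes` element of a [threeseb()] fit).
#' @param mask logical daytime mask, same length.
#' @param season_breaks DOY breakpoints of the seasonal windows.
#' @return list of class `partition_series`: `daily` (data.frame with
#'   date, daytime-mean component LE, `T_ET` and component fractions),
#'   `seasonal` (per-window means), `annual` (mean and SD of daily T/ET).
#' @export
partition_series <- function(fluxes, mask,
                             season_breaks = c(90, 150, 330)) {
  stopifnot(all(c("timestamp", "LE_ov", "LE_un", "LE_soil") %in% names(fluxes)))
  mask[is.na(mask)] <- FALSE
  ok <- mask & !is.na(fluxes$LE_ov) & !is.na(fluxes$LE_un) &
    !is.na(fluxes$LE_soil)
  f <- fluxes[ok, , drop = FALSE]
  if (!nrow(f)) stop("no valid daytime records")
  day <- as.Date(f$timestamp)
  agg <- function(v) tapply(v, day, mean)
  daily <- data.frame(
    date = as.Date(names(agg(f$LE_ov))),
    LE_ov = as.numeric(agg(f$LE_ov)),
    LE_un = as.numeric(agg(f$LE_un)),
    LE_soil = as.numeric(agg(f$LE_soil)))
  daily$LE_total <- daily$LE_ov + daily$LE_un + daily$LE_soil
  tot <- ifelse(daily$LE_total > 0, daily$LE_total, NA_real_)
  daily$T_ET <- (daily$LE_ov + daily$LE_un) / tot
  daily$f_vine <- daily$LE_ov / tot
  daily$f_cc <- daily$LE_un / tot
  daily$f_soil <- daily$LE_soil / tot
  doy <- as.integer(format(daily$date, "%j"))
  win <- cut(doy, breaks = c(0, season_breaks, 366),
             labels = c(sprintf("doy<=%d", season_breaks[1]),
                        sprintf("doy%d-%d", season_breaks[1], season_breaks[2]),
                        sprintf("doy%d-%d", season_breaks[2], season_breaks[3]),
                        sprintf("doy>%d", season_breaks[3])))
  seasonal <- do.call(rbind, lapply(split(daily, win), function(d) {
    if (!nrow(d)) return(NULL)
    data.frame(n_days = nrow(d),
               LE_ov = mean(d$LE_ov), LE_un = mean(d$LE_un),
               LE_soil = mean(d$LE_soil),
               T_ET = mean(d$T_ET, na.rm = TRUE))
  }))
  structure(list(
    daily = daily,
    seasonal = seasonal,
    annual = list(T_ET_mean = mean(daily$T_ET, na.rm = TRUE),
                  T_ET_sd = stats::sd(daily$T_ET, na.rm = TRUE),
                  f_vine = mean(daily$f_vine, na.rm = TRUE),
                  f_cc = mean(daily$f_cc, na.rm = TRUE),
                  f_soil = mean(daily$f_soil, na.rm = TRUE))),
    class = "partition_series")
}

#' Convert a latent heat flux series to an evaporation depth
#'
#' `depth = sum(LE * dt) / lambda(T_A)` in kg m-2 = mm, with lambda the
#' temperature-dependent latent heat of vaporization. Missing values
#' (e.g. unsolved nighttime records) are treated as zero flux.
#'
#' @param LE latent heat flux series (W m-2).
#' @param timestamps POSIXct vector on a regular time step.
#' @param T_A air temperature series (K); a scalar is recycled.
#' @return total evaporation depth (mm) over the series.
#' @export
volumetric_et <- function(LE, timestamps, T_A = 293.15) {
  stopifnot(length(LE) == length(timestamps))
  dts <- diff(as.numeric(timestamps))
  if (length(dts) == 0) stop("need at least 2 timestamps")
  if (max(dts) - min(dts) > 1e-6) stop("time step must be regular")
  dt <- dts[1]
  T_A <- rep_len(T_A, length(LE))
  LE0 <- ifelse(is.na(LE), 0, LE)
  sum(LE0 * dt / latent_heat(T_A))
}
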