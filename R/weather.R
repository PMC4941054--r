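# Stochastic weather generator: disaggregates monthly climate for one grid
# cell into hourly drivers on a 360-day year (12 x 30-day months). The
# testable contract is conservation: hourly series reproduce the monthly
# mean (states) or total (fluxes) exactly, up to floating-point error.

HOURS_PER_MONTH <- 720L
HOURS_PER_DAY <- 24L

# Fraction of the day with daylight for latitude (deg) and month.
daylight_hours <- function(lat_deg, m) {
  phi <- lat_deg * pi / 180
  dec <- month_declination(m) * pi / 180
  x <- -tan(phi) * tan(dec)
  h0 <- acos(pmin(1, pmax(-1, x)))
  24 * h0 / pi
}

# Hourly weights of one wet-event process over n hours: exponential dry
# gaps and event durations with configurable means, random event intensity.
# Guarantees at least one wet hour.
wet_event_weights <- function(n, gap_mean, event_mean) {
  w <- numeric(n)
  t <- 1 + stats::rexp(1, rate = 1 / gap_mean)
  while (t <= n) {
    dur <- max(1, round(stats::rexp(1, rate = 1 / event_mean)))
    idx <- seq(floor(t), min(n, floor(t) + dur - 1))
    w[idx] <- w[idx] + stats::runif(1, 0.5, 1.5)
    t <- t + dur + stats::rexp(1, rate = 1 / gap_mean)
  }
  if (all(w == 0)) w[sample.int(n, 1)] <- 1
  w
}

#' Disaggregate monthly climate for one cell to hourly forcing
#'
#' Generates one 360-day model year (8640 hours) of drivers from 12 monthly
#' values per variable:
#' \itemize{
#'   \item temperature: sinusoidal diurnal cycle around the monthly mean
#'     (peak at 14:00 local time, configurable amplitude);
#'   \item shortwave: daylight half-sine with day length from latitude and
#'     season, rescaled so the monthly mean is met exactly;
#'   \item relative humidity: in anti-phase with temperature, with the
#'     coupling damped where needed so the series stays in `[0, 1]` and
#'     the monthly mean is preserved;
#'   \item rainfall and snowfall: stochastic wet events (exponential dry
#'     gaps and durations), rescaled so the monthly total is met exactly;
#'   \item longwave and wind: constant at the monthly value.
#' }
#'
#' @param monthly list with 12-vectors `sw`, `lw`, `rain`, `snow`, `temp`,
#'   `wind`, `rh` and scalar `lat` (see [generate_monthly_climate()] and
#'   `cell_monthly()`), or a `monthly_climate` with `i`, `j` given.
#' @param seed integer seed.
#' @param i,j cell indices when `monthly` is a `monthly_climate`.
#' @param diurnal_temp_amplitude peak-to-trough diurnal temperature range
#'   (deg C, default 8; 0 gives constant temperature within each month).
#' @param rh_temp_coupling relative-humidity decrease per deg C of diurnal
#'   temperature anomaly (default 0.015).
#' @param wet_gap_hours,wet_event_hours mean dry-gap and wet-event
#'   durations (hours) of the precipitation event process.
#' @return object of class `hourly_forcing`: vectors of length 8640 for
#'   `sw` (W m-2), `lw` (W m-2), `rain` (mm/h), `snow` (mm/h water
#'   equivalent), `temp` (deg C), `wind` (m s-1), `rh` (fraction), plus
#'   `lat`, `month` (1..12 per hour) and `hour_of_day` (0..23).
#' @export
downscale_to_hourly <- function(monthly, seed, i = NULL, j = NULL,
                                diurnal_temp_amplitude = 8,
                                rh_temp_coupling = 0.015,
                                wet_gap_hours = 72,
                                wet_event_hours = 6) {
  if (inherits(monthly, "monthly_climate")) {
    if (is.null(i) || is.null(j)) stop("give `i`, `j` for a gridded input", call. = FALSE)
    monthly <- cell_monthly(monthly, i, j)
  }
  vars <- c("sw", "lw", "rain", "snow", "temp", "wind", "rh")
  for (v in vars) {
    if (length(monthly[[v]]) != 12L) {
      stop(sprintf("`monthly$%s` must have 12 values", v), call. = FALSE)
    }
  }
  if (any(monthly$rain < 0) || any(monthly$snow < 0)) {
    stop("monthly precipitation must be non-negative", call. = FALSE)
  }

  n <- 12L * HOURS_PER_MONTH
  hod <- rep(rep(0:23, times = 30L), times = 12L)
  month_of_hour <- rep(1:12, each = HOURS_PER_MONTH)
  out <- list(sw = numeric(n), lw = numeric(n), rain = numeric(n),
              snow = numeric(n), temp = numeric(n), wind = numeric(n),
              rh = numeric(n))

  withr::with_seed(derive_seed(seed, 303L), {
    for (m in 1:12) {
      sel <- which(month_of_hour == m)
      h <- hod[sel]

      # temperature: diurnal sinusoid, exact zero mean over whole days
      anom <- (diurnal_temp_amplitude / 2) * cos(2 * pi * (h - 14) / 24)
      out$temp[sel] <- monthly$temp[m] + anom

      # shortwave: half-sine over the daylight window, exact monthly mean
      L <- daylight_hours(monthly$lat, m)
      shape <- if (L > 0) pmax(0, cos(pi * (h - 12) / max(L, 1e-6))) else
        numeric(length(sel))
      if (sum(shape) == 0 && monthly$sw[m] > 0) shape <- rep(1, length(sel))
      out$sw[sel] <- if (monthly$sw[m] > 0)
        monthly$sw[m] * length(sel) * shape / sum(shape) else 0

      # relative humidity: anti-phase with temperature, damped into [0, 1]
      max_dev <- diurnal_temp_amplitude / 2
      beta <- if (max_dev > 0) {
        min(rh_temp_coupling,
            0.95 * monthly$rh[m] / max_dev,
            0.95 * (1 - monthly$rh[m]) / max_dev)
      } else 0
      out$rh[sel] <- monthly$rh[m] - max(0, beta) * anom

      # precipitation: wet events rescaled to the monthly total
      for (v in c("rain", "snow")) {
        tot <- monthly[[v]][m]
        if (tot > 0) {
          w <- wet_event_weights(length(sel), wet_gap_hours, wet_event_hours)
          out[[v]][sel] <- tot * w / sum(w)
        }
      }

      out$lw[sel] <- monthly$lw[m]
      out$wind[sel] <- monthly$wind[m]
    }
  })

  structure(
    c(out, list(lat = monthly$lat, month = month_of_hour, hour_of_day = hod)),
    class = "hourly_forcing"
  )
}

#' @export
print.hourly_forcing <- function(x, ...) {
  cat(sprintf(
    "<hourly_forcing> 8640 h at lat %.1f deg: mean T %.1f degC, precip %.0f mm/yr, mean SW %.0f W m-2\n",
    x$lat, mean(x$temp), sum(x$rain + x$snow), mean(x$sw)))
  invisible(x)
}
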