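#' Construct an oxygen trace
#'
#' A time-stamped series of oxygen readings for one fish at one speed step,
#' with a per-sample phase flag distinguishing the closed (measurement) phase
#' from flushing. Oxygen is recorded in percent air saturation by default
#' (electrodes are two-point calibrated against sodium-sulphite 0% and
#' air-saturated 100% water); raw umol/L readings are accepted via
#' `unit = "umol_l"`.
#'
#' @param time_s Numeric vector of timestamps, seconds, strictly increasing.
#' @param oxygen Oxygen readings, same length as `time_s`. In %AS (default)
#'   values must lie in \[0, 120\].
#' @param phase Character vector, `"closed"` or `"flush"` per sample.
#'   Recycled if length 1.
#' @param fish_id Identifier of the fish.
#' @param speed_pct_ucrit Optional swimming speed as % of the fish's U_crit.
#' @param unit `"pct_as"` (canonical) or `"umol_l"`.
#' @return An object of class `oxygen_trace` (a data frame with attributes).
#' @export
oxygen_trace <- function(time_s, oxygen, phase = "closed", fish_id = "fish",
                         speed_pct_ucrit = NA_real_, unit = c("pct_as", "umol_l")) {
  unit <- match.arg(unit)
  if (length(time_s) != length(oxygen)) {
    stop("'time_s' and 'oxygen' must have equal length", call. = FALSE)
  }
  if (any(diff(time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  phase <- rep_len(as.character(phase), length(time_s))
  if (!all(phase %in% c("closed", "flush"))) {
    stop("phase values must be 'closed' or 'flush'", call. = FALSE)
  }
  if (unit == "pct_as" && any(oxygen < 0 | oxygen > 120, na.rm = TRUE)) {
    stop("oxygen in %AS must lie within [0, 120]", call. = FALSE)
  }
  structure(
    data.frame(time_s = as.numeric(time_s), oxygen = as.numeric(oxygen),
               phase = phase, stringsAsFactors = FALSE),
    fish_id = fish_id, speed_pct_ucrit = speed_pct_ucrit, unit = unit,
    class = c("oxygen_trace", "data.frame")
  )
}

#' Fit the closed-phase oxygen decline
#'
#' Ordinary least squares through (time in hours, dissolved O2 in umol/L) over
#' the closed-phase samples of a trace. The signed slope is the rate of change
#' of the O2 content per litre of tunnel water; for a respiring fish it is
#' negative. An r-squared below `min_r_squared` triggers a quality warning
#' (noisy electrode, leaks, or spontaneous activity bursts).
#'
#' @param trace An [oxygen_trace()].
#' @param spec A [tunnel_spec()] used to convert %AS readings to umol/L.
#' @param trim_leading,trim_trailing Seconds discarded from the start/end of
#'   the closed phase before fitting (mixing transients); default 0.
#' @param min_r_squared Warn when the fit r-squared falls below this (default
#'   0.9).
#' @param blank_slope Optional background (microbial) respiration slope in
#'   umol/L/h from a blank trace, subtracted from the fitted slope. Default
#'   `NULL` applies no correction.
#' @return An object of class `decline_fit`: list with `slope` (umol/L/h,
#'   signed), `intercept` (umol/L), `r_squared`, `n_points`, and
#'   `blank_corrected`.
#' @export
fit_decline <- function(trace, spec, trim_leading = 0, trim_trailing = 0,
                        min_r_squared = 0.9, blank_slope = NULL) {
  stopifnot(inherits(trace, "oxygen_trace"), inherits(spec, "tunnel_spec"))
  closed <- trace[trace$phase == "closed", , drop = FALSE]
  if (trim_leading > 0 || trim_trailing > 0) {
    t0 <- min(closed$time_s) + trim_leading
    t1 <- max(closed$time_s) - trim_trailing
    closed <- closed[closed$time_s >= t0 & closed$time_s <= t1, , drop = FALSE]
  }
  if (nrow(closed) < 2L) {
    stop("need at least 2 closed-phase samples to fit a decline", call. = FALSE)
  }
  conc <- if (attr(trace, "unit") == "pct_as") {
    pct_as_to_concentration(closed$oxygen, spec)
  } else {
    closed$oxygen
  }
  time_h <- closed$time_s / 3600
  fit <- stats::lm(conc ~ time_h)
  slope <- unname(stats::coef(fit)[["time_h"]])
  r2 <- if (stats::var(conc) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  if (!is.null(blank_slope)) slope <- slope - blank_slope
  if (is.finite(r2) && r2 < min_r_squared) {
    warning(sprintf("decline fit r-squared %.3f below %.2f; inspect trace",
                    r2, min_r_squared), call. = FALSE)
  }
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[[1L]]),
         r_squared = r2, n_points = nrow(closed),
         blank_corrected = !is.null(blank_slope)),
    class = "decline_fit"
  )
}

#' @export
print.decline_fit <- function(x, ...) {
  cat(sprintf("O2 decline: %.4g umol/L/h over %d samples (r2 = %.4f)%s\n",
              x$slope, x$n_points, x$r_squared,
              if (x$blank_corrected) " [blank-corrected]" else ""))
  invisible(x)
}

#' Mass-specific oxygen-consumption rate from a decline fit
#'
#' Scales the fitted per-litre O2 depletion rate by the tunnel water volume
#' and normalises by fish body mass:
#' `MO2 = |slope| * volume / body_mass` (umol O2 per g per h).
#'
#' @param fit A [fit_decline()] result.
#' @param spec A [tunnel_spec()]; supplies the tunnel volume.
#' @param body_mass Fish body weight, g (> 0).
#' @param allow_positive_slope If `FALSE` (default) a positive slope (oxygen
#'   increasing during the closed phase, i.e. a leak or sensor fault) is an
#'   error; set `TRUE` to force through with a warning and an MO2 of 0.
#' @return MO2 in umol O2 g^-1 h^-1.
#' @examples
#' sp <- tunnel_spec(volume = 1.8)
#' f <- structure(list(slope = -10, intercept = 245, r_squared = 1,
#'                     n_points = 600, blank_corrected = FALSE),
#'                class = "decline_fit")
#' mo2(f, sp, body_mass = 0.43)  # 41.86 umol/g/h
#' @export
mo2 <- function(fit, spec, body_mass, allow_positive_slope = FALSE) {
  stopifnot(inherits(fit, "decline_fit"), inherits(spec, "tunnel_spec"))
  if (!is.numeric(body_mass) || length(body_mass) != 1L || body_mass <= 0) {
    stop("'body_mass' must be a single positive number (g)", call. = FALSE)
  }
  if (fit$slope > 1e-9) {    # tolerate numerically-zero slopes from flat traces
    if (!allow_positive_slope) {
      stop("oxygen increased during the closed phase; check for leaks ",
           "(use allow_positive_slope = TRUE to override)", call. = FALSE)
    }
    warning("positive O2 slope treated as zero consumption", call. = FALSE)
    return(0)
  }
  abs(fit$slope) * spec$volume / body_mass
}

#' Read an oxygen-trace CSV
#'
#' Expected dialect: header
#' `fish_id,time_s,o2_pct_as,phase,speed_pct_ucrit`, UTF-8, comma separated,
#' '.' decimal. Phase vocabulary `closed|flush`. Returns one [oxygen_trace()]
#' per fish/speed combination.
#'
#' @param path Path to the CSV file.
#' @return Named list of `oxygen_trace` objects, named `fishid@speed`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("fish_id", "time_s", "o2_pct_as", "phase", "speed_pct_ucrit")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("trace CSV ", path, " missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$fish_id, df$speed_pct_ucrit, sep = "@")
  lapply(split(df, key), function(d) {
    d <- d[order(d$time_s), ]
    oxygen_trace(d$time_s, d$o2_pct_as, d$phase, fish_id = d$fish_id[1L],
                 speed_pct_ucrit = d$speed_pct_ucrit[1L])
  })
}
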