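#' Fit the quadratic oxygen-uptake vs speed model
#'
#' Least-squares fit of `VO2 = SMR + a*U^2 + b*U` with a free intercept. The
#' intercept is the standard metabolic rate (SMR) extrapolated to zero
#' swimming speed; the fitted value at the fish's U_crit (U = 100 on the
#' %U_crit axis) estimates the active maximum VO2max.
#'
#' The default speed axis is percent of U_crit, on which the group curves of
#' small cyprinids are conventionally reported; absolute cm/s is supported by
#' passing those speeds and `speed_axis = "cm_s"` (the model form is
#' axis-agnostic, the label travels with the fit).
#'
#' @param speed Swimming speeds (distinct values >= 3), on the axis named by
#'   `speed_axis`.
#' @param mo2 Mass-specific oxygen uptake at each speed, umol g^-1 h^-1.
#' @param speed_axis `"pct_ucrit"` (default) or `"cm_s"`.
#' @return An object of class `vo2_curve`: list with `smr`, `a`, `b`,
#'   `r_squared`, `speed_axis`.
#' @examples
#' u <- c(25, 50, 75, 100)
#' v <- 43.79 + 0.0081 * u^2 - 0.4353 * u
#' fit_vo2_curve(u, v)
#' @export
fit_vo2_curve <- function(speed, mo2, speed_axis = c("pct_ucrit", "cm_s")) {
  speed_axis <- match.arg(speed_axis)
  if (length(speed) != length(mo2)) {
    stop("'speed' and 'mo2' must have equal length", call. = FALSE)
  }
  if (length(unique(speed)) < 3L) {
    stop("need at least 3 distinct speeds for a quadratic fit", call. = FALSE)
  }
  fit <- stats::lm(mo2 ~ I(speed^2) + speed)
  cf <- stats::coef(fit)
  r2 <- if (stats::var(mo2) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(
    list(smr = unname(cf[[1L]]), a = unname(cf[[2L]]), b = unname(cf[[3L]]),
         r_squared = r2, speed_axis = speed_axis),
    class = "vo2_curve"
  )
}

#' Evaluate a fitted VO2 curve
#' @param object A `vo2_curve`.
#' @param speed Speeds on the curve's axis.
#' @param ... Unused.
#' @return Predicted VO2, umol g^-1 h^-1.
#' @export
predict.vo2_curve <- function(object, speed, ...) {
  object$smr + object$a * speed^2 + object$b * speed
}

#' @export
print.vo2_curve <- function(x, ...) {
  cat(sprintf("VO2 = %.4g %+.4g*U^2 %+.4g*U  (U in %s, r2 = %.4f)\n",
              x$smr, x$a, x$b, x$speed_axis, x$r_squared))
  cat(sprintf("  SMR (extrapolated to U = 0): %.4g umol/g/h\n", x$smr))
  invisible(x)
}

#' Cost of transport from oxygen uptake and speed
#'
#' COT is oxygen consumed per gram of fish per unit distance, obtained by
#' dividing the uptake rate by the speed. Two unit modes:
#' \describe{
#'   \item{`"per_metre"`}{speed is interpreted as cm/s and converted to metres
#'     per hour (1 cm/s = 36 m/h), giving strict umol g^-1 m^-1.}
#'   \item{`"curve"`}{plain ratio VO2 / U on whatever axis the speeds are on
#'     (e.g. %U_crit); this is the scale on which group COT polynomials are
#'     printed and minimised. Dimensionally it is umol g^-1 h^-1 per axis
#'     unit.}
#' }
#'
#' @param mo2 Oxygen uptake, umol g^-1 h^-1.
#' @param speed Speed (> 0), cm/s for `"per_metre"`, curve-axis units for
#'   `"curve"`.
#' @param scale `"per_metre"` (default) or `"curve"`.
#' @return COT values. Strictly decreasing in speed at fixed uptake.
#' @examples
#' cot_from_vo2(36, 1)   # 1 umol/g/m: 1 cm/s is 36 m/h
#' @export
cot_from_vo2 <- function(mo2, speed, scale = c("per_metre", "curve")) {
  scale <- match.arg(scale)
  if (any(speed <= 0)) {
    stop("COT is undefined at zero or negative speed", call. = FALSE)
  }
  switch(scale,
         per_metre = mo2 / (speed * 36),
         curve = mo2 / speed)
}

#' Fit the quadratic cost-of-transport curve
#'
#' Least squares for `COT = a2*U^2 + b2*U + c2`. A positive leading
#' coefficient is required for the curve to have a minimum (see
#' [find_uopt()]).
#'
#' @param speed Speeds (>= 3 distinct values).
#' @param cot COT at each speed.
#' @param speed_axis `"pct_ucrit"` (default) or `"cm_s"`.
#' @return An object of class `cot_curve`: list with `a2`, `b2`, `c2`,
#'   `r_squared`, `speed_axis`.
#' @export
fit_cot_curve <- function(speed, cot, speed_axis = c("pct_ucrit", "cm_s")) {
  speed_axis <- match.arg(speed_axis)
  if (length(speed) != length(cot)) {
    stop("'speed' and 'cot' must have equal length", call. = FALSE)
  }
  if (length(unique(speed)) < 3L) {
    stop("need at least 3 distinct speeds for a quadratic fit", call. = FALSE)
  }
  fit <- stats::lm(cot ~ I(speed^2) + speed)
  cf <- stats::coef(fit)
  r2 <- if (stats::var(cot) == 0) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(
    list(a2 = unname(cf[[2L]]), b2 = unname(cf[[3L]]), c2 = unname(cf[[1L]]),
         r_squared = r2, speed_axis = speed_axis),
    class = "cot_curve"
  )
}

#' Build a COT curve from known coefficients
#'
#' Convenience constructor for evaluating a printed/group polynomial without
#' refitting, e.g. `cot_curve(0.0104, -1.6239, 88.767)`.
#'
#' @param a2,b2,c2 Quadratic, linear and constant coefficients.
#' @param speed_axis Axis label.
#' @return A `cot_curve`.
#' @export
cot_curve <- function(a2, b2, c2, speed_axis = c("pct_ucrit", "cm_s")) {
  speed_axis <- match.arg(speed_axis)
  structure(list(a2 = a2, b2 = b2, c2 = c2, r_squared = NA_real_,
                 speed_axis = speed_axis),
            class = "cot_curve")
}

#' Evaluate a COT curve
#' @param object A `cot_curve`.
#' @param speed Speeds on the curve's axis.
#' @param ... Unused.
#' @export
predict.cot_curve <- function(object, speed, ...) {
  object$a2 * speed^2 + object$b2 * speed + object$c2
}

#' @export
print.cot_curve <- function(x, ...) {
  cat(sprintf("COT = %.4g*U^2 %+.4g*U %+.4g  (U in %s)\n",
              x$a2, x$b2, x$c2, x$speed_axis))
  invisible(x)
}

#' Optimal swimming speed: the COT minimum
#'
#' The optimal swimming speed U_opt is where the first derivative of the
#' quadratic COT curve vanishes: `U_opt = -b2 / (2 * a2)`, the vertex of the
#' parabola; `COT_opt` is the curve evaluated there. Requires an upward
#' parabola (`a2 > 0`), otherwise no minimum exists.
#'
#' @param curve A `cot_curve`.
#' @return List with `uopt` (curve-axis units) and `cot_opt`.
#' @examples
#' find_uopt(cot_curve(0.0104, -1.6239, 88.767))
#' @export
find_uopt <- function(curve) {
  stopifnot(inherits(curve, "cot_curve"))
  if (!is.finite(curve$a2) || curve$a2 <= 0) {
    stop("COT curve has no minimum (leading coefficient not positive)",
         call. = FALSE)
  }
  uopt <- -curve$b2 / (2 * curve$a2)
  list(uopt = uopt, cot_opt = predict(curve, uopt))
}

#' Mean and standard error of per-fish swimming-fitness quantities
#'
#' Group summaries are reported as arithmetic mean plus standard error of the
#' mean (SEM = sample SD / sqrt(n), with the n-1 denominator in the SD).
#'
#' @param x Numeric vector (n >= 2) or a data frame of per-fish scalar
#'   results, summarised column-wise.
#' @return For a vector, list with `mean`, `sem`, `n`; for a data frame, a
#'   data frame with one row per numeric column.
#' @examples
#' summarize_group(c(1, 3))  # mean 2, SEM 1
#' @export
summarize_group <- function(x) {
  if (is.data.frame(x)) {
    num <- x[vapply(x, is.numeric, logical(1L))]
    rows <- lapply(names(num), function(v) {
      s <- summarize_group(num[[v]])
      data.frame(variable = v, mean = s$mean, sem = s$sem, n = s$n,
                 stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) {
    stop("need at least 2 values for a standard error", call. = FALSE)
  }
  list(mean = mean(x), sem = stats::sd(x) / sqrt(n), n = n)
}

#' Full swimming-fitness summary for one fish
#'
#' Combines the fitted VO2 curve, the derived COT curve and the fish's U_crit
#' into the standard set of swimming-economy quantities: SMR (intercept of
#' the VO2 curve), RMR (measured uptake at the 5 %U_crit minimal-flow
#' condition, if supplied), VO2max (fitted uptake at 100 %U_crit), U_opt on
#' the %U_crit axis and in m/s and BL/s, and COT_opt on the curve scale.
#'
#' @param speed_pct Measured speeds, %U_crit.
#' @param mo2 Measured uptake at each speed, umol g^-1 h^-1.
#' @param ucrit_ms The fish's critical swimming speed, m/s.
#' @param standard_bl_cm Standard body length, cm (for BL/s conversion).
#' @param rmr Optional measured routine metabolic rate (uptake at 5 %U_crit).
#' @return An object of class `swim_fitness`: list with `ucrit_ms`,
#'   `ucrit_bls`, `smr`, `rmr`, `vo2max`, `uopt_pct`, `uopt_ms`, `uopt_bls`,
#'   `cot_opt_curve` (curve scale), `cot_opt_per_m` (strict umol g^-1 m^-1,
#'   uptake at U_opt divided by U_opt in m/h), and the two fitted curves.
#' @export
swim_fitness <- function(speed_pct, mo2, ucrit_ms, standard_bl_cm,
                         rmr = NA_real_) {
  vo2 <- fit_vo2_curve(speed_pct, mo2, speed_axis = "pct_ucrit")
  cot <- fit_cot_curve(speed_pct, cot_from_vo2(mo2, speed_pct, "curve"),
                       speed_axis = "pct_ucrit")
  opt <- find_uopt(cot)
  uopt_ms <- opt$uopt / 100 * ucrit_ms
  vo2_at_uopt <- predict(vo2, opt$uopt)
  # strict units: speed in m/h = uopt_ms * 3600
  cot_per_m <- vo2_at_uopt / (uopt_ms * 3600)
  if (!(opt$uopt > 0 && opt$uopt < 100)) {
    warning("U_opt outside (0, U_crit); COT curve poorly constrained",
            call. = FALSE)
  }
  has_bl <- length(standard_bl_cm) == 1L && is.finite(standard_bl_cm) &&
    standard_bl_cm > 0
  structure(
    list(ucrit_ms = ucrit_ms,
         ucrit_bls = if (has_bl) to_relative_speed(ucrit_ms, standard_bl_cm)
                     else NA_real_,
         smr = vo2$smr, rmr = rmr, vo2max = predict(vo2, 100),
         uopt_pct = opt$uopt, uopt_ms = uopt_ms,
         uopt_bls = if (has_bl) to_relative_speed(uopt_ms, standard_bl_cm)
                    else NA_real_,
         cot_opt_curve = opt$cot_opt, cot_opt_per_m = cot_per_m,
         vo2_curve = vo2, cot_curve = cot),
    class = "swim_fitness"
  )
}

#' @export
print.swim_fitness <- function(x, ...) {
  cat(sprintf("U_crit:  %.3f m/s (%.1f BL/s)\n", x$ucrit_ms, x$ucrit_bls))
  cat(sprintf("SMR:     %.2f umol/g/h   VO2max: %.2f umol/g/h\n",
              x$smr, x$vo2max))
  if (is.finite(x$rmr)) cat(sprintf("RMR:     %.2f umol/g/h\n", x$rmr))
  cat(sprintf("U_opt:   %.2f %%U_crit = %.3f m/s (%.1f BL/s)\n",
              x$uopt_pct, x$uopt_ms, x$uopt_bls))
  cat(sprintf("COT_opt: %.2f (curve scale); %.4f umol/g/m strict\n",
              x$cot_opt_curve, x$cot_opt_per_m))
  invisible(x)
}
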