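# Fermentation-side quantitative methods: the glucose standard curve for
# total sugar (phenol-sulfuric assay, OD490), the size-exclusion
# chromatography log-linear molecular-weight calibration, and growth /
# degradation summaries over fermentation time series.

#' Fit a calibration line
#'
#' Ordinary least squares fit (via [stats::lm()]) underlying both
#' calibrations.  `r2 = 1 - SSres/SStot`, defined as 1 when both sums are
#' zero (a perfect fit to constant data).  A fitted slope of exactly zero
#' yields a curve that is rejected for calibration use by the prediction
#' functions.
#'
#' @param x,y Equal-length numeric vectors; at least two distinct `x`
#'   values.
#' @param kind `"sugar_standard"` (response = absorbance at 490 nm against
#'   concentration in mg/mL) or `"sec_mw"` (response = log10 molecular
#'   weight in Da against retention time in minutes; slope < 0 expected
#'   because larger molecules elute earlier -- the sign is recorded, not
#'   enforced).
#' @return A `calibration_curve`: list with `kind`, `slope`, `intercept`,
#'   `r2`, `x_domain`, `n`.
#' @export
fit_line <- function(x, y, kind = c("sugar_standard", "sec_mw")) {
  kind <- match.arg(kind)
  if (length(x) != length(y)) abort_parse("x and y must have equal length")
  if (length(x) < 2 || any(!is.finite(x)) || any(!is.finite(y))) {
    abort_parse("need >= 2 finite (x, y) points")
  }
  if (length(unique(x)) < 2) {
    abort_pulcall("degenerate fit: all x values identical", "pulcall_fit_error")
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-12) 1 else 0
  } else {
    max(0, min(1, 1 - ss_res / ss_tot))
  }
  structure(list(kind = kind, slope = unname(co[2]),
                 intercept = unname(co[1]), r2 = r2,
                 x_domain = range(x), n = length(x)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("calibration_curve [%s]: y = %.6g x + %.6g (r2 = %.4f, n = %d, x in [%g, %g])\n",
              x$kind, x$slope, x$intercept, x$r2, x$n,
              x$x_domain[1], x$x_domain[2]))
  invisible(x)
}

#' Fit the glucose standard curve
#'
#' Convenience wrapper: absorbance (OD490) regressed on glucose
#' concentration (mg/mL), the standard curve of the phenol-sulfuric total
#' sugar assay.
#'
#' @param concentration Glucose standard concentrations, mg/mL.
#' @param absorbance Measured OD490 values.
#' @return A `calibration_curve` of kind `sugar_standard`.
#' @export
fit_sugar_standard <- function(concentration, absorbance) {
  fit_line(concentration, absorbance, "sugar_standard")
}

#' Fit the SEC molecular-weight calibration
#'
#' Retention time regressed against log10 molecular weight.  The
#' relationship is implemented as affine log-linear (slope plus intercept):
#' pure proportionality through the origin cannot span the range of typical
#' dextran standard sets.
#'
#' @param retention_time Retention times of the standards, minutes.
#' @param mw_da Molecular weights of the standards, Da (`> 0`).
#' @return A `calibration_curve` of kind `sec_mw` whose response is
#'   `log10(Mw)`.
#' @export
fit_sec_calibration <- function(retention_time, mw_da) {
  if (any(mw_da <= 0)) abort_parse("molecular weights must be > 0")
  fit_line(retention_time, log10(mw_da), "sec_mw")
}

curve_accepted <- function(curve) {
  inherits(curve, "calibration_curve") && curve$slope != 0
}

#' Predict sugar concentration from absorbance
#'
#' Inverse prediction on the glucose standard curve:
#' `dilution_factor * (absorbance - intercept) / slope`.  Negative
#' predictions are clipped to 0 (concentrations are physical quantities);
#' the `clipped` attribute flags which values were clipped.
#'
#' @param absorbance OD490 value(s), `>= 0`.
#' @param curve A `calibration_curve` of kind `sugar_standard` with nonzero
#'   slope.
#' @param dilution_factor Dilution applied before the assay (`>= 1`).
#' @return Concentration(s) in mg/mL with logical attribute `clipped`.
#' @export
sugar_concentration <- function(absorbance, curve, dilution_factor = 1) {
  if (!inherits(curve, "calibration_curve") || curve$kind != "sugar_standard") {
    abort_type("sugar_concentration needs a sugar_standard calibration curve")
  }
  if (curve$slope == 0) abort_type("calibration curve rejected: zero slope")
  if (any(absorbance < 0)) abort_parse("absorbance must be >= 0")
  if (dilution_factor < 1) abort_parse("dilution_factor must be >= 1")
  conc <- dilution_factor * (absorbance - curve$intercept) / curve$slope
  clipped <- conc < 0
  conc[clipped] <- 0
  attr(conc, "clipped") <- clipped
  conc
}

#' Predict molecular weight from SEC retention time
#'
#' `Mw = 10^(slope * rt + intercept)`.  Queries outside the fitted
#' retention-time domain (extended by `margin`) raise an extrapolation
#' error naming the domain.
#'
#' @param retention_time Retention time(s), minutes.
#' @param curve A `calibration_curve` of kind `sec_mw` with nonzero slope.
#' @param margin Allowed extrapolation beyond the fitted domain, in
#'   minutes; default is `extrapolation_margin` (config, 0.1) times the
#'   domain width.
#' @return Molecular weight(s) in Da.
#' @export
mw_from_rt <- function(retention_time, curve, margin = NULL) {
  if (!inherits(curve, "calibration_curve") || curve$kind != "sec_mw") {
    abort_type("mw_from_rt needs a sec_mw calibration curve")
  }
  if (curve$slope == 0) abort_type("calibration curve rejected: zero slope")
  if (is.null(margin)) {
    margin <- cfg_num(read_run_config(), "extrapolation_margin") *
      diff(curve$x_domain)
  }
  lo <- curve$x_domain[1] - margin
  hi <- curve$x_domain[2] + margin
  if (any(retention_time < lo | retention_time > hi)) {
    bad <- retention_time[retention_time < lo | retention_time > hi][1]
    abort_lookup(sprintf(
      "retention time %.6g outside calibration domain [%.6g, %.6g] (margin %.3g)",
      bad, curve$x_domain[1], curve$x_domain[2], margin))
  }
  10^(curve$slope * retention_time + curve$intercept)
}

#' Degradation metrics of a declining time series
#'
#' Summarises a total-sugar or molecular-weight series: absolute drop and
#' percent drop between the first and last observation, and the interval of
#' steepest decline (the consecutive pair maximising
#' `(v_i - v_{i+1}) / (t_{i+1} - t_i)`, ties resolved to the earliest
#' interval).
#'
#' @param time Strictly increasing times, hours.
#' @param value Non-negative values; the first value must be positive for
#'   the percent drop to be defined.
#' @return List with `absolute_drop`, `percent_drop`, `steepest_interval`
#'   (`c(t_i, t_{i+1})`) and `steepest_rate` (value units per hour).
#' @examples
#' degradation_metrics(c(0, 12, 24, 48, 72),
#'                     c(23598.8, 22254.13, 20559.55, 20319.72, 18203.04))
#' @export
degradation_metrics <- function(time, value) {
  if (length(time) != length(value) || length(time) < 2) {
    abort_parse("need >= 2 (time, value) points")
  }
  if (any(diff(time) <= 0)) abort_parse("times must be strictly increasing")
  if (any(value < 0)) abort_parse("values must be >= 0")
  if (value[1] == 0) {
    abort_pulcall("percent drop undefined: first value is 0",
                  "pulcall_fit_error")
  }
  n <- length(value)
  rates <- (value[-n] - value[-1]) / diff(time)
  imax <- which.max(rates)  # which.max keeps the earliest tie
  list(absolute_drop = value[1] - value[n],
       percent_drop = 100 * (value[1] - value[n]) / value[1],
       steepest_interval = c(time[imax], time[imax + 1]),
       steepest_rate = rates[imax])
}

#' Summarise a growth curve into phases
#'
#' Phase boundaries from an OD600 series: `lag_end` is the last sampled time
#' before the curve first exceeds its initial value by `baseline_delta`;
#' `stationary_start` is the earliest time after which every successive
#' increase is below `plateau_eps`.  A series that never exceeds the
#' baseline is flagged `no_growth`; a monotone rise without plateau is
#' flagged `no_plateau` with `stationary_start` at the last time.
#'
#' @param time Strictly increasing times, hours (`>= 3` points).
#' @param value OD600 values.
#' @param baseline_delta OD increase over the initial value that ends the
#'   lag phase (default 0.05 OD).
#' @param plateau_eps Largest per-interval OD increase still considered
#'   stationary (default 0.02 OD).
#' @return A `growth_summary`: list with `lag_end`, `max_value`,
#'   `time_of_max`, `stationary_start`, `no_growth`, `no_plateau`.
#' @export
summarize_growth <- function(time, value, baseline_delta = 0.05,
                             plateau_eps = 0.02) {
  if (length(time) != length(value) || length(time) < 3) {
    abort_parse("need >= 3 (time, value) points")
  }
  if (any(diff(time) <= 0)) abort_parse("times must be strictly increasing")
  n <- length(value)
  exceeds <- which(value > value[1] + baseline_delta)
  no_growth <- !length(exceeds)
  lag_end <- if (no_growth) time[n] else time[exceeds[1] - 1L]
  imax <- which.max(value)
  diffs <- diff(value)
  big <- which(diffs >= plateau_eps)
  stat_i <- if (!length(big)) 1L else max(big) + 1L
  structure(list(
    lag_end = lag_end,
    max_value = value[imax],
    time_of_max = time[imax],
    stationary_start = time[stat_i],
    no_growth = no_growth,
    no_plateau = stat_i == n
  ), class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf("growth_summary: lag ends %g h, max %.3f at %g h, stationary from %g h%s%s\n",
              x$lag_end, x$max_value, x$time_of_max, x$stationary_start,
              if (x$no_growth) " [no growth]" else "",
              if (x$no_plateau) " [no plateau]" else ""))
  invisible(x)
}

#' Average replicate time series
#'
#' Replicates are summarised by mean and standard deviation per (analyte,
#' substrate, time) before phase detection.
#'
#' @param ts Long-format `data.frame` with columns `analyte`, `substrate`,
#'   `replicate`, `time_h`, `value`.
#' @return `data.frame` with columns `analyte`, `substrate`, `time_h`,
#'   `mean`, `sd`, `n`, sorted by time within series.
#' @export
average_replicates <- function(ts) {
  req <- c("analyte", "substrate", "replicate", "time_h", "value")
  if (!all(req %in% names(ts))) {
    abort_parse("time series needs columns analyte, substrate, replicate, time_h, value")
  }
  agg <- stats::aggregate(value ~ analyte + substrate + time_h, ts,
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  out <- data.frame(analyte = agg$analyte, substrate = agg$substrate,
                    time_h = agg$time_h,
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    n = as.integer(agg$value[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$analyte, out$substrate, out$time_h), , drop = FALSE]
}

#' Read / write fermentation time-series CSV
#'
#' Columns: `analyte`, `substrate`, `replicate`, `time_h`, `value`.
#'
#' @param path CSV path.
#' @return `data.frame` (reader) or `path` invisibly (writer).
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("time series not found: ", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_parse(paste0("cannot parse ", path)))
  req <- c("analyte", "substrate", "replicate", "time_h", "value")
  if (!all(req %in% names(df))) {
    abort_parse(paste0(path, " lacks column(s): ",
                       paste(setdiff(req, names(df)), collapse = ", ")))
  }
  df
}

#' @rdname read_timeseries_csv
#' @param ts Time-series `data.frame` to write.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(ts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibration input CSV
#'
#' Columns `x`, `y`, `kind`; one curve is fitted per `kind` value
#' (`sugar_standard`: x = concentration, y = absorbance; `sec_mw`: x =
#' retention time, y = molecular weight in Da).
#'
#' @param path CSV path.
#' @return `data.frame` with the three columns.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) abort_io(paste0("calibration table not found: ", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) abort_parse(paste0("cannot parse ", path)))
  if (!all(c("x", "y", "kind") %in% names(df))) {
    abort_parse("calibration table needs columns x, y, kind")
  }
  df
}
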