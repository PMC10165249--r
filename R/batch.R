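#' Batch drawdown series
#'
#' A timestamped set of NH4/NO2/NO3 concentration measurements from a batch
#' test, with the reactor metadata needed to convert volumetric rates to
#' membrane-area-specific rates.
#'
#' @param time_min Sampling times, minutes from the start (strictly
#'   increasing).
#' @param nh4,no2,no3 Concentrations, g N/m3 (mg N/L).
#' @param temperature Batch temperature, degC.
#' @param volume Total liquid volume, m3.
#' @param area Membrane surface area, m2.  The default corresponds to two
#'   1.87 m2 fibre bundles.
#' @param run Run label, `"first"` or `"second"`.
#' @param truth Optional list of generator truth values (kept by the
#'   synthetic-data module for recovery tests only).
#' @return Object of class `"batch_series"`: a data frame with columns
#'   `time_min`, `nh4_mgL`, `no2_mgL`, `no3_mgL` and metadata attributes.
#' @export
batch_series <- function(time_min, nh4, no2, no3, temperature,
                         volume, area = 3.74, run = "first", truth = NULL) {
  if (any(diff(time_min) <= 0))
    stop("batch_series: `time_min` must be strictly increasing",
         call. = FALSE)
  if (any(c(nh4, no2, no3) < 0))
    stop("batch_series: concentrations must be >= 0", call. = FALSE)
  if (volume <= 0 || area <= 0)
    stop("batch_series: `volume` and `area` must be > 0", call. = FALSE)
  df <- data.frame(time_min = time_min, nh4_mgL = nh4, no2_mgL = no2,
                   no3_mgL = no3)
  structure(df, temperature_C = temperature, volume_m3 = volume,
            area_m2 = area, run = run, truth = truth,
            class = c("batch_series", "data.frame"))
}

#' @export
print.batch_series <- function(x, ...) {
  cat(sprintf("batch series: %d samples at %g degC (run %s), V = %g m3, A = %g m2\n",
              nrow(x), attr(x, "temperature_C"), attr(x, "run"),
              attr(x, "volume_m3"), attr(x, "area_m2")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Windowed linear rate estimate from a batch series
#'
#' Ordinary least-squares slope of ammonium concentration against time,
#' restricted to samples whose NH4 lies inside the stated concentration
#' window (bounds inclusive), sign-flipped to a positive removal rate.  The
#' volumetric rate (g N m-3 d-1) is converted to an area-specific rate by
#' multiplying by the liquid volume and dividing by the membrane area.
#'
#' @param series A [batch_series()].
#' @param c_lo,c_hi Window bounds on measured NH4, g N/m3.
#' @return Object of class `"rate_estimate"`: list with `volumetric`
#'   (g N m-3 d-1), `areal` (g N m-2 d-1), the window, `n` points used,
#'   residual standard error and the series metadata.
#' @export
windowed_rate <- function(series, c_lo, c_hi) {
  if (c_lo >= c_hi)
    stop("windowed_rate: need c_lo < c_hi", call. = FALSE)
  sel <- series$nh4_mgL >= c_lo & series$nh4_mgL <= c_hi
  if (sum(sel) < 3)
    stop(sprintf(paste0("windowed_rate: only %d sample(s) inside the ",
                        "(%g, %g) g/m3 window; need at least 3"),
                 sum(sel), c_lo, c_hi), call. = FALSE)
  t_d <- (series$time_min[sel] - series$time_min[sel][1]) / 1440
  fit <- stats::lm(series$nh4_mgL[sel] ~ t_d)
  V <- attr(series, "volume_m3"); A <- attr(series, "area_m2")
  volumetric <- -unname(stats::coef(fit)[2])
  structure(list(volumetric = volumetric,
                 areal = volumetric * V / A,
                 window = c(c_lo, c_hi),
                 n = sum(sel),
                 ## suppress the "essentially perfect fit" note on noiseless data
                 sigma = suppressWarnings(summary(fit)$sigma),
                 temperature = attr(series, "temperature_C"),
                 run = attr(series, "run"),
                 volume = V, area = A),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(paste0("rate in window (%g, %g) g/m3 at %g degC: ",
                     "%.3f g N/m3/d volumetric, %.4f g N/m2/d areal ",
                     "(n = %d, rse = %.3g)\n"),
              x$window[1], x$window[2], x$temperature, x$volumetric,
              x$areal, x$n, x$sigma))
  invisible(x)
}

#' Fit an Arrhenius-type temperature correlation to rates
#'
#' Nonlinear least-squares fit of \eqn{R(T) = R_{T0} \, \theta^{T - T_0}} to
#' areal rates measured at several temperatures, by Levenberg-Marquardt.
#' Returns the classic modelling-object surface: `coef()`, `summary()`,
#' `predict()`, `plot()` and `residuals()` methods are available.
#'
#' @param rates Data frame with columns `temperature` (degC) and `rate`
#'   (positive), or a list of [windowed_rate()] estimates.
#' @param T0 Reference temperature, degC.
#' @return Object of class `"arrhenius_fit"` with components `R_T0`, `theta`,
#'   their standard errors, `T0`, the data and the underlying `nls` fit.
#' @examples
#' d <- data.frame(temperature = c(8, 12, 18, 24, 30),
#'                 rate = 3 * 1.03^(c(8, 12, 18, 24, 30) - 20))
#' fit <- fit_arrhenius(d, T0 = 20)
#' coef(fit)
#' @export
fit_arrhenius <- function(rates, T0 = 20) {
  if (is.list(rates) && !is.data.frame(rates) &&
      all(vapply(rates, inherits, logical(1), "rate_estimate")))
    rates <- data.frame(
      temperature = vapply(rates, `[[`, numeric(1), "temperature"),
      rate = vapply(rates, `[[`, numeric(1), "areal"))
  stopifnot(is.data.frame(rates),
            all(c("temperature", "rate") %in% names(rates)))
  if (length(unique(rates$temperature)) < 3)
    stop("fit_arrhenius: need rates at >= 3 distinct temperatures",
         call. = FALSE)
  if (any(rates$rate <= 0))
    stop("fit_arrhenius: all rates must be > 0", call. = FALSE)
  ## log-linear start (exact for noiseless data)
  ll <- stats::lm(log(rate) ~ I(temperature - T0), data = rates)
  start <- list(R0 = exp(unname(stats::coef(ll)[1])),
                theta = exp(unname(stats::coef(ll)[2])))
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ R0 * theta^(temperature - T0),
                      data = rates, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fit_arrhenius: nonlinear fit failed to converge: ",
           conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(R0 = NA_real_, theta = NA_real_))
  structure(list(R_T0 = unname(cf["R0"]), theta = unname(cf["theta"]),
                 se_R_T0 = unname(se["R0"]), se_theta = unname(se["theta"]),
                 T0 = T0, data = rates, fit = fit),
            class = "arrhenius_fit")
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(R_T0 = object$R_T0, theta = object$theta)
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius-type fit R(T) = R_T0 * theta^(T - %g)\n", x$T0))
  cat(sprintf("  R_T0 = %.4g (+/- %.2g), theta = %.4f (+/- %.4f)\n",
              x$R_T0, x$se_R_T0, x$theta, x$se_theta))
  invisible(x)
}

#' @export
summary.arrhenius_fit <- function(object, ...) summary(object$fit, ...)

#' @export
predict.arrhenius_fit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$data$temperature
       else if (is.data.frame(newdata)) newdata$temperature else newdata
  object$R_T0 * object$theta^(T - object$T0)
}

#' @export
residuals.arrhenius_fit <- function(object, ...) {
  object$data$rate - predict(object)
}

#' @export
plot.arrhenius_fit <- function(x, ...) {
  d <- x$data
  Tgrid <- seq(min(d$temperature), max(d$temperature), length.out = 100)
  graphics::plot(d$temperature, d$rate, xlab = "temperature (degC)",
                 ylab = "areal rate (g N/m2/d)",
                 main = sprintf("theta = %.3f", x$theta), ...)
  graphics::lines(Tgrid, x$R_T0 * x$theta^(Tgrid - x$T0), col = 2)
  invisible(x)
}

#' Average windowed rates over replicate runs
#'
#' Arithmetic mean of the areal rate per (temperature, window) group over the
#' replicate batch runs; groups with a single run pass through with
#' `single_run = TRUE`.
#'
#' @param estimates List of [windowed_rate()] objects, or a data frame with
#'   columns `temperature`, `c_lo`, `c_hi`, `run`, `areal`.
#' @return Data frame with one row per (temperature, window): mean areal
#'   rate, number of runs and the single-run flag.
#' @export
average_runs <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, function(e)
      data.frame(temperature = e$temperature, c_lo = e$window[1],
                 c_hi = e$window[2], run = e$run, areal = e$areal)))
  }
  if (is.null(estimates) || nrow(estimates) == 0)
    stop("average_runs: empty group of estimates", call. = FALSE)
  agg <- stats::aggregate(areal ~ temperature + c_lo + c_hi,
                          data = estimates,
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(temperature = agg$temperature, c_lo = agg$c_lo,
                    c_hi = agg$c_hi, rate = agg$areal[, "mean"],
                    n_runs = as.integer(agg$areal[, "n"]))
  out$single_run <- out$n_runs == 1L
  out[order(out$temperature, out$c_lo), , drop = FALSE]
}

#' Nitrite fraction of the oxidised nitrogen at the end of a batch
#'
#' `100 * NO2 / (NO2 + NO3)` at the last sample: the indicator of nitrite
#' oxidiser activity lagging ammonia oxidiser activity (nitrite
#' accumulation).
#'
#' @param series A [batch_series()].
#' @return Percentage in \[0, 100\].
#' @export
nitrite_accumulation <- function(series) {
  last <- series[nrow(series), ]
  ox <- last$no2_mgL + last$no3_mgL
  if (ox <= 0)
    stop("nitrite_accumulation: no oxidised nitrogen in the final sample; ",
         "fraction undefined", call. = FALSE)
  100 * last$no2_mgL / ox
}

#' Write / read a batch series as delimiter-separated text
#'
#' Plain tab-separated format with a commented metadata header
#' (`# temperature_C`, `# volume_m3`, `# area_m2`, `# run`) followed by the
#' columns `time_min`, `nh4_mgL`, `no2_mgL`, `no3_mgL`.
#'
#' @param series A [batch_series()].
#' @param path File path.
#' @return `write_batch_series()` returns `path` invisibly;
#'   `read_batch_series()` returns a [batch_series()].
#' @export
write_batch_series <- function(series, path) {
  meta <- c(sprintf("# temperature_C: %.10g", attr(series, "temperature_C")),
            sprintf("# volume_m3: %.10g", attr(series, "volume_m3")),
            sprintf("# area_m2: %.10g", attr(series, "area_m2")),
            sprintf("# run: %s", attr(series, "run")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(as.data.frame(series), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_batch_series
#' @export
read_batch_series <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  need <- c("temperature_C", "volume_m3", "area_m2", "run")
  if (!all(need %in% names(meta)))
    stop("read_batch_series: missing metadata header field(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t")
  batch_series(df$time_min, df$nh4_mgL, df$no2_mgL, df$no3_mgL,
               temperature = as.numeric(meta$temperature_C),
               volume = as.numeric(meta$volume_m3),
               area = as.numeric(meta$area_m2),
               run = meta$run)
}
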