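#' Simulate a mechanical-ventilation pressure/flow recording
#'
#' Forward model of single-compartment respiratory mechanics: a smooth
#' sinusoidal-squared tidal volume waveform is scaled so that the peak
#' airway pressure equals the requested maximal inspiratory pressure (MIP),
#' and pressure is synthesised as `P = E*V + R*V' + P0` plus additive
#' Gaussian noise.  Volume restarts at zero each cycle.
#'
#' @param E elastance, cmH2O/mL.
#' @param R resistance, cmH2O.s/mL.
#' @param P0 baseline pressure, cmH2O.
#' @param rate ventilation rate, breaths/min.
#' @param mip target maximal inspiratory pressure, cmH2O.
#' @param n_cycles number of breath cycles.
#' @param noise_sd pressure noise SD, cmH2O.
#' @param seed integer RNG seed (`NULL` uses the current stream).
#' @param fs sampling rate, Hz.
#' @return list of class `pressure_flow_signal` with uniform `time` (s),
#'   `pressure` (cmH2O), `flow` (mL/s) and metadata.
#' @export
generate_ventilation_signal <- function(E, R, P0 = 2, rate = 24, mip = 13,
                                        n_cycles = 3, noise_sd = 0.1,
                                        seed = NULL, fs = 200) {
  stopifnot(E > 0, R > 0, rate > 0, n_cycles >= 1, mip > P0)
  tcyc <- 60 / rate
  dt <- 1 / fs
  tt <- seq(0, n_cycles * tcyc - dt, by = dt)
  tph <- tt %% tcyc
  v1 <- sin(pi * tph / tcyc)^2                  # unit-amplitude volume
  dv1 <- pi / tcyc * sin(2 * pi * tph / tcyc)
  # scale tidal volume so peak P hits the MIP target
  peak1 <- max(E * v1 + R * dv1)
  vt <- (mip - P0) / peak1
  v <- vt * v1
  dv <- vt * dv1
  p <- E * v + R * dv + P0
  p <- with_seed(seed, p + stats::rnorm(length(p), 0, noise_sd))
  structure(list(time = tt, pressure = p, flow = dv,
                 meta = list(rate = rate, mip_design = mip, fs = fs,
                             truth = c(E = E, R = R, P0 = P0))),
            class = "pressure_flow_signal")
}

#' @export
print.pressure_flow_signal <- function(x, ...) {
  cat(sprintf(
    "<pressure_flow_signal> %.1f s at %d Hz, %g breaths/min, peak P %.1f cmH2O\n",
    max(x$time), x$meta$fs, x$meta$rate, max(x$pressure)))
  invisible(x)
}

#' Simulate a forced-expiration flow maneuver
#'
#' Exponentially decaying expiratory flow `(V0/tau) * exp(-t/tau)` sampled
#' until the flow has fallen to a negligible fraction of its peak, plus
#' additive Gaussian noise.  The noiseless integral of the full recording
#' equals `fvc_true` (up to trapezoidal quadrature error, relative ~1e-5).
#'
#' @param fvc_true total expired volume, mL.
#' @param tau expiratory time constant, s.
#' @param noise_sd flow noise SD, mL/s.
#' @param seed integer RNG seed.
#' @param fs sampling rate, Hz.
#' @param duration recording length in time constants.
#' @return list of class `flow_signal` with `time` (s) and `flow` (mL/s).
#' @export
generate_fvc_maneuver <- function(fvc_true, tau = 0.15, noise_sd = 0,
                                  seed = NULL, fs = 1000, duration = 12) {
  stopifnot(fvc_true > 0, tau > 0)
  tt <- seq(0, duration * tau, by = 1 / fs)
  fl <- fvc_true / tau * exp(-tt / tau)
  fl <- with_seed(seed, fl + stats::rnorm(length(fl), 0, noise_sd))
  structure(list(time = tt, flow = fl, meta = list(fvc_true = fvc_true,
                                                   tau = tau, fs = fs)),
            class = "flow_signal")
}

#' @export
print.flow_signal <- function(x, ...) {
  cat(sprintf("<flow_signal> %.2f s, peak flow %.0f mL/s\n",
              max(x$time), max(x$flow)))
  invisible(x)
}

#' Read/write pressure-flow and flow signals as CSV
#'
#' The on-disk dialect is a 3-column CSV `time_s, pressure_cmH2O, flow_mL_s`
#' (pressure all-`NA` for pure flow signals).
#'
#' @param x a `pressure_flow_signal` or `flow_signal`.
#' @param path file path.
#' @param rate breaths/min metadata to attach on read (pressure-flow only).
#' @return `read_signal_csv` returns a `pressure_flow_signal` when the
#'   pressure column is populated, otherwise a `flow_signal`.
#' @export
write_signal_csv <- function(x, path) {
  p <- if (!is.null(x$pressure)) x$pressure else rep(NA_real_, length(x$time))
  utils::write.csv(data.frame(time_s = x$time, pressure_cmH2O = p,
                              flow_mL_s = x$flow),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path, rate = NA_real_) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "pressure_cmH2O", "flow_mL_s") %in% names(d)))
  fs <- 1 / stats::median(diff(d$time_s))
  if (all(is.na(d$pressure_cmH2O)))
    structure(list(time = d$time_s, flow = d$flow_mL_s,
                   meta = list(fs = fs)), class = "flow_signal")
  else
    structure(list(time = d$time_s, pressure = d$pressure_cmH2O,
                   flow = d$flow_mL_s, meta = list(rate = rate, fs = fs)),
              class = "pressure_flow_signal")
}
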