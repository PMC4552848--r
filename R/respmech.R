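#' Single-compartment respiratory mechanics by recursive least squares
#'
#' Fits the single-compartment equation of motion
#' `P(t) = E*V(t) + R*V'(t) + P0` to an airway pressure/flow recording.
#' Volume is obtained by trapezoidal integration of flow with a per-cycle
#' linear drift correction (volume returns to zero at each cycle boundary).
#' The parameters are estimated recursively with exponential forgetting and
#' a large diagonal covariance initialisation; the reported elastance and
#' resistance are the means of the recursive estimates over the final
#' breath cycle.  Records whose maximal inspiratory pressure (MIP, the peak
#' of the lightly smoothed pressure) exceeds 14 cmH2O are flagged `gated`
#' and excluded from cohort analyses, since such inflations exceed the
#' linear elastic range of tidal breathing.
#'
#' @param signal a [generate_ventilation_signal()]-type `pressure_flow_signal`
#'   (uniform sampling, at least 3 breath cycles).
#' @param forgetting exponential forgetting factor in `(0.9, 1]`.
#' @param mip_limit gating threshold, cmH2O.
#' @param cov_init initial covariance scale of the recursive estimator.
#' @return object of class `resp_fit` with coefficients `E` (cmH2O/mL),
#'   `R` (cmH2O.s/mL), `P0` (cmH2O), recursive traces, fitted values,
#'   `MIP` and the `gated` flag.  Supports `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot` and `simulate` methods.
#' @export
fit_single_compartment <- function(signal, forgetting = 0.995,
                                   mip_limit = 14, cov_init = 1e6) {
  stopifnot(inherits(signal, "pressure_flow_signal"))
  if (forgetting <= 0.9 || forgetting > 1)
    stop("forgetting factor must lie in (0.9, 1]")
  tt <- signal$time
  dt <- diff(tt)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("signal must be uniformly sampled")
  dt <- dt[1]
  rate <- signal$meta$rate
  if (is.null(rate) || is.na(rate))
    stop("signal metadata must carry the ventilation rate")
  tcyc <- 60 / rate
  n_cycles <- floor((max(tt) + dt) / tcyc + 1e-9)
  if (n_cycles < 3)
    stop("at least 3 complete breath cycles are required")

  # volume by trapezoidal integration with per-cycle drift correction
  n <- length(tt)
  v_raw <- c(0, cumsum((signal$flow[-1] + signal$flow[-n]) / 2 * dt))
  cyc <- pmin(floor(tt / tcyc) + 1L, n_cycles)
  v <- numeric(n)
  for (ci in seq_len(n_cycles)) {
    sel <- which(cyc == ci)
    vs <- v_raw[sel]
    drift <- (vs[length(vs)] - vs[1]) / (tt[sel[length(sel)]] - tt[sel[1]])
    v[sel] <- vs - vs[1] - drift * (tt[sel] - tt[sel[1]])
  }

  # recursive least squares on theta = (E, R, P0)
  lambda <- forgetting
  theta <- c(0, 0, 0)
  P <- diag(cov_init, 3)
  trace <- matrix(NA_real_, n, 3,
                  dimnames = list(NULL, c("E", "R", "P0")))
  for (i in seq_len(n)) {
    phi <- c(v[i], signal$flow[i], 1)
    Pphi <- P %*% phi
    k <- Pphi / (lambda + sum(phi * Pphi))
    theta <- theta + as.numeric(k) * (signal$pressure[i] - sum(phi * theta))
    P <- (P - k %*% t(phi) %*% P) / lambda
    trace[i, ] <- theta
  }
  if (!all(is.finite(theta)) || kappa(P, exact = FALSE) > 1e14)
    stop("ill-conditioned recursive estimator (degenerate excitation)")

  final <- which(cyc == n_cycles)
  est <- colMeans(trace[final, , drop = FALSE])
  fitted <- est["E"] * v + est["R"] * signal$flow + est["P0"]

  # MIP from lightly smoothed pressure (25 ms moving average)
  w <- max(1L, round(0.025 / dt))
  psm <- as.numeric(stats::filter(signal$pressure, rep(1 / w, w),
                                  sides = 2))
  mip <- max(psm, na.rm = TRUE)

  structure(list(coefficients = est, trace = trace, volume = v,
                 fitted.values = fitted,
                 residuals = signal$pressure - fitted,
                 signal = signal, forgetting = forgetting,
                 MIP = mip, gated = mip > mip_limit,
                 mip_limit = mip_limit, n_cycles = n_cycles),
            class = "resp_fit")
}

#' @export
print.resp_fit <- function(x, ...) {
  cat(sprintf(
    "<resp_fit> E %.4g cmH2O/mL, R %.4g cmH2O.s/mL, P0 %.3g cmH2O\n",
    x$coefficients["E"], x$coefficients["R"], x$coefficients["P0"]))
  cat(sprintf("  MIP %.1f cmH2O%s, %d cycles, forgetting %.3f\n",
              x$MIP, if (x$gated) " [gated: above linear range]" else "",
              x$n_cycles, x$forgetting))
  invisible(x)
}

#' @export
coef.resp_fit <- function(object, ...) object$coefficients

#' @export
residuals.resp_fit <- function(object, ...) object$residuals

#' @export
fitted.resp_fit <- function(object, ...) object$fitted.values

#' @export
summary.resp_fit <- function(object, ...) {
  # batch OLS on the same regressors for reference standard errors
  X <- cbind(V = object$volume, dV = object$signal$flow, 1)
  fit <- stats::lm.fit(X, object$signal$pressure)
  sigma2 <- sum(fit$residuals^2) / (length(fit$residuals) - 3)
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2)
  out <- list(fit = object,
              ols = stats::setNames(fit$coefficients, c("E", "R", "P0")),
              se = stats::setNames(se, c("E", "R", "P0")),
              rmse = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.resp_fit"
  out
}

#' @export
print.summary.resp_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  batch OLS reference: E %.4g, R %.4g, P0 %.3g (SE %.2g/%.2g/%.2g)\n",
              x$ols["E"], x$ols["R"], x$ols["P0"],
              x$se["E"], x$se["R"], x$se["P0"]))
  cat(sprintf("  residual RMS %.3g cmH2O\n", x$rmse))
  invisible(x)
}

#' @export
predict.resp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  stopifnot(inherits(newdata, "pressure_flow_signal"))
  refit <- fit_single_compartment(newdata, forgetting = object$forgetting,
                                  mip_limit = object$mip_limit)
  est <- object$coefficients
  est["E"] * refit$volume + est["R"] * newdata$flow + est["P0"]
}

#' @export
plot.resp_fit <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(oldpar))
  graphics::plot(x$signal$time, x$signal$pressure, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "pressure (cmH2O)",
                 main = "observed vs fitted airway pressure")
  graphics::lines(x$signal$time, x$fitted.values, col = "red3")
  graphics::matplot(x$signal$time, x$trace[, c("E", "R")], type = "l",
                    lty = 1, xlab = "time (s)", ylab = "estimate",
                    main = "recursive estimates (E, R)")
  invisible(x)
}

#' @export
simulate.resp_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0.1,
                              ...) {
  est <- object$coefficients
  with_seed(seed, lapply(seq_len(nsim), function(i)
    generate_ventilation_signal(E = est[["E"]], R = est[["R"]],
                                P0 = est[["P0"]],
                                rate = object$signal$meta$rate,
                                mip = object$MIP,
                                n_cycles = object$n_cycles,
                                noise_sd = noise_sd,
                                fs = object$signal$meta$fs)))
}

# integrate one forced-expiration maneuver up to flow cessation
integrate_maneuver <- function(sig, cessation_frac = 0.02, sustain_s = 0.05) {
  stopifnot(inherits(sig, "flow_signal"))
  tt <- sig$time
  fl <- sig$flow
  dt <- stats::median(diff(tt))
  peak <- max(fl)
  thr <- cessation_frac * peak
  below <- abs(fl) < thr
  need <- max(1L, round(sustain_s / dt))
  run <- 0L
  stop_i <- length(fl)
  for (i in seq_along(fl)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= need) { stop_i <- i; break }
  }
  sel <- seq_len(stop_i)
  cumvol <- c(0, cumsum((fl[sel][-1] + fl[sel][-stop_i]) / 2 * diff(tt[sel])))
  vol <- cumvol[length(cumvol)]
  # a forced expiration must not "un-expire": cumulative volume may not
  # retreat from its running maximum by more than 2% of the total
  valid <- max(cummax(cumvol) - cumvol) <= 0.02 * max(cumvol)
  list(volume_ml = vol, valid = valid, stop_time_s = tt[stop_i])
}

#' Forced vital capacity with the repeatability rule
#'
#' Integrates each forced-expiration flow signal from expiration onset
#' until flow ceases (|flow| below 2% of the peak for at least 50 ms).
#' With at least two valid maneuvers whose expired volumes all lie within a
#' 10% disparity margin of the maximum, FVC is the maximum expired volume;
#' otherwise FVC is missing with the reason reported.  Disparity is
#' `(max - min) / max` over the valid maneuvers.
#'
#' @param maneuvers list of `flow_signal` objects (at least one).
#' @param disparity_margin maximum allowed disparity (default 0.10).
#' @param cessation_frac flow-cessation threshold as a fraction of peak
#'   expiratory flow.
#' @param sustain_s time the flow must remain below threshold, s.
#' @return list of class `fvc_result`: `FVC` (mL or `NA`), per-maneuver
#'   `volumes_ml` and `valid` flags, `disparity`, `reason`.
#' @export
forced_vital_capacity <- function(maneuvers, disparity_margin = 0.10,
                                  cessation_frac = 0.02, sustain_s = 0.05) {
  if (inherits(maneuvers, "flow_signal")) maneuvers <- list(maneuvers)
  stopifnot(length(maneuvers) >= 1)
  res <- lapply(maneuvers, integrate_maneuver,
                cessation_frac = cessation_frac, sustain_s = sustain_s)
  vols <- vapply(res, `[[`, numeric(1), "volume_ml")
  valid <- vapply(res, `[[`, logical(1), "valid")
  vv <- vols[valid]
  fvc <- NA_real_
  disp <- NA_real_
  if (length(vv) < 2) {
    reason <- "fewer than 2 valid maneuvers"
  } else {
    disp <- (max(vv) - min(vv)) / max(vv)
    if (disp <= disparity_margin) {
      fvc <- max(vv)
      reason <- "accepted"
    } else {
      reason <- sprintf("repeatability failure (%.1f%% disparity)",
                        100 * disp)
    }
  }
  structure(list(FVC = fvc, volumes_ml = vols, valid = valid,
                 disparity = disp, reason = reason,
                 disparity_margin = disparity_margin),
            class = "fvc_result")
}

#' @export
print.fvc_result <- function(x, ...) {
  cat(sprintf("<fvc_result> FVC %s mL (%s); maneuvers: %s\n",
              ifelse(is.na(x$FVC), "missing", sprintf("%.1f", x$FVC)),
              x$reason,
              paste(sprintf("%.1f", x$volumes_ml), collapse = ", ")))
  invisible(x)
}
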