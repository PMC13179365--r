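# Impedimetric film-degradation analysis.
#
# A PET film separating two electrode chambers behaves, to first order, as a
# simplified Randles equivalent circuit: solution resistance R_s in series
# with the parallel combination of a charge-transfer resistance R_ct and the
# film capacitance C. As the enzyme thins the film the capacitance rises
# (parallel-plate law), so fitted capacitances track film thickness and the
# degradation rate in um/h.

#' Randles circuit parameters
#'
#' @param R_s solution resistance, ohm.
#' @param R_ct charge-transfer resistance, ohm.
#' @param C_film film capacitance, farad.
#' @return object of class \code{pk_randles}.
#' @export
randles_params <- function(R_s, R_ct, C_film) {
  .check_number(R_s, "R_s", positive = TRUE)
  .check_number(R_ct, "R_ct", positive = TRUE)
  .check_number(C_film, "C_film", positive = TRUE)
  structure(list(R_s = R_s, R_ct = R_ct, C_film = C_film),
            class = "pk_randles")
}

#' @export
print.pk_randles <- function(x, ...) {
  cat(sprintf("<randles> R_s = %.4g ohm, R_ct = %.4g ohm, C = %.4g F\n",
              x$R_s, x$R_ct, x$C_film))
  invisible(x)
}

#' Film geometry for the parallel-plate conversion
#'
#' @param epsilon_r relative permittivity of PET (default 3.3).
#' @param area_mm2 exposed film area in mm^2 (default 44.7). The effective
#'   dielectric aperture may differ from the film area in a given cell;
#'   override as needed.
#' @return object of class \code{pk_film_geometry}.
#' @export
film_geometry <- function(epsilon_r = 3.3, area_mm2 = 44.7) {
  .check_number(epsilon_r, "epsilon_r", positive = TRUE)
  if (epsilon_r <= 1) stop("'epsilon_r' must be > 1", call. = FALSE)
  .check_number(area_mm2, "area_mm2", positive = TRUE)
  structure(list(epsilon_r = epsilon_r, area_m2 = area_mm2 * 1e-6,
                 epsilon_0 = 8.8541878128e-12),
            class = "pk_film_geometry")
}

#' Complex impedance of the simplified Randles circuit
#'
#' \deqn{Z(\omega) = R_s + R_{ct} / (1 + i \omega R_{ct} C)}
#' with \eqn{\omega = 2\pi f}. The imaginary part is <= 0 at every frequency
#' for positive parameters.
#'
#' @param params \code{pk_randles}.
#' @param frequency frequency in Hz, vectorised, all > 0.
#' @return complex impedance in ohm.
#' @export
randles_impedance <- function(params, frequency) {
  stopifnot(inherits(params, "pk_randles"))
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequencies must be finite and > 0", call. = FALSE)
  omega <- 2 * pi * frequency
  params$R_s + params$R_ct / (1 + 1i * omega * params$R_ct * params$C_film)
}

#' Assemble an impedance spectrum
#'
#' @param frequencies Hz; at least 6 points; need not be sorted (sorted
#'   internally, fits are order-invariant).
#' @param impedance complex ohm, same length.
#' @param time_h hours since reaction start (metadata).
#' @return object of class \code{pk_spectrum}.
#' @export
impedance_spectrum <- function(frequencies, impedance, time_h = NA_real_) {
  stopifnot(length(frequencies) == length(impedance))
  if (length(frequencies) < 6L)
    stop("an impedance spectrum needs at least 6 frequency points",
         call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be finite and > 0", call. = FALSE)
  o <- order(frequencies)
  frequencies <- frequencies[o]
  impedance <- impedance[o]
  if (any(duplicated(frequencies)))
    stop("frequencies must be strictly increasing after sorting", call. = FALSE)
  if (any(Re(impedance) <= 0))
    stop("real part of the impedance must be > 0 at every point", call. = FALSE)
  structure(list(frequencies = frequencies, impedance = as.complex(impedance),
                 time_h = time_h),
            class = "pk_spectrum")
}

#' Fit the Randles model to a spectrum
#'
#' Least-squares fit of the stacked real and imaginary residuals, each point
#' weighted by 1/|Z| so that the decades-spanning magnitude does not let the
#' low-frequency points dominate. Default initial values: R_s from the
#' highest-frequency real part, R_s + R_ct from the lowest-frequency
#' magnitude, and C from the frequency of the imaginary-part extremum
#' (omega = 1/(R_ct C) at the semicircle apex).
#'
#' @param spectrum \code{pk_spectrum}.
#' @param initial optional \code{pk_randles} start values.
#' @return \code{pk_randles} with attributes \code{se} (standard errors),
#'   \code{rss}, \code{converged}, \code{niter}.
#' @export
fit_randles <- function(spectrum, initial = NULL) {
  stopifnot(inherits(spectrum, "pk_spectrum"))
  f <- spectrum$frequencies
  Z <- spectrum$impedance
  if (length(f) < 3L)
    stop("underdetermined: need at least 3 frequency points for 3 parameters",
         call. = FALSE)
  w <- 1 / Mod(Z)

  if (is.null(initial)) {
    Rs0 <- max(Re(Z[which.max(f)]), 1e-6)
    Rct0 <- max(Mod(Z[which.min(f)]) - Rs0, 10 * .Machine$double.eps * Rs0)
    iext <- which.min(Im(Z))  # most negative imaginary part
    C0 <- 1 / (2 * pi * f[iext] * Rct0)
    initial <- randles_params(Rs0, Rct0, C0)
  }
  # log-parameterisation keeps everything positive and spans decades evenly
  p0 <- log(c(R_s = initial$R_s, R_ct = initial$R_ct, C = initial$C_film))

  resid_fn <- function(p) {
    q <- exp(p)
    g <- 1 / q[2] + 1i * 2 * pi * f * q[3]
    Zm <- q[1] + 1 / g
    c(w * (Re(Zm) - Re(Z)), w * (Im(Zm) - Im(Z)))
  }
  jac_fn <- function(p) {
    q <- exp(p)
    g <- 1 / q[2] + 1i * 2 * pi * f * q[3]
    dRs <- rep(1 + 0i, length(f))
    dRct <- (1 / g^2) / q[2]^2          # d(1/g)/dRct
    dC <- -(1 / g^2) * (1i * 2 * pi * f)
    # chain rule for log-params: d/dlog(q) = q * d/dq
    J <- cbind(q[1] * dRs, q[2] * dRct, q[3] * dC)
    rbind(w * Re(J), w * Im(J))
  }
  fit <- lm_least_squares(p0, resid_fn, jac_fn)
  q <- exp(fit$par)
  out <- randles_params(q[[1]], q[[2]], q[[3]])
  # delta method back from log scale
  se <- if (all(is.finite(fit$se))) q * fit$se else rep(NA_real_, 3)
  attr(out, "se") <- setNames(se, c("R_s", "R_ct", "C_film"))
  attr(out, "rss") <- fit$rss
  attr(out, "converged") <- fit$converged
  attr(out, "niter") <- fit$niter
  if (!fit$converged)
    warning(sprintf("Randles fit did not converge (rss = %g)", fit$rss))
  out
}

#' Convert film capacitance to thickness (parallel plate)
#'
#' \deqn{d = \epsilon_0 \epsilon_r A / C}
#'
#' @param C_film capacitance in farad (vectorised, > 0).
#' @param geometry \code{pk_film_geometry}.
#' @return thickness in micrometres.
#' @export
capacitance_to_thickness <- function(C_film, geometry = film_geometry()) {
  stopifnot(inherits(geometry, "pk_film_geometry"))
  if (any(!is.finite(C_film)) || any(C_film <= 0))
    stop("capacitance must be finite and > 0", call. = FALSE)
  d_m <- geometry$epsilon_0 * geometry$epsilon_r * geometry$area_m2 / C_film
  d_m * 1e6
}

#' Inverse of \code{capacitance_to_thickness}
#'
#' @param thickness_um film thickness in micrometres (> 0).
#' @param geometry \code{pk_film_geometry}.
#' @return capacitance in farad.
#' @export
thickness_to_capacitance <- function(thickness_um, geometry = film_geometry()) {
  stopifnot(inherits(geometry, "pk_film_geometry"))
  if (any(!is.finite(thickness_um)) || any(thickness_um <= 0))
    stop("thickness must be finite and > 0", call. = FALSE)
  geometry$epsilon_0 * geometry$epsilon_r * geometry$area_m2 /
    (thickness_um * 1e-6)
}

#' Fit a time series of spectra and convert to thickness
#'
#' Fits each sweep with \code{\link{fit_randles}} (warm-starting each fit at
#' the previous sweep's parameters) and inverts the fitted capacitances to a
#' thickness series.
#'
#' @param spectra list of \code{pk_spectrum} with \code{time_h} set.
#' @param geometry \code{pk_film_geometry}.
#' @return data.frame \code{time_h, R_s, R_ct, C_farad, thickness_um, rss}
#'   of class \code{pk_thickness_series}.
#' @export
fit_eis_series <- function(spectra, geometry = film_geometry()) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "pk_spectrum")))
  times <- vapply(spectra, function(s) s$time_h, 1.0)
  o <- order(times)
  spectra <- spectra[o]
  prev <- NULL
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    fit <- fit_randles(spectra[[i]], initial = prev)
    prev <- fit
    rows[[i]] <- data.frame(
      time_h = spectra[[i]]$time_h, R_s = fit$R_s, R_ct = fit$R_ct,
      C_farad = fit$C_film,
      thickness_um = capacitance_to_thickness(fit$C_film, geometry),
      rss = attr(fit, "rss"))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pk_thickness_series", class(out))
  out
}

#' Film degradation rate over a time window
#'
#' Per-point thinning rates are central finite differences of a locally
#' smoothed thickness series (centered rolling linear fit, default 1 h
#' window); the reported rate is their mean over the window, positive when
#' the film thins. Exact on a linear series regardless of smoothing.
#'
#' @param time_h times in hours, ascending.
#' @param thickness_um thickness in micrometres (or a
#'   \code{pk_thickness_series} passed as \code{time_h}).
#' @param window length-2 window in hours, default \code{c(3, 8)}.
#' @param smooth_half_window_h half-width of the rolling linear smoother in
#'   hours (default 0.5, i.e. a 1 h window).
#' @return object of class \code{pk_rate}: list with \code{rate_um_h},
#'   \code{window}, \code{point_rates} (data.frame time_h, rate_um_h).
#' @export
degradation_rate <- function(time_h, thickness_um = NULL, window = c(3, 8),
                             smooth_half_window_h = 0.5) {
  if (inherits(time_h, "pk_thickness_series")) {
    thickness_um <- time_h$thickness_um
    time_h <- time_h$time_h
  }
  stopifnot(length(time_h) == length(thickness_um), length(window) == 2L,
            window[1] < window[2])
  if (any(thickness_um <= 0)) stop("thickness must be > 0", call. = FALSE)
  o <- order(time_h)
  time_h <- time_h[o]; thickness_um <- thickness_um[o]
  if (window[1] < min(time_h) || window[2] > max(time_h))
    stop("rate window lies outside the measured time range", call. = FALSE)

  sm <- rolling_linear(time_h, thickness_um, smooth_half_window_h)$value
  n <- length(time_h)
  rate <- rep(NA_real_, n)
  if (n >= 3L) {
    i <- 2:(n - 1)
    rate[i] <- -(sm[i + 1] - sm[i - 1]) / (time_h[i + 1] - time_h[i - 1])
  }
  rate[1] <- -(sm[2] - sm[1]) / (time_h[2] - time_h[1])
  rate[n] <- -(sm[n] - sm[n - 1]) / (time_h[n] - time_h[n - 1])

  inwin <- time_h >= window[1] & time_h <= window[2]
  if (sum(inwin) < 3L)
    stop("need at least 3 points inside the rate window", call. = FALSE)
  structure(list(rate_um_h = mean(rate[inwin]),
                 window = window,
                 point_rates = data.frame(time_h = time_h[inwin],
                                          rate_um_h = rate[inwin])),
            class = "pk_rate")
}

#' @export
print.pk_rate <- function(x, ...) {
  cat(sprintf("<degradation rate> %.3f um/h (mean over %g-%g h, %d points)\n",
              x$rate_um_h, x$window[1], x$window[2], nrow(x$point_rates)))
  invisible(x)
}

#' Read spectra from a long-format CSV
#'
#' Columns \code{time_h, frequency_hz, z_real_ohm, z_imag_ohm}, one row per
#' frequency per sweep.
#'
#' @param path CSV path.
#' @return list of \code{pk_spectrum}.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_h", "frequency_hz", "z_real_ohm", "z_imag_ohm")
  if (!all(need %in% names(df)))
    stop("spectra CSV must have columns time_h, frequency_hz, z_real_ohm, z_imag_ohm",
         call. = FALSE)
  lapply(split(df, df$time_h), function(d)
    impedance_spectrum(d$frequency_hz, complex(real = d$z_real_ohm,
                                               imaginary = d$z_imag_ohm),
                       time_h = d$time_h[1]))
}

#' Write spectra to a long-format CSV
#' @param spectra list of \code{pk_spectrum}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_spectra_csv <- function(spectra, path) {
  df <- do.call(rbind, lapply(spectra, function(s)
    data.frame(time_h = s$time_h, frequency_hz = s$frequencies,
               z_real_ohm = Re(s$impedance), z_imag_ohm = Im(s$impedance))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
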