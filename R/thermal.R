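# nanoDSF melt-curve simulation and melting-point extraction.
#
# Label-free differential scanning fluorimetry follows intrinsic tryptophan
# fluorescence at 330 and 350 nm while ramping temperature (20-95 C at
# 1 C/min is the standard protocol). Unfolding red-shifts the emission, so
# the F350/F330 ratio traces a sigmoid whose first-derivative peak defines
# the apparent melting temperature Tm. Synthesis uses a two-state van't
# Hoff model; extraction uses central differences with 3-point quadratic
# peak interpolation, the standard instrument convention.

GAS_CONSTANT_KJ <- 8.31446261815324e-3  # kJ mol^-1 K^-1

#' Two-state melt model
#'
#' @param Tm_C midpoint temperature, Celsius.
#' @param dH_vH_kJ van't Hoff enthalpy, kJ/mol (> 0; larger = sharper
#'   transition; 400 kJ/mol is typical for a single-domain hydrolase).
#' @param baseline_folded \code{c(intercept, slope_per_C)} of the folded
#'   ratio baseline.
#' @param baseline_unfolded same for the unfolded state.
#' @return object of class \code{pk_melt_model}.
#' @export
melt_model <- function(Tm_C, dH_vH_kJ = 400,
                       baseline_folded = c(0.80, 0),
                       baseline_unfolded = c(1.00, 0)) {
  .check_number(Tm_C, "Tm_C")
  .check_number(dH_vH_kJ, "dH_vH_kJ", positive = TRUE)
  stopifnot(length(baseline_folded) == 2L, length(baseline_unfolded) == 2L)
  structure(list(Tm_C = Tm_C, dH_vH_kJ = dH_vH_kJ,
                 baseline_folded = baseline_folded,
                 baseline_unfolded = baseline_unfolded),
            class = "pk_melt_model")
}

#' Fraction unfolded under the two-state model
#'
#' \deqn{f(T) = 1 / (1 + \exp[(\Delta H_{vH}/R)(1/T - 1/T_m)])}
#' with temperatures in kelvin; \code{f(Tm) = 0.5}.
#'
#' @param temp_C temperatures in Celsius (vectorised).
#' @param model \code{pk_melt_model}.
#' @return fraction unfolded in [0, 1].
#' @export
fraction_unfolded <- function(temp_C, model) {
  stopifnot(inherits(model, "pk_melt_model"))
  TK <- temp_C + 273.15
  TmK <- model$Tm_C + 273.15
  1 / (1 + exp((model$dH_vH_kJ / GAS_CONSTANT_KJ) * (1 / TK - 1 / TmK)))
}

#' Simulate a nanoDSF ratio melt curve
#'
#' Ratio = (1 - f) * folded baseline + f * unfolded baseline + Gaussian
#' noise; baselines are linear in temperature.
#'
#' @param model \code{pk_melt_model}; the midpoint must lie on (or the
#'   transition be deliberately beyond) the ramp.
#' @param temp_C temperature grid in Celsius, default \code{seq(20, 95, 1)}
#'   matching a 1 C/min ramp sampled each minute.
#' @param noise_sd Gaussian noise SD in ratio units (default 0).
#' @param allow_out_of_ramp permit Tm beyond the grid (used to emulate
#'   "> 95 C" melters); default FALSE.
#' @return object of class \code{pk_melt_curve}: data.frame-like list with
#'   \code{temp_C}, \code{ratio}.
#' @export
simulate_melt <- function(model, temp_C = seq(20, 95, by = 1), noise_sd = 0,
                          allow_out_of_ramp = FALSE) {
  stopifnot(inherits(model, "pk_melt_model"))
  if (length(temp_C) < 20L)
    stop("melt curve needs at least 20 temperature points", call. = FALSE)
  if (any(diff(temp_C) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  if (!allow_out_of_ramp &&
      (model$Tm_C < min(temp_C) || model$Tm_C > max(temp_C)))
    stop("model Tm lies outside the temperature ramp; set allow_out_of_ramp = TRUE to simulate a censored melter",
         call. = FALSE)
  f <- fraction_unfolded(temp_C, model)
  bf <- model$baseline_folded[1] + model$baseline_folded[2] * temp_C
  bu <- model$baseline_unfolded[1] + model$baseline_unfolded[2] * temp_C
  ratio <- (1 - f) * bf + f * bu
  if (noise_sd > 0) ratio <- ratio + stats::rnorm(length(ratio), 0, noise_sd)
  melt_curve(temp_C, ratio)
}

#' Construct a melt curve from measured data
#'
#' @param temp_C temperatures, strictly increasing, >= 20 points.
#' @param ratio F350/F330 ratio (or any monotone-transition signal).
#' @return object of class \code{pk_melt_curve}.
#' @export
melt_curve <- function(temp_C, ratio) {
  stopifnot(length(temp_C) == length(ratio))
  if (length(temp_C) < 20L)
    stop("melt curve needs at least 20 temperature points", call. = FALSE)
  if (any(diff(temp_C) <= 0))
    stop("temperatures must be strictly increasing", call. = FALSE)
  structure(list(temp_C = as.numeric(temp_C), ratio = as.numeric(ratio)),
            class = "pk_melt_curve")
}

#' Extract the apparent melting temperature
#'
#' Tm is the argmax of the first derivative of the ratio signal, computed
#' by central differences and refined by a 3-point quadratic interpolation
#' around the peak. By default the derivative is taken against reciprocal
#' absolute temperature: for a two-state van't Hoff transition with flat
#' baselines, d(signal)/d(1/T) is proportional to f(1-f) and peaks exactly
#' at the midpoint, whereas the plain dT peak sits ~0.1 K below it (the
#' 1/T^2 tilt). The conventional d/dT axis is available via
#' \code{axis = "celsius"}; the two differ by well under the instrument
#' resolution for sharp transitions. Peaks within one grid step of the ramp
#' end are reported as censored bounds ("> ramp max"), mirroring instrument
#' detection limits. Invariant under affine transforms of the signal (a
#' positive scale plus offset).
#'
#' @param curve \code{pk_melt_curve}.
#' @param axis derivative axis: \code{"reciprocal"} (default, unbiased for
#'   the van't Hoff model) or \code{"celsius"}.
#' @param smooth_k half-width (grid points) of the local-linear derivative
#'   window and of the quadratic vertex fit. \code{NULL} (default) selects
#'   1 (plain central differences) for effectively noiseless curves and 3
#'   for noisy ones, using a robust second-difference noise estimate.
#' @return object of class \code{pk_tm}: list with \code{Tm_C} (NA when
#'   censored), \code{censored} (logical), \code{bound_C} (ramp edge when
#'   censored), \code{ambiguous} (TRUE when several equal peaks; the first
#'   is used).
#' @export
extract_tm <- function(curve, axis = c("reciprocal", "celsius"),
                       smooth_k = NULL) {
  stopifnot(inherits(curve, "pk_melt_curve"))
  axis <- match.arg(axis)
  x <- if (axis == "reciprocal") -1 / (curve$temp_C + 273.15)
       else curve$temp_C          # both strictly increasing with T
  y <- curve$ratio
  n <- length(x)

  if (diff(range(y)) < .Machine$double.eps * 100)
    stop("no derivative peak: curve is flat", call. = FALSE)

  # adaptive smoothing: estimate the noise SD robustly from second
  # differences (Var = 6 sigma^2 for white noise); smooth only when the
  # signal is measurably noisy, since smoothing trades a little bias near
  # the ramp edges for a large variance reduction
  if (is.null(smooth_k)) {
    sd_hat <- stats::mad(diff(y, differences = 2)) / sqrt(6)
    smooth_k <- if (sd_hat > 1e-4 * diff(range(y))) 3L else 1L
  }
  k <- max(1L, as.integer(smooth_k))
  vtx <- k  # quadratic-vertex half-window matches the smoothing window
  if (n < 2 * k + 3)
    stop("melt curve too short for the smoothing window", call. = FALSE)

  # local linear slope over +/- k points (central difference when k = 1)
  d <- rep(NA_real_, n)
  for (i in (k + 1):(n - k)) {
    xs <- x[(i - k):(i + k)] - x[i]
    ys <- y[(i - k):(i + k)]
    d[i] <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  }
  ok <- which(!is.na(d))
  dm <- d[ok]
  if (max(dm) <= 0 || isTRUE(all.equal(max(dm), min(dm))))
    stop("no derivative peak: curve is flat or monotonically decreasing",
         call. = FALSE)
  peaks <- which(dm == max(dm))
  ambiguous <- length(peaks) > 1L
  j <- ok[peaks[1]]

  # censoring: transition still rising at the edge of the resolvable range
  if (j >= max(ok) - 1L) {
    return(structure(list(Tm_C = NA_real_, censored = TRUE,
                          bound_C = curve$temp_C[n], ambiguous = ambiguous),
                     class = "pk_tm"))
  }
  if (j <= min(ok) + 1L) {
    return(structure(list(Tm_C = NA_real_, censored = TRUE,
                          bound_C = curve$temp_C[1], ambiguous = ambiguous,
                          side = "below"),
                     class = "pk_tm"))
  }
  # quadratic vertex over the peak neighbourhood (exact 3-point
  # interpolation when vtx = 1)
  lo <- max(min(ok), j - vtx); hi <- min(max(ok), j + vtx)
  sc <- max(abs(x[lo:hi] - x[j]))   # condition the normal equations
  xs <- (x[lo:hi] - x[j]) / sc
  ds <- d[lo:hi]
  X <- cbind(1, xs, xs^2)
  cf <- tryCatch(solve(crossprod(X), crossprod(X, ds)),
                 error = function(e) NULL)
  x_peak <- if (is.null(cf) || !is.finite(cf[3]) || cf[3] >= 0) x[j] else
    x[j] + sc * max(min(-cf[2] / (2 * cf[3]), xs[length(xs)]), xs[1])
  Tm <- if (axis == "reciprocal") -1 / x_peak - 273.15 else x_peak
  structure(list(Tm_C = Tm, censored = FALSE,
                 bound_C = NA_real_, ambiguous = ambiguous),
            class = "pk_tm")
}

#' @export
format.pk_tm <- function(x, ...) {
  if (x$censored) sprintf("> %g C", x$bound_C) else sprintf("%.2f C", x$Tm_C)
}

#' @export
print.pk_tm <- function(x, ...) {
  cat("<apparent Tm>", format(x),
      if (x$ambiguous) "(ambiguous: multiple equal derivative peaks)" else "",
      "\n")
  invisible(x)
}

#' Read a melt-curve CSV
#'
#' Columns \code{temp_c} plus either \code{ratio} or the raw channels
#' \code{f330, f350} (ratio computed as f350/f330).
#' @param path CSV path.
#' @return \code{pk_melt_curve}.
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!("temp_c" %in% names(df)))
    stop("melt CSV must have a temp_c column", call. = FALSE)
  ratio <- if (!is.null(df$ratio)) df$ratio
           else if (!is.null(df$f330) && !is.null(df$f350)) df$f350 / df$f330
           else stop("melt CSV needs ratio or f330/f350 columns", call. = FALSE)
  melt_curve(df$temp_c, ratio)
}
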