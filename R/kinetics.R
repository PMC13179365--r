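# Inverse Michaelis-Menten kinetics for interfacial PET hydrolysis.
#
# With an excess of solid substrate surface, the enzyme concentration (not
# the substrate) is varied and the rate saturates in [E]:
#   v = invVmax * [E] / (invKM + [E])
# invKM reflects the affinity of the enzyme for the PET surface and invVmax
# the rate at surface saturation. Released terephthalic acid (TPA)
# equivalents are quantified by A240 against a linear standard curve.

#' Fit a TPA standard curve
#'
#' Ordinary least-squares line through A240 versus TPA concentration
#' calibration points (typically a 0-1 mM dilution series).
#'
#' @param conc_mM TPA concentrations in mM (>= 3 distinct values).
#' @param a240 absorbances at 240 nm.
#' @return object of class \code{pk_standard_curve}: slope (A240 per mM),
#'   intercept, their standard errors, and \code{sigma}.
#' @export
fit_standard_curve <- function(conc_mM, a240) {
  stopifnot(length(conc_mM) == length(a240))
  if (length(conc_mM) < 3L)
    stop("a standard curve needs at least 3 calibration points", call. = FALSE)
  if (stats::var(conc_mM) == 0)
    stop("calibration concentrations have zero variance", call. = FALSE)
  fit <- stats::lm(a240 ~ conc_mM)
  cf <- stats::coef(summary(fit))
  slope <- cf["conc_mM", "Estimate"]
  if (slope <= 0)
    stop("fitted standard-curve slope must be > 0", call. = FALSE)
  structure(list(slope = slope, intercept = cf["(Intercept)", "Estimate"],
                 slope_se = cf["conc_mM", "Std. Error"],
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 sigma = summary(fit)$sigma, n = length(conc_mM)),
            class = "pk_standard_curve")
}

#' Convert A240 readings to TPA concentration
#'
#' Inverts the standard curve: \code{(a240 - intercept) / slope}. Predicted
#' negative concentrations are returned as-is but flagged with a warning so
#' that blank drift is visible rather than silently clipped.
#'
#' @param a240 absorbance readings (vectorised).
#' @param curve \code{pk_standard_curve}.
#' @return TPA concentration in mM.
#' @export
quantify_tpa <- function(a240, curve) {
  stopifnot(inherits(curve, "pk_standard_curve"))
  conc <- (a240 - curve$intercept) / curve$slope
  if (any(conc < 0))
    warning(sprintf("%d reading(s) below the calibration intercept give negative concentration",
                    sum(conc < 0)))
  conc
}

#' Inverse Michaelis-Menten rate law
#'
#' @param enzyme_uM enzyme concentration in uM (vectorised, >= 0).
#' @param inv_Vmax saturation rate, nmol g^-1 s^-1.
#' @param inv_KM half-saturation enzyme concentration, uM.
#' @return rate in nmol g^-1 s^-1; \code{v(0) = 0} and \code{v(inv_KM) =
#'   inv_Vmax / 2}.
#' @export
inverse_mm_rate <- function(enzyme_uM, inv_Vmax, inv_KM) {
  .check_number(inv_Vmax, "inv_Vmax", positive = TRUE)
  .check_number(inv_KM, "inv_KM", positive = TRUE)
  if (any(enzyme_uM < 0)) stop("enzyme concentrations must be >= 0", call. = FALSE)
  inv_Vmax * enzyme_uM / (inv_KM + enzyme_uM)
}

#' Fit the inverse Michaelis-Menten model
#'
#' Nonlinear least squares with initial values from the double-reciprocal
#' (1/v vs 1/[E]) linearisation of the nonzero points. Replicates are fitted
#' jointly (pooled residuals). With the default \code{weighting =
#' "relative"} the fit minimises relative residuals \code{(v_model - v) /
#' v_model}, the correct weighting when measurement error scales with the
#' signal (constant CV), which is what TPA-release assays show; zero-enzyme
#' anchors then carry no residual (the model passes through the origin
#' structurally). \code{weighting = "none"} gives the plain unweighted fit.
#' Standard errors come from the Jacobian-based covariance.
#'
#' @param enzyme_uM enzyme concentrations in uM.
#' @param rate rates in nmol g^-1 s^-1.
#' @param replicate optional replicate labels (kept for bookkeeping; the fit
#'   pools residuals and is invariant under replicate ordering).
#' @param include_zero keep measurements at \code{[E] = 0}? Default TRUE.
#' @param weighting \code{"relative"} (default) or \code{"none"}.
#' @return object of class \code{pk_invmm}: \code{inv_Vmax}, \code{inv_KM},
#'   \code{se} (named), \code{rss}, \code{df}, \code{fitted_fn}.
#' @export
fit_inverse_mm <- function(enzyme_uM, rate, replicate = NULL,
                           include_zero = TRUE,
                           weighting = c("relative", "none")) {
  stopifnot(length(enzyme_uM) == length(rate))
  weighting <- match.arg(weighting)
  if (!include_zero) {
    keep <- enzyme_uM > 0
    enzyme_uM <- enzyme_uM[keep]; rate <- rate[keep]
    if (!is.null(replicate)) replicate <- replicate[keep]
  }
  if (length(unique(enzyme_uM[enzyme_uM > 0])) < 4L)
    stop("need at least 4 distinct nonzero enzyme concentrations", call. = FALSE)
  if (all(rate == 0)) stop("all rates are zero; nothing to fit", call. = FALSE)

  # double-reciprocal start values: 1/v = (invKM/invVmax) (1/E) + 1/invVmax
  pos <- enzyme_uM > 0 & rate > 0
  if (sum(pos) < 2L) stop("too few positive (enzyme, rate) pairs", call. = FALSE)
  dr <- stats::lm(I(1 / rate[pos]) ~ I(1 / enzyme_uM[pos]))
  b0 <- stats::coef(dr)[[1]]; b1 <- stats::coef(dr)[[2]]
  V0 <- if (b0 > 0) 1 / b0 else max(rate)
  K0 <- if (b0 > 0 && b1 > 0) b1 / b0 else stats::median(enzyme_uM[pos])
  V0 <- max(V0, 1e-12); K0 <- max(K0, 1e-12)

  # under relative weighting the zero-enzyme anchor contributes no residual
  E_fit <- if (weighting == "relative") enzyme_uM[enzyme_uM > 0] else enzyme_uM
  v_fit <- if (weighting == "relative") rate[enzyme_uM > 0] else rate

  p0 <- log(c(inv_Vmax = V0, inv_KM = K0))
  resid_fn <- function(p) {
    q <- exp(p)
    vm <- q[1] * E_fit / (q[2] + E_fit)
    if (weighting == "relative") (vm - v_fit) / vm else vm - v_fit
  }
  jac_fn <- function(p) {
    q <- exp(p)
    vm <- q[1] * E_fit / (q[2] + E_fit)
    dV <- E_fit / (q[2] + E_fit)
    dK <- -q[1] * E_fit / (q[2] + E_fit)^2
    if (weighting == "relative") {
      # resid = 1 - v/vm => d resid/d theta = (v/vm^2) dvm/dtheta
      cbind((v_fit / vm^2) * dV * q[1], (v_fit / vm^2) * dK * q[2])
    } else {
      cbind(q[1] * dV, q[2] * dK)
    }
  }
  fit <- lm_least_squares(p0, resid_fn, jac_fn)
  if (!fit$converged)
    warning(sprintf("inverse-MM fit did not converge (rss = %g)", fit$rss))
  q <- exp(fit$par)
  se <- if (all(is.finite(fit$se))) q * fit$se else rep(NA_real_, 2)
  structure(list(inv_Vmax = q[[1]], inv_KM = q[[2]],
                 se = setNames(se, c("inv_Vmax", "inv_KM")),
                 rss = fit$rss, df = length(v_fit) - 2L,
                 n = length(rate), weighting = weighting,
                 fitted_fn = function(E) inverse_mm_rate(E, q[[1]], q[[2]])),
            class = "pk_invmm")
}

#' @export
print.pk_invmm <- function(x, ...) {
  cat(sprintf("<inverse-MM fit> invVmax = %.4g +/- %.2g nmol g^-1 s^-1, invKM = %.4g +/- %.2g uM (n = %d)\n",
              x$inv_Vmax, x$se[["inv_Vmax"]], x$inv_KM, x$se[["inv_KM"]], x$n))
  invisible(x)
}

#' Read a kinetics dataset CSV
#'
#' Columns \code{enzyme_um, rate_nmol_g_s, replicate}.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_kinetics_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("enzyme_um", "rate_nmol_g_s")
  if (!all(need %in% names(df)))
    stop("kinetics CSV must have columns enzyme_um, rate_nmol_g_s", call. = FALSE)
  if (is.null(df$replicate)) df$replicate <- 1L
  df
}
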