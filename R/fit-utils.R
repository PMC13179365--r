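# Small Levenberg-Marquardt core shared by the nonlinear fits.
#
# base::nls() refuses artificial zero-residual data, which several of the
# round-trip contracts in this package rely on (noiseless synthetic spectra
# must be recovered to ~1e-6 relative error), so the damped Gauss-Newton
# loop is implemented here with an optional analytic Jacobian.

#' Levenberg-Marquardt least squares
#'
#' Minimises \code{sum(resid_fn(par)^2)} over \code{par}. Residuals carry any
#' weighting already; the caller is responsible for scaling.
#'
#' @param par numeric start values (named).
#' @param resid_fn function(par) -> numeric residual vector.
#' @param jac_fn optional function(par) -> Jacobian matrix (d resid / d par);
#'   a forward-difference Jacobian is used when omitted.
#' @param lower optional lower bounds (box constraint by clipping).
#' @param control list: \code{maxit}, \code{ftol} (relative decrease of the
#'   sum of squares), \code{ptol} (relative parameter step).
#' @return list with \code{par}, \code{residuals}, \code{rss}, \code{niter},
#'   \code{converged}, \code{cov} (parameter covariance from the Jacobian,
#'   \code{NULL} when the normal matrix is singular) and \code{se}.
#' @keywords internal
lm_least_squares <- function(par, resid_fn, jac_fn = NULL,
                             lower = rep(-Inf, length(par)),
                             control = list()) {
  ctrl <- modifyList(list(maxit = 200L, ftol = 1e-14, ptol = 1e-12), control)
  nm <- names(par)
  clip <- function(p) pmax(p, lower)
  par <- clip(par)

  num_jac <- function(p) {
    r0 <- resid_fn(p)
    J <- matrix(0, length(r0), length(p))
    for (j in seq_along(p)) {
      h <- max(abs(p[j]), 1e-8) * 1e-7
      pj <- p; pj[j] <- pj[j] + h
      J[, j] <- (resid_fn(pj) - r0) / h
    }
    J
  }
  jac <- if (is.null(jac_fn)) num_jac else jac_fn

  r <- resid_fn(par)
  rss <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < ctrl$maxit) {
    iter <- iter + 1L
    J <- jac(par)
    g <- crossprod(J, r)          # gradient/2
    A <- crossprod(J)
    step_ok <- FALSE
    for (k in 1:30) {
      Ad <- A + lambda * diag(diag(A) + 1e-30, nrow(A))
      delta <- tryCatch(solve(Ad, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        par_new <- clip(par + as.numeric(delta))
        r_new <- resid_fn(par_new)
        rss_new <- sum(r_new^2)
        if (is.finite(rss_new) && rss_new <= rss) {
          rel_f <- (rss - rss_new) / max(rss, .Machine$double.eps)
          rel_p <- max(abs(par_new - par) / pmax(abs(par), 1e-30))
          par <- par_new; r <- r_new; rss <- rss_new
          lambda <- max(lambda / 10, 1e-12)
          step_ok <- TRUE
          if (rel_f < ctrl$ftol || rel_p < ctrl$ptol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_ok || converged) {
      if (!step_ok) converged <- TRUE  # stuck in a (local) minimum
      break
    }
  }
  names(par) <- nm

  J <- jac(par)
  p <- length(par); n <- length(r)
  cov <- NULL; se <- rep(NA_real_, p)
  if (n > p) {
    sigma2 <- rss / (n - p)
    A <- crossprod(J)
    covu <- tryCatch(solve(A), error = function(e) NULL)
    if (!is.null(covu)) {
      cov <- sigma2 * covu
      se <- sqrt(pmax(diag(cov), 0))
    }
  }
  names(se) <- nm
  list(par = par, residuals = r, rss = rss, niter = iter,
       converged = converged, cov = cov, se = se)
}

#' Centered rolling linear smoother
#'
#' For each point, fits a straight line to all points whose abscissa lies
#' within \code{half_window} of it and returns the fitted value and slope.
#' Used for rate extraction from noisy thickness / mass time series.
#'
#' @param x abscissa (e.g. time in hours), ascending.
#' @param y ordinate.
#' @param half_window half-width of the window in units of \code{x}.
#' @return list with \code{value} and \code{slope}, both length(x).
#' @keywords internal
rolling_linear <- function(x, y, half_window) {
  stopifnot(length(x) == length(y), half_window > 0)
  n <- length(x)
  value <- numeric(n)
  slope <- numeric(n)
  for (i in seq_len(n)) {
    sel <- abs(x - x[i]) <= half_window
    if (sum(sel) < 2L) {
      value[i] <- y[i]
      slope[i] <- NA_real_
    } else {
      xi <- x[sel] - x[i]
      yi <- y[sel]
      sxx <- sum((xi - mean(xi))^2)
      b <- sum((xi - mean(xi)) * (yi - mean(yi))) / sxx
      a <- mean(yi) - b * mean(xi)
      value[i] <- a
      slope[i] <- b
    }
  }
  list(value = value, slope = slope)
}

# shared input checker
.check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
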