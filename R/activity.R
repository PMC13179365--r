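# Gravimetric activity accounting: weight loss, fold-activity versus the
# wild type under matched conditions, and residual-activity time courses.

#' Weight-loss percentage
#'
#' \code{100 * (initial - final) / initial}.
#'
#' @param initial_mg initial film mass, mg (> 0), vectorised.
#' @param final_mg final film mass, mg (0 <= final <= initial).
#' @return percent weight loss in [0, 100].
#' @export
weight_loss <- function(initial_mg, final_mg) {
  if (any(!is.finite(initial_mg)) || any(initial_mg <= 0))
    stop("initial mass must be finite and > 0", call. = FALSE)
  if (any(!is.finite(final_mg)) || any(final_mg < 0))
    stop("final mass must be finite and >= 0", call. = FALSE)
  if (any(final_mg > initial_mg))
    stop("final mass exceeds initial mass", call. = FALSE)
  100 * (initial_mg - final_mg) / initial_mg
}

#' Fold-activity relative to the wild type
#'
#' Ratio of weight-loss percentages measured under matched buffer,
#' temperature and duration. This is a conversion-ratio proxy for a rate
#' ratio: near-complete conversion compresses the ratio, so fold-activities
#' where either side approaches 100% weight loss understate true rate
#' differences.
#'
#' @param variant_wl variant weight loss, percent.
#' @param wt_wl wild-type weight loss, percent (> 0); a zero reference is
#'   rejected (only a lower bound would be defined).
#' @return fold activity (unitless); satisfies
#'   \code{fold_activity(x, y) * fold_activity(y, x) == 1}.
#' @export
fold_activity <- function(variant_wl, wt_wl) {
  if (any(!is.finite(variant_wl)) || any(variant_wl < 0))
    stop("variant weight loss must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(wt_wl)) || any(wt_wl <= 0))
    stop("reference weight loss is zero: fold-activity undefined (lower bound only)",
         call. = FALSE)
  variant_wl / wt_wl
}

#' Residual-activity time course and half-life
#'
#' Activities after incubation are expressed relative to the unincubated
#' reference; the half-life is the first crossing of 50% by log-linear
#' interpolation between the bracketing samples (exact for exponential
#' decay). If the series never crosses, the half-life is censored at the
#' last time point ("> t_max").
#'
#' @param time_h incubation times, hours, ascending, first may be 0.
#' @param activity activities at those times (same units as
#'   \code{reference}).
#' @param reference activity at time zero (> 0); defaults to
#'   \code{activity[1]} when \code{time_h[1] == 0}.
#' @return object of class \code{pk_residual}: data.frame \code{series}
#'   (time_h, percent) plus \code{half_life_h} (NA when censored),
#'   \code{censored}, \code{bound_h}.
#' @export
residual_activity <- function(time_h, activity, reference = NULL) {
  stopifnot(length(time_h) == length(activity), length(time_h) >= 1L)
  o <- order(time_h)
  time_h <- time_h[o]; activity <- activity[o]
  if (is.null(reference)) {
    if (time_h[1] != 0)
      stop("supply 'reference' when the series has no t = 0 sample",
           call. = FALSE)
    reference <- activity[1]
  }
  if (!is.finite(reference) || reference <= 0)
    stop("reference activity must be > 0", call. = FALSE)
  pct <- 100 * activity / reference

  half <- NA_real_; censored <- FALSE
  below <- which(pct <= 50)
  if (length(below) == 0L) {
    censored <- TRUE
  } else {
    i <- below[1]
    if (pct[i] == 50 || i == 1L) {
      half <- time_h[i]
    } else {
      # log-linear interpolation (exact under exponential decay)
      p1 <- pct[i - 1]; p2 <- pct[i]
      t1 <- time_h[i - 1]; t2 <- time_h[i]
      if (p2 <= 0) p2 <- .Machine$double.xmin
      half <- t1 + (t2 - t1) * (log(p1) - log(50)) / (log(p1) - log(p2))
    }
  }
  structure(list(series = data.frame(time_h = time_h, percent = pct),
                 half_life_h = half, censored = censored,
                 bound_h = if (censored) max(time_h) else NA_real_),
            class = "pk_residual")
}

#' @export
print.pk_residual <- function(x, ...) {
  hl <- if (x$censored) sprintf("> %g h", x$bound_h)
        else sprintf("%.2f h", x$half_life_h)
  cat(sprintf("<residual activity> %d time points, half-life %s\n",
              nrow(x$series), hl))
  invisible(x)
}

#' Summarise a weight-loss table against a reference enzyme
#'
#' Records are grouped by condition (buffer molarity, temperature,
#' duration); within each condition the mean weight loss per variant is
#' normalised to the mean weight loss of the reference.
#'
#' @param records data.frame with columns \code{variant, buffer_m, temp_c,
#'   duration_h, initial_mg, final_mg} (a \code{replicate} column is
#'   optional).
#' @param reference reference variant label (e.g. \code{"PHL7"}).
#' @return data.frame \code{variant, buffer_m, temp_c, duration_h,
#'   weight_loss_pct, fold_vs_ref}.
#' @export
activity_summary <- function(records, reference) {
  need <- c("variant", "buffer_m", "temp_c", "duration_h",
            "initial_mg", "final_mg")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  records$wl <- weight_loss(records$initial_mg, records$final_mg)
  key <- interaction(records$buffer_m, records$temp_c, records$duration_h,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(d) {
    agg <- stats::aggregate(wl ~ variant, data = d, FUN = mean)
    ref <- agg$wl[agg$variant == reference]
    if (length(ref) != 1L)
      stop(sprintf("condition %.3g M / %g C / %g h lacks reference '%s'",
                   d$buffer_m[1], d$temp_c[1], d$duration_h[1], reference),
           call. = FALSE)
    data.frame(variant = agg$variant, buffer_m = d$buffer_m[1],
               temp_c = d$temp_c[1], duration_h = d$duration_h[1],
               weight_loss_pct = agg$wl,
               fold_vs_ref = fold_activity(agg$wl, ref))
  }))
  rownames(out) <- NULL
  out
}
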