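# pH-stat titration stoichiometry.
#
# Enzymatic PET depolymerisation releases terephthalic acid (TPA), which at
# constant pH 8 is neutralised by NaOH in a 1:2 molar ratio. The cumulative
# NaOH consumption therefore reports the depolymerised PET mass:
#   mol TPA = 0.5 * mol NaOH;  g PET = mol TPA * 192.2 (repeat-unit MW).
# Ethylene glycol is not acidic and is ignored, so the conversion assumes
# TPA is the sole titrated acid.

#' Reactor configuration
#'
#' @param pet_mass_g PET charge in grams (default 50).
#' @param volume_L working volume in litres (default 0.5).
#' @param naoh_molarity titrant molarity in mol/L (default 5).
#' @param repeat_unit_mw PET repeat-unit molar mass, g/mol (192.2).
#' @param naoh_per_tpa mol NaOH per mol TPA (2).
#' @param naoh_density_g_ml titrant solution density used when consumption is
#'   recorded gravimetrically (default 1.18 g/mL for 5 M NaOH).
#' @return object of class \code{pk_reactor}.
#' @export
reactor_config <- function(pet_mass_g = 50, volume_L = 0.5, naoh_molarity = 5,
                           repeat_unit_mw = 192.2, naoh_per_tpa = 2,
                           naoh_density_g_ml = 1.18) {
  for (nm in c("pet_mass_g", "volume_L", "naoh_molarity", "repeat_unit_mw",
               "naoh_per_tpa", "naoh_density_g_ml"))
    .check_number(get(nm), nm, positive = TRUE)
  structure(list(pet_mass_g = pet_mass_g, volume_L = volume_L,
                 naoh_molarity = naoh_molarity,
                 repeat_unit_mw = repeat_unit_mw, naoh_per_tpa = naoh_per_tpa,
                 naoh_density_g_ml = naoh_density_g_ml),
            class = "pk_reactor")
}

#' Convert NaOH consumption to hydrolyzed PET mass
#'
#' \code{mass = (naoh_mol / naoh_per_tpa) * repeat_unit_mw}; linear in the
#' input.
#'
#' @param naoh_mol cumulative NaOH consumed, mol (vectorised, >= 0).
#' @param config \code{pk_reactor}.
#' @return grams of PET hydrolyzed.
#' @export
naoh_to_pet_mass <- function(naoh_mol, config = reactor_config()) {
  stopifnot(inherits(config, "pk_reactor"))
  if (any(!is.finite(naoh_mol)) || any(naoh_mol < 0))
    stop("NaOH amounts must be finite and >= 0", call. = FALSE)
  (naoh_mol / config$naoh_per_tpa) * config$repeat_unit_mw
}

#' Inverse of \code{naoh_to_pet_mass}
#' @param pet_mass_g grams of PET hydrolyzed (>= 0).
#' @param config \code{pk_reactor}.
#' @return mol NaOH required.
#' @export
pet_mass_to_naoh <- function(pet_mass_g, config = reactor_config()) {
  stopifnot(inherits(config, "pk_reactor"))
  if (any(!is.finite(pet_mass_g)) || any(pet_mass_g < 0))
    stop("PET masses must be finite and >= 0", call. = FALSE)
  pet_mass_g / config$repeat_unit_mw * config$naoh_per_tpa
}

#' Convert gravimetric titrant readings to moles
#'
#' Grams of titrant solution are converted via the solution density and
#' molarity: \code{mol = g / density / 1000 * molarity} (g -> mL -> L -> mol).
#'
#' @param naoh_g grams of NaOH solution dispensed.
#' @param config \code{pk_reactor}.
#' @return mol NaOH.
#' @export
naoh_grams_to_mol <- function(naoh_g, config = reactor_config()) {
  stopifnot(inherits(config, "pk_reactor"))
  naoh_g / config$naoh_density_g_ml / 1000 * config$naoh_molarity
}

#' Degradation profile from a titration series
#'
#' Converts cumulative NaOH consumption to percent PET degraded, a smoothed
#' volumetric production rate, and times to stated conversions. The series
#' must start at zero and be non-decreasing. Percentages above 100 are
#' reported capped at 100 with a warning; above 105 the stoichiometry is
#' considered violated and the series rejected.
#'
#' @param time_h times in hours, ascending.
#' @param naoh_mol cumulative NaOH consumed, mol (same length).
#' @param config \code{pk_reactor}.
#' @param targets_pct conversions (percent) for which crossing times are
#'   interpolated; default \code{c(50, 90)}.
#' @param smooth_half_window_h half-width of the rolling linear smoother for
#'   the rate, hours (default 0.5).
#' @return object of class \code{pk_degradation_profile}: data.frame
#'   \code{profile} (time_h, pet_g, percent, rate_g_L_h) plus
#'   \code{time_to_pct} (named, NA when not reached).
#' @export
degradation_profile <- function(time_h, naoh_mol, config = reactor_config(),
                                targets_pct = c(50, 90),
                                smooth_half_window_h = 0.5) {
  stopifnot(inherits(config, "pk_reactor"),
            length(time_h) == length(naoh_mol), length(time_h) >= 2L)
  o <- order(time_h)
  time_h <- time_h[o]; naoh_mol <- naoh_mol[o]
  if (naoh_mol[1] != 0)
    stop("titration series must start at 0 mol NaOH", call. = FALSE)
  if (any(diff(naoh_mol) < 0))
    stop("titration series must be non-decreasing", call. = FALSE)

  pet_g <- naoh_to_pet_mass(naoh_mol, config)
  percent_raw <- 100 * pet_g / config$pet_mass_g
  if (any(percent_raw > 105))
    stop(sprintf("stoichiometry violation: computed degradation reaches %.1f%% (> 105%%)",
                 max(percent_raw)), call. = FALSE)
  if (any(percent_raw > 100))
    warning(sprintf("computed degradation exceeds 100%% (max %.1f%%); reporting capped at 100",
                    max(percent_raw)))
  percent <- pmin(percent_raw, 100)

  slope <- rolling_linear(time_h, pet_g, smooth_half_window_h)$slope
  rate_g_L_h <- slope / config$volume_L

  time_to <- vapply(targets_pct, function(p) {
    idx <- which(percent_raw >= p)
    if (length(idx) == 0L) return(NA_real_)
    i <- idx[1]
    if (i == 1L) return(time_h[1])
    # monotone linear interpolation between the bracketing samples
    stats::approx(percent_raw[(i - 1):i], time_h[(i - 1):i], xout = p,
                  ties = "ordered")$y
  }, 1.0)
  names(time_to) <- paste0("t", targets_pct, "pct_h")

  structure(list(profile = data.frame(time_h = time_h, naoh_mol = naoh_mol,
                                      pet_g = pet_g, percent = percent,
                                      rate_g_L_h = rate_g_L_h),
                 time_to_pct = time_to, config = config),
            class = "pk_degradation_profile")
}

#' @export
print.pk_degradation_profile <- function(x, ...) {
  p <- x$profile
  cat(sprintf("<degradation profile> %d points, %.1f h, final %.1f%% of %.3g g PET\n",
              nrow(p), max(p$time_h), p$percent[nrow(p)], x$config$pet_mass_g))
  for (nm in names(x$time_to_pct))
    cat(sprintf("  %s = %s\n", nm,
                ifelse(is.na(x$time_to_pct[[nm]]), "not reached",
                       sprintf("%.2f h", x$time_to_pct[[nm]]))))
  invisible(x)
}

#' Read a titration CSV
#'
#' Columns \code{time_h} and either \code{naoh_mol} or \code{naoh_g}
#' (gravimetric readings, converted via the reactor config).
#'
#' @param path CSV path.
#' @param config \code{pk_reactor} used for the gravimetric conversion.
#' @return data.frame with \code{time_h, naoh_mol}.
#' @export
read_titration_csv <- function(path, config = reactor_config()) {
  df <- utils::read.csv(path)
  if (!("time_h" %in% names(df)))
    stop("titration CSV must have a time_h column", call. = FALSE)
  if (!is.null(df$naoh_mol)) {
    data.frame(time_h = df$time_h, naoh_mol = df$naoh_mol)
  } else if (!is.null(df$naoh_g)) {
    data.frame(time_h = df$time_h,
               naoh_mol = naoh_grams_to_mol(df$naoh_g, config))
  } else {
    stop("titration CSV needs a naoh_mol or naoh_g column", call. = FALSE)
  }
}
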