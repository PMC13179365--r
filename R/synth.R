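# Seeded synthetic-data generators.
#
# Every analysis input the package consumes can be generated here with the
# statistical structure the estimators assume, so each stage is testable
# end to end without instrument data. All randomness flows from one
# explicit seed per call; the caller's RNG state is restored on exit.
# Default noise magnitudes (EIS 1% multiplicative, kinetics CV 5%, melt
# ratio SD 0.002) are package choices documented in the methods vignette.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    env <- globalenv()
    old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
      get(".Random.seed", envir = env) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(seed)
  }
  force(expr)
}

runif_sphere <- function(n, radius = 1) {
  # uniform points inside a sphere
  v <- matrix(stats::rnorm(3 * n), ncol = 3L)
  v <- v / sqrt(rowSums(v^2))
  v * radius * stats::runif(n)^(1 / 3)
}

runit <- function(n = 1L) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3L)
  v / sqrt(rowSums(v^2))
}

#' Synthesize an EIS time series of a thinning film
#'
#' Film thickness follows \code{d(t) = d0 - rate * t} (floored at
#' \code{min_thickness_um}, with a warning when the floor engages); the
#' capacitance follows the parallel-plate law and each sweep is a Randles
#' spectrum with multiplicative complex Gaussian noise.
#'
#' @param rate_um_h thinning rate, um/h (>= 0).
#' @param d0_um initial thickness, um (default 225).
#' @param duration_h run length, hours (default 20).
#' @param dt_min sweep interval, minutes (default 3).
#' @param freq_range_hz sweep limits, Hz (default 1 kHz - 1 MHz).
#' @param n_freq log-spaced frequency points per sweep (default 51).
#' @param noise multiplicative noise fraction on real and imaginary parts
#'   independently (default 0.01).
#' @param R_s,R_ct circuit resistances, ohm (defaults 100 and 1e6).
#' @param geometry \code{pk_film_geometry}.
#' @param min_thickness_um floor, um (default 5).
#' @param seed integer seed (NULL = use current RNG state).
#' @return list of \code{pk_spectrum}.
#' @export
gen_eis_timeseries <- function(rate_um_h, d0_um = 225, duration_h = 20,
                               dt_min = 3, freq_range_hz = c(1e3, 1e6),
                               n_freq = 51, noise = 0.01,
                               R_s = 100, R_ct = 1e6,
                               geometry = film_geometry(),
                               min_thickness_um = 5, seed = NULL) {
  .check_number(rate_um_h, "rate_um_h", nonneg = TRUE)
  .check_number(d0_um, "d0_um", positive = TRUE)
  with_seed(seed, {
    times <- seq(0, duration_h, by = dt_min / 60)
    freqs <- exp(seq(log(freq_range_hz[1]), log(freq_range_hz[2]),
                     length.out = n_freq))
    d <- d0_um - rate_um_h * times
    if (any(d < min_thickness_um)) {
      warning("thinning rate drives thickness to the floor inside the run; flooring")
      d <- pmax(d, min_thickness_um)
    }
    lapply(seq_along(times), function(i) {
      C <- thickness_to_capacitance(d[i], geometry)
      Z <- randles_impedance(randles_params(R_s, R_ct, C), freqs)
      if (noise > 0)
        Z <- complex(real = Re(Z) * (1 + noise * stats::rnorm(n_freq)),
                     imaginary = Im(Z) * (1 + noise * stats::rnorm(n_freq)))
      impedance_spectrum(freqs, Z, time_h = times[i])
    })
  })
}

#' Synthesize an inverse-MM kinetics dataset
#'
#' Rates follow \code{v = inv_Vmax [E] / (inv_KM + [E])} with multiplicative
#' Gaussian noise of the stated coefficient of variation; zero-enzyme wells
#' produce exactly zero rate (blank wells carry no signal to scale).
#'
#' @param inv_Vmax,inv_KM generating parameters (nmol g^-1 s^-1, uM).
#' @param enzyme_uM concentration grid, uM (default an 8-point 0-0.6 uM
#'   design spanning both sides of typical inv_KM values).
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param n_rep replicates per concentration (default 2, i.e. duplicate).
#' @param seed integer seed.
#' @return data.frame \code{enzyme_um, rate_nmol_g_s, replicate}.
#' @export
gen_kinetics <- function(inv_Vmax, inv_KM,
                         enzyme_uM = c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.45, 0.6),
                         cv = 0.05, n_rep = 2, seed = NULL) {
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  with_seed(seed, {
    grid <- rep(enzyme_uM, times = n_rep)
    repl <- rep(seq_len(n_rep), each = length(enzyme_uM))
    v <- inverse_mm_rate(grid, inv_Vmax, inv_KM)
    if (cv > 0) v <- v * (1 + cv * stats::rnorm(length(v)))
    data.frame(enzyme_um = grid, rate_nmol_g_s = v, replicate = repl)
  })
}

#' Synthesize a nanoDSF melt curve
#'
#' Thin wrapper over \code{\link{simulate_melt}} with seeded noise.
#'
#' @param Tm_C midpoint, Celsius.
#' @param dH_vH_kJ van't Hoff enthalpy, kJ/mol (default 400).
#' @param baseline_folded,baseline_unfolded baselines
#'   \code{c(intercept, slope)}.
#' @param noise_sd ratio-unit noise SD (default 0.002).
#' @param temp_C ramp grid (default 20-95 C in 1 C steps).
#' @param seed integer seed.
#' @param allow_out_of_ramp permit a midpoint beyond the ramp.
#' @return \code{pk_melt_curve}.
#' @export
gen_melt <- function(Tm_C, dH_vH_kJ = 400, baseline_folded = c(0.80, 0),
                     baseline_unfolded = c(1.00, 0), noise_sd = 0.002,
                     temp_C = seq(20, 95, by = 1), seed = NULL,
                     allow_out_of_ramp = FALSE) {
  with_seed(seed,
    simulate_melt(melt_model(Tm_C, dH_vH_kJ, baseline_folded,
                             baseline_unfolded),
                  temp_C = temp_C, noise_sd = noise_sd,
                  allow_out_of_ramp = allow_out_of_ramp))
}

#' Synthesize a pH-stat titration series
#'
#' A normalised logistic conversion curve (exactly 0 at t = 0, approaching
#' \code{final_fraction}) is converted to cumulative NaOH; monotone by
#' construction. When \code{target_time_h} is given, the logistic midpoint
#' is calibrated so the curve crosses \code{target_pct} percent conversion
#' at that time.
#'
#' @param config \code{pk_reactor}.
#' @param duration_h run length, hours (default 48).
#' @param dt_h sampling interval, hours (default 0.25).
#' @param k logistic steepness, 1/h (default 0.2).
#' @param t_mid_h logistic midpoint, hours (default 12; ignored when
#'   calibrating).
#' @param final_fraction asymptotic conversion fraction (default 1).
#' @param target_pct,target_time_h optional calibration point: percent
#'   conversion crossed at the stated time.
#' @return data.frame \code{time_h, naoh_mol, pet_g, percent}.
#' @export
gen_titration <- function(config = reactor_config(), duration_h = 48,
                          dt_h = 0.25, k = 0.2, t_mid_h = 12,
                          final_fraction = 1,
                          target_pct = NULL, target_time_h = NULL) {
  stopifnot(inherits(config, "pk_reactor"))
  frac <- function(t, tm) {
    L <- function(u) 1 / (1 + exp(-k * (u - tm)))
    final_fraction * (L(t) - L(0)) / (1 - L(0))
  }
  if (!is.null(target_pct) && !is.null(target_time_h)) {
    f_target <- target_pct / 100
    if (f_target >= final_fraction)
      stop("calibration target exceeds the asymptotic conversion", call. = FALSE)
    t_mid_h <- stats::uniroot(function(tm)
      frac(target_time_h, tm) - f_target,
      interval = c(-duration_h, 2 * duration_h), tol = 1e-10)$root
  }
  time_h <- seq(0, duration_h, by = dt_h)
  f <- frac(time_h, t_mid_h)
  pet_g <- f * config$pet_mass_g
  data.frame(time_h = time_h, naoh_mol = pet_mass_to_naoh(pet_g, config),
             pet_g = pet_g, percent = 100 * f)
}

# fixed scaffold positions used by the trajectory generators (Angstrom)
.scaffold <- list(ser_og = c(0, 0, 0), oxyanion_n = c(3, 0, 0))

#' Synthesize an enzyme-substrate trajectory with set state occupancies
#'
#' Frames are drawn i.i.d. with the given occupancies; substrate carbonyl
#' coordinates are then rejection-sampled inside each state's defining
#' distance region, so every generated frame classifies back to its
#' generating label with certainty. The protein scaffold (Ser OG, oxyanion
#' N) is fixed; only the substrate moves.
#'
#' @param occupancies named numeric over
#'   \code{c("in_oxyanion", "near_active_site", "other")}; must sum to 1.
#' @param n_frames number of frames.
#' @param criteria \code{pk_criteria} defining the state regions.
#' @param seed integer seed.
#' @return list of \code{pk_frame} with attribute \code{labels} (the
#'   generating state labels).
#' @export
gen_trajectory <- function(occupancies = c(in_oxyanion = 0.3,
                                           near_active_site = 0.3,
                                           other = 0.4),
                           n_frames = 1000,
                           criteria = geometric_criteria(), seed = NULL) {
  lev <- c("in_oxyanion", "near_active_site", "other")
  stopifnot(all(names(occupancies) %in% lev), all(occupancies >= 0),
            isTRUE(all.equal(sum(occupancies), 1)))
  occ <- setNames(numeric(3), lev)
  occ[names(occupancies)] <- occupancies
  og <- .scaffold$ser_og; nn <- .scaffold$oxyanion_n
  sel <- default_selection_map()
  bond <- 1.23  # carbonyl C=O, Angstrom

  sample_state <- function(state) {
    repeat {
      if (state == "in_oxyanion") {
        oo <- nn + as.numeric(runif_sphere(1, criteria$d_oxyanion_in * 0.999))
        cc <- oo + bond * as.numeric(runit())
      } else if (state == "near_active_site") {
        cc <- og + as.numeric(runif_sphere(1, criteria$d_ser_carbonyl_max * 0.999))
        oo <- cc + bond * as.numeric(runit())
      } else {
        cc <- as.numeric(runif_sphere(1, 15))
        oo <- cc + bond * as.numeric(runit())
      }
      fr <- md_frame(resno = c(131L, 132L, 500L, 500L),
                     resname = c("SER", "MET", "MHT", "MHT"),
                     atom = c("OG", "N", "C1", "O1"),
                     x = c(og[1], nn[1], cc[1], oo[1]),
                     y = c(og[2], nn[2], cc[2], oo[2]),
                     z = c(og[3], nn[3], cc[3], oo[3]))
      if (classify_frame(fr, criteria, sel) == state) return(fr)
    }
  }
  with_seed(seed, {
    labels <- sample(lev, n_frames, replace = TRUE, prob = occ)
    frames <- lapply(labels, sample_state)
    attr(frames, "labels") <- labels
    frames
  })
}

#' Synthesize a salt-bridge trajectory with set contact probability
#'
#' Each frame independently forms the contact (minimum side-chain N-O
#' distance drawn below the cutoff) with probability \code{p_contact},
#' otherwise all N-O distances are placed above it.
#'
#' @param p_contact contact probability in [0, 1].
#' @param n_frames number of frames.
#' @param basic_resno,acidic_resno residue numbers (default 148 Lys /
#'   233 Asp).
#' @param cutoff contact cutoff, Angstrom (default 4.0).
#' @param seed integer seed.
#' @return list of \code{pk_frame} with attribute \code{contacts}
#'   (logical generating labels).
#' @export
gen_salt_bridge_trajectory <- function(p_contact, n_frames,
                                       basic_resno = 148, acidic_resno = 233,
                                       cutoff = 4.0, seed = NULL) {
  stopifnot(p_contact >= 0, p_contact <= 1)
  with_seed(seed, {
    contacts <- stats::runif(n_frames) < p_contact
    frames <- lapply(contacts, function(hit) {
      nz <- c(0, 0, 0)
      d1 <- if (hit) stats::runif(1, 2.6, cutoff) else stats::runif(1, cutoff + 1, cutoff + 6)
      od1 <- d1 * as.numeric(runit())
      repeat {
        od2 <- od1 + 2.2 * as.numeric(runit())
        d2 <- sqrt(sum(od2^2))
        if (hit || d2 > cutoff) break
      }
      md_frame(resno = c(basic_resno, acidic_resno, acidic_resno),
               resname = c("LYS", "ASP", "ASP"),
               atom = c("NZ", "OD1", "OD2"),
               x = c(nz[1], od1[1], od2[1]),
               y = c(nz[2], od1[2], od2[2]),
               z = c(nz[3], od1[3], od2[3]))
    })
    attr(frames, "contacts") <- contacts
    frames
  })
}

#' Synthesize frames of uniform (ideal-gas) water around a site
#'
#' Waters are placed uniformly at random in a periodic box with the
#' reference site at the box center; the resulting radial distribution
#' function is flat at 1 beyond contact.
#'
#' @param n_water waters per frame.
#' @param box length-3 box, Angstrom (default 40 cube).
#' @param n_frames number of frames (default 3).
#' @param seed integer seed.
#' @return list of \code{pk_frame} (reference atom: residue 1, atom "REF").
#' @export
gen_water_frames <- function(n_water = 3000, box = c(40, 40, 40),
                             n_frames = 3, seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      W <- cbind(stats::runif(n_water, 0, box[1]),
                 stats::runif(n_water, 0, box[2]),
                 stats::runif(n_water, 0, box[3]))
      md_frame(resno = c(1L, seq_len(n_water) + 1L),
               resname = c("REF", rep("HOH", n_water)),
               atom = c("REF", rep("O", n_water)),
               x = c(box[1] / 2, W[, 1]),
               y = c(box[2] / 2, W[, 2]),
               z = c(box[3] / 2, W[, 3]),
               box = box)
    })
  })
}

#' Perturb a structure by a rigid motion plus coordinate jitter
#'
#' Applies a uniformly random proper rotation and a random translation,
#' then adds isotropic Gaussian jitter per coordinate. The expected RMSD
#' against the original (after optimal superposition, for large n) is
#' approximately \code{jitter_sd * sqrt(3)}; supply \code{target_rmsd}
#' instead to set the jitter accordingly.
#'
#' @param frame \code{pk_frame} to perturb.
#' @param jitter_sd per-coordinate Gaussian SD, Angstrom.
#' @param target_rmsd alternative to \code{jitter_sd}:
#'   \code{jitter_sd = target_rmsd / sqrt(3)}.
#' @param rigid apply the random rotation + translation? Default TRUE.
#' @param max_translation translation magnitude bound, Angstrom (default 10).
#' @param seed integer seed.
#' @return perturbed \code{pk_frame} with attribute \code{expected_rmsd}.
#' @export
gen_perturbed_structure <- function(frame, jitter_sd = 0, target_rmsd = NULL,
                                    rigid = TRUE, max_translation = 10,
                                    seed = NULL) {
  if (!is.null(target_rmsd)) jitter_sd <- target_rmsd / sqrt(3)
  with_seed(seed, {
    X <- as.matrix(frame[, c("x", "y", "z")])
    if (rigid) {
      # uniform random rotation via QR of a Gaussian matrix, det fixed to +1
      M <- matrix(stats::rnorm(9), 3, 3)
      qr_ <- qr(M)
      R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
      if (det(R) < 0) R[, 1] <- -R[, 1]
      tr <- stats::runif(3, -max_translation, max_translation)
      X <- sweep(X %*% t(R), 2, tr, "+")
    }
    if (jitter_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, jitter_sd), ncol = 3L)
    out <- md_frame(frame$resno, frame$resname, frame$atom,
                    X[, 1], X[, 2], X[, 3], box = attr(frame, "box"))
    attr(out, "expected_rmsd") <- jitter_sd * sqrt(3)
    out
  })
}
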