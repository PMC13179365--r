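# End-to-end headline quantities, recomputed from scratch.
#
# Each entry runs a full generate -> analyse round trip (or exact
# arithmetic on packaged inputs) and reports the measured value with the
# problem size used. Reference conditions: R4M6 inverse-MM parameters
# (invVmax 139 nmol g^-1 s^-1, invKM 0.145 uM), R4M6 film degradation rate
# 21.0 um/h at 70 C / 1 M buffer, wild-type apparent Tm 79.1 C, the R2M2
# salt-bridge contact fraction 45%, a 225 um film of 44.7 mm^2 at
# relative permittivity 3.3, and the R2M2 24-mutation set shifting the
# wild-type net charge of -6 at pH 8.

#' Recompute the package's headline acceptance quantities
#'
#' @param seed integer seed driving every stochastic step.
#' @return named list; each element is \code{list(value =, n =)}.
#' @export
acceptance_report <- function(seed) {
  seed <- as.integer(seed)
  out <- list()

  # t1/t2: inverse-MM parameter recovery on seeded duplicate datasets
  kin <- gen_kinetics(inv_Vmax = 139, inv_KM = 0.145, cv = 0.05, n_rep = 2,
                      seed = seed)
  fit <- fit_inverse_mm(kin$enzyme_um, kin$rate_nmol_g_s, kin$replicate)
  out$t1 <- list(value = fit$inv_KM, n = nrow(kin))
  out$t2 <- list(value = fit$inv_Vmax, n = nrow(kin))

  # t4: R2M2 net charge at pH 8 from the packaged mutation table
  tab <- read_variant_table(system.file("extdata", "phl7_variants.csv",
                                        package = "petkit"))
  r2m2 <- tab[["R2M2"]]
  out$t4 <- list(value = -6 + net_charge_delta(r2m2),
                 n = length(r2m2$mutations))

  # t5: full EIS pipeline on a film thinning at 21.0 um/h; the film is
  # fully degraded before the 20 h run ends (floored, flagged by the
  # generator), which does not touch the 3-8 h rate window
  spectra <- suppressWarnings(
    gen_eis_timeseries(rate_um_h = 21.0, seed = seed + 1L))
  series <- fit_eis_series(spectra)
  rate <- degradation_rate(series, window = c(3, 8))
  out$t5 <- list(value = rate$rate_um_h, n = length(spectra))

  # t6: apparent Tm of a noiseless two-state curve at the wild-type midpoint
  curve <- simulate_melt(melt_model(Tm_C = 79.1), temp_C = seq(20, 95, 1))
  out$t6 <- list(value = extract_tm(curve)$Tm_C, n = length(curve$temp_C))

  # t7: salt-bridge occupancy (percent) on a 2000-frame synthetic trajectory
  traj <- gen_salt_bridge_trajectory(p_contact = 0.45, n_frames = 2000,
                                     seed = seed + 2L)
  occ <- salt_bridge_occupancy(traj, basic_resno = 148, acidic_resno = 233,
                               cutoff = 4.0)
  out$t7 <- list(value = 100 * as.numeric(occ), n = length(traj))

  # t8: parallel-plate round trip through a noiseless Randles fit
  geom <- film_geometry()
  C0 <- thickness_to_capacitance(225, geom)
  freqs <- exp(seq(log(1e3), log(1e6), length.out = 51))
  Z <- randles_impedance(randles_params(100, 1e6, C0), freqs)
  fit8 <- fit_randles(impedance_spectrum(freqs, Z))
  out$t8 <- list(value = capacitance_to_thickness(fit8$C_film, geom),
                 n = length(freqs))

  out
}
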