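# petkit

Quantitative analytics for PET hydrolase engineering.

Enzymatic recycling of poly(ethylene terephthalate) (PET) hinges on
engineered hydrolases that stay folded and fast at ~65–70 °C in low-salt
buffers. Campaigns that engineer such enzymes lean on a recurring set of
bespoke quantitative procedures, and this package implements them as
tested, reusable R functions for protein engineers and enzymology labs:

* **EIS film degradation** — fit frequency-swept complex impedance spectra
  of a degrading PET film with a simplified Randles equivalent circuit
  `Z(ω) = R_s + R_ct / (1 + iω·R_ct·C)`, invert the fitted capacitance to
  thickness via the parallel-plate law `d = ε₀ε_r A / C`, and report the
  mean thinning rate (µm/h) over a time window.
* **Inverse Michaelis–Menten kinetics** — fit
  `v = ^inv^V_max·[E] / (^inv^K_M + [E])` to rate-vs-enzyme data from
  interfacial catalysis, with relative-residual weighting matched to
  constant-CV measurement error and Jacobian-based standard errors.
* **pH-stat titration stoichiometry** — convert cumulative NaOH
  consumption to depolymerised PET mass (`0.5 × mol NaOH × 192.2 g/mol`),
  percent conversion, volumetric rates, and times to target conversion.
* **nanoDSF melting points** — simulate two-state van't Hoff F350/F330
  melt curves on a 20–95 °C ramp and extract apparent Tm by
  first-derivative peak analysis, with censored reporting ("> 95 °C") at
  the detection limit.
* **Variant accounting** — parse mutation sets (`L93F` notation), apply
  them to sequences, and compute formal net-charge deltas at pH 8
  (Asp/Glu −1, Lys/Arg +1, His 0).
* **Trajectory geometry** — classify enzyme–substrate frames into
  catalytic sub-states (in-oxyanion: N–O < 5 Å; near-active-site:
  OG–C < 5.5 Å with N–O in [5, 7.5) Å), salt-bridge occupancies, H-bond
  geometry with out-of-plane angles, φ/ψ dihedrals, water radial
  distribution functions, and Kabsch superposition/RMSD, reading
  multi-model PDB or CSV trajectories.
* **Seeded synthetic generators** for every one of those inputs, so the
  full pipeline is testable end to end without instrument data.

## Worked example

```r
library(petkit)

# --- EIS: film thinning at 21 um/h, 1% noise, full pipeline back ---
spectra <- gen_eis_timeseries(rate_um_h = 21, seed = 42)
series  <- fit_eis_series(spectra)           # 401 Randles fits -> thickness
degradation_rate(series, window = c(3, 8))
#> <degradation rate> 21.003 um/h (mean over 3-8 h, 101 points)

# --- inverse Michaelis-Menten on seeded duplicate data ---
kin <- gen_kinetics(inv_Vmax = 139, inv_KM = 0.145, cv = 0.05, seed = 42)
fit_inverse_mm(kin$enzyme_um, kin$rate_nmol_g_s, kin$replicate)
#> <inverse-MM fit> invVmax = 142 +/- 4.7 nmol g^-1 s^-1, invKM = 0.1461 +/- 0.01 uM (n = 16)

# --- nanoDSF: noiseless two-state curve, derivative-peak Tm ---
extract_tm(simulate_melt(melt_model(Tm_C = 79.1)))
#> <apparent Tm> 79.10 C

# --- variant charge accounting from the packaged table ---
tab <- read_variant_table(system.file("extdata", "phl7_variants.csv",
                                      package = "petkit"))
net_charge_delta(tab$R2M2)   # 24 mutations
#> [1] 2                      # i.e. a net charge of -6 shifts to -4 at pH 8

# --- salt-bridge occupancy on a 2000-frame synthetic trajectory ---
traj <- gen_salt_bridge_trajectory(p_contact = 0.45, n_frames = 2000,
                                   seed = 42)
salt_bridge_occupancy(traj, basic_resno = 148, acidic_resno = 233,
                      cutoff = 4.0)
#> [1] 0.46
```

The degradation rate (21.0 µm/h) is the generator's thinning rate
recovered through 401 independent circuit fits and the parallel-plate
inversion; the kinetic parameters land within their standard errors of
the generating values (139, 0.145); the melting point is the van't Hoff
midpoint recovered by the derivative-peak estimator; the charge delta +2
is the sum of formal side-chain charge changes over the 24 mutations; and
the occupancy is the fraction of frames with a sub-4 Å minimum N–O
contact.

## Command line

An executable wrapper ships in `inst/cli/petkit`:

```sh
petkit simulate --what eis --rate 21 --seed 1 --out data/
petkit eis --spectra data/spectra.csv --area-mm2 44.7 --eps-r 3.3 --window 3 8
petkit kinetics --data kinetics.csv --out fit.json
petkit melt --data curve.csv
petkit reactor --data titration.csv --pet-g 50 --volume-l 0.5
petkit mdgeom --states --traj traj.csv
petkit variants --table variants.csv --name R2M2 --wt-charge -6
petkit demo --seed 1 --out demo.json
```

Exit codes: 0 success, 2 usage error, 3 data error, 4 convergence failure.

## Documentation

See `vignettes/petkit-methods.Rmd` for the models, default parameters,
what the synthetic generators do and do not emulate, numerical choices,
and known limitations.
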