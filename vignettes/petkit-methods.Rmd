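---
title: "Models and methods behind petkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind petkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkit)
```

petkit collects the quantitative procedures that accompany a PET-hydrolase
engineering campaign: impedance-based film degradation rates, inverse
Michaelis-Menten kinetics, pH-stat titration stoichiometry, nanoDSF melting
points, variant charge accounting, and geometric classification of
enzyme-substrate simulation frames. This vignette records the models, the
parameters that matter, and the design choices made where the underlying
protocols leave the analysis open.

## Impedance spectroscopy of a degrading film (`eis`)

A PET film separating two electrolyte chambers acts as the dielectric of a
capacitor. The spectrum is modelled by a simplified Randles equivalent
circuit — solution resistance $R_s$ in series with the parallel combination
of a charge-transfer resistance $R_{ct}$ and the film capacitance $C$:

$$Z(\omega) = R_s + \frac{R_{ct}}{1 + i\,\omega R_{ct} C}, \qquad
  \omega = 2\pi f.$$

The topology is fixed: no Warburg element, because a single derived
capacitance is all the thickness conversion needs. The imaginary part is
non-positive for all positive parameters (a property test enforces this).

**Fitting.** `fit_randles()` minimises the stacked real and imaginary
residuals weighted by $1/|Z|$. The weighting matters: $|Z|$ spans several
decades across a 1 kHz–1 MHz sweep and an unweighted fit is dominated by
the low-frequency points. Parameters are optimised on the log scale with a
Levenberg–Marquardt loop and an analytic Jacobian; `nls()` is not used
because the test contracts require exact recovery on noiseless synthetic
spectra, which `nls()` refuses ("zero-residual data"). Initial values need
no user input: $R_s$ from the highest-frequency real part, $R_s + R_{ct}$
from the lowest-frequency magnitude, and $C$ from the frequency of the
imaginary-part extremum, where $\omega = 1/(R_{ct} C)$. Whether the
original instrument software fit real/imaginary parts or modulus/phase is
not documented; the chosen contract is stated here, not asserted as the
original.

**Thickness and rate.** The parallel-plate law inverts capacitance to
thickness, $d = \varepsilon_0 \varepsilon_r A / C$, with
$\varepsilon_r = 3.3$ and $A = 44.7\,\mathrm{mm}^2$ by default. The
effective dielectric aperture of a given cell may be smaller than the film
(an O-ring, for instance), so the area is configurable. Per-point thinning
rates are central differences of a locally smoothed thickness series
(centred rolling linear fit, 1 h window — 3-minute sampling is noisy and
"rate" is otherwise undefined); the reported rate is the mean over a
window, by default 3–8 h. On a linear series the rate is exact regardless
of smoothing, and it is invariant under time shifts and thickness offsets.

## Inverse Michaelis–Menten kinetics (`kinetics`)

For interfacial catalysis on a solid substrate in excess, the enzyme — not
the substrate — is titrated, and the rate saturates in enzyme
concentration:

$$v = \frac{{}^{inv}V_{max}\,[E]}{{}^{inv}K_M + [E]}.$$

${}^{inv}K_M$ reflects affinity for the PET surface; ${}^{inv}V_{max}$ the
rate at surface saturation. `fit_inverse_mm()` uses nonlinear least
squares with start values from the double-reciprocal linearisation.

**Weighting.** The default minimises *relative* residuals
$(v_{model}-v)/v_{model}$. Absorbance-based TPA quantification has error
roughly proportional to the signal (constant CV), and for such noise the
relative weighting is the correct generalised least squares; in simulation
it reduces the ${}^{inv}K_M$ sampling SD by ~30% relative to the
unweighted fit and brings the 2-SE coverage of the Jacobian-based
intervals to ~95% (the unweighted fit under-covers at ~88% because its
covariance assumes homoscedastic noise). Unweighted fitting remains
available (`weighting = "none"`). Under relative weighting the
zero-enzyme blanks carry no residual — the model passes through the origin
structurally — but they are retained in the data by default and the
`include_zero` flag exposes both behaviours, since the original protocol
does not state whether blanks entered the fit.

## pH-stat titration stoichiometry (`titration`)

Hydrolysis releases terephthalic acid, which at constant pH 8 consumes
NaOH in a 2:1 molar ratio; ethylene glycol is not acidic and is ignored
(the protocol's stated assumption). With the PET repeat-unit molar mass of
192.2 g/mol:

$$m_{PET} = \tfrac{1}{2}\, n_{NaOH} \times 192.2\ \mathrm{g\,mol^{-1}}.$$

Gravimetric titrant readings convert through molarity and a configurable
solution density (default 1.18 g/mL for 5 M NaOH — the protocol monitors
consumption gravimetrically but does not state the conversion). Percent
degradation above 100% is capped with a warning; above 105% the series is
rejected as a stoichiometry violation. Rates use the same 1 h rolling
linear smoother as the EIS module; times to stated conversions are found
by monotone linear interpolation between bracketing samples.

## nanoDSF melt curves (`thermal`)

The instrument records intrinsic tryptophan fluorescence at 330 and 350 nm
over a 20–95 °C ramp at 1 °C/min; unfolding red-shifts the emission so the
F350/F330 ratio traces a sigmoid. Synthesis uses a two-state van't Hoff
model,

$$f_u(T) = \frac{1}{1 + \exp\!\big[\tfrac{\Delta H_{vH}}{R}
  (\tfrac{1}{T} - \tfrac{1}{T_m})\big]},$$

with linear folded/unfolded baselines and Gaussian noise; the default
$\Delta H_{vH} = 400$ kJ/mol is typical for a single-domain hydrolase,
default baselines 0.80 → 1.00 (ratio units), default noise SD 0.002.

**Extraction.** The apparent $T_m$ is the first-derivative peak, refined
by a quadratic vertex fit. Two details matter:

* *Derivative axis.* For the van't Hoff model the derivative with respect
  to temperature peaks about 0.07 K *below* the midpoint at
  $\Delta H_{vH} = 400$ kJ/mol (the $1/T^2$ tilt), whereas
  $df_u/d(1/T) \propto f_u(1-f_u)$ peaks exactly at the midpoint. The
  default therefore differentiates against reciprocal absolute
  temperature, which makes the estimator unbiased for the model; the
  conventional d/dT axis is available via `axis = "celsius"`. The two
  agree to well within instrument resolution for sharp transitions.
* *Adaptive smoothing.* For effectively noiseless curves, plain central
  differences plus 3-point interpolation recover the midpoint to
  < 0.02 °C. For noisy curves that estimator has ±1.5 °C outliers, so
  when a robust second-difference noise estimate flags the curve as noisy
  the derivative is taken as a local-linear slope over ±3 grid points and
  the vertex fit widens to match. A 300-seed simulation at noise SD 0.002
  gives an error SD of 0.13 °C and a maximum of 0.39 °C; the frozen test
  tolerance is the 3.3-sigma envelope, 0.45 °C. Near the ramp edges the
  smoothing costs some bias (up to ~0.07 °C at 91 °C on the default
  ramp).

Transitions whose derivative peak sits at the edge of the resolvable range
are reported as censored bounds ("> 95 °C"), mirroring how instruments
report melters beyond the ramp.

## Weight loss and fold-activity (`activity`)

Weight loss is $100\,(m_0 - m_t)/m_0$; fold-activity is the ratio of
weight-loss percentages under matched buffer, temperature and duration.
This is a conversion ratio, not a rate ratio: near-complete conversion
compresses it, which is documented rather than corrected. Residual
activity after incubation is normalised to the unincubated reference;
half-lives use log-linear interpolation between bracketing samples (exact
for exponential decay) and are censored ("> 7 d") when the series never
crosses 50%.

## Trajectory geometry (`mdgeom`)

Frames are plain data frames (residue number, residue name, atom name,
coordinates in Å); trajectories are lists of frames, read from multi-model
PDB or a long-format CSV. Binary MD formats are deliberately out of scope.

**Catalytic sub-states.** Two distances classify each enzyme–substrate
frame: the catalytic-serine OG to the attacked ester carbonyl carbon, and
the oxyanion-hole backbone N to the carbonyl oxygen. A frame is
*in-oxyanion* when N–O < 5.0 Å; *near-active-site* when OG–C < 5.5 Å and
N–O lies in [5.0, 7.5) Å; otherwise *other*. Upper bounds are strict and
lower bounds inclusive, so a tie at exactly 5.0 Å goes to
near-active-site and the states partition every frame exactly once. The
substrate atom names default to `C1`/`O1` on residue `MHT` — a topology
assumption, so the selection map is fully configurable.

**Salt bridges.** Occupancy is the fraction of frames whose minimum
side-chain N–O distance (Lys NZ vs Asp OD1/OD2 by default) is at or below
a cutoff, default 4.0 Å. The underlying study never defines "close"
numerically, so the cutoff is exposed and should be reported alongside
results.

**Other measures.** Dihedrals follow the IUPAC sign convention
(mirror-image negates); phi/psi read the standard backbone atoms and fail
informatively at chain termini. Hydrogen-bond geometry reports the
H···acceptor distance, the donor–H···acceptor angle, and an out-of-plane
angle (90° minus the angle between the amide-plane normal and the
acceptor→H direction, signed by the normal). Water radial distribution
functions use minimum-image distances in an orthorhombic box normalised by
ideal-gas shell counts; an open-boundary mode normalises against the mean
density in the histogram sphere. Superposition uses the Kabsch algorithm
with the determinant correction that forbids reflections; a brute-force
rotation-grid oracle validates it on small systems in the test suite.

## Synthetic data (`synth`)

Every analysis input can be generated with the statistical structure the
estimator assumes, from one explicit seed per call (the caller's RNG state
is restored). The generators emulate: Randles sweeps of a film thinning at
a set rate (51 log-spaced frequencies 1 kHz–1 MHz, sweeps every 3 min for
20 h, 1% multiplicative noise on both impedance components); duplicate
rate-vs-[E] datasets on a 0–0.6 µM grid with 5% CV multiplicative noise;
two-state ratio melt curves on the 20–95 °C ramp; monotone logistic NaOH
consumption curves that can be calibrated to cross a stated conversion at
a stated time; trajectories whose frames are drawn i.i.d. with prescribed
state occupancies and then rejection-sampled inside the defining distance
regions (so generated frames classify back to their labels with
certainty); and rigid-motion-plus-jitter structure pairs with known
expected RMSD ($\sigma\sqrt{3}$ for per-coordinate jitter $\sigma$).

The noise magnitudes (EIS 1%, kinetics CV 5%, melt SD 0.002) are package
choices — the protocols report none — set at levels a lab would consider
ordinary for these instruments. What a green round-trip test establishes
is that the estimator recovers the generating parameters under the
assumed noise structure; it does not establish robustness to instrument
artefacts the generators do not model (electrode drift, baseline curvature
beyond linear, product inhibition, correlated replicate error).

## Numerical choices and degenerate inputs

* Randles and inverse-MM fits run on log-parameters (positivity without
  constraints) with analytic Jacobians; standard errors use the
  delta-method back-transform of the Jacobian covariance.
* Quadratic vertex fits condition their normal equations by rescaling the
  abscissa (reciprocal-temperature offsets are ~1e-5 and would otherwise
  be numerically singular).
* Flat melt curves, all-zero rate tables, empty trajectories, non-monotone
  titration series, sub-3-point spectra and sub-3-atom superpositions are
  rejected with informative errors rather than estimated.
* Ties: equal derivative peaks return the first and set an `ambiguous`
  flag; classification ties at boundary distances follow the strict/
  inclusive convention above.

## Known limitations

* The EIS model has no constant-phase element or Warburg branch; films
  with strongly non-ideal dielectric response will show structured
  residuals that the fit diagnostics expose but the model cannot absorb.
* Fold-activity near 100% conversion saturates and understates rate
  differences.
* The charge model counts side-chain formal charges only (His neutral at
  pH 8, Cys/Tyr neutral, termini excluded); it reproduces integer
  formal-charge deltas, not Henderson–Hasselbalch fractional charges or
  pI values.
* Trajectory readers assume orthorhombic boxes and unique (residue
  number, atom name) pairs per frame; altloc and chain identifiers are
  not modelled.
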