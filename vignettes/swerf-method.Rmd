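---
title: "The SWeRF method: size-weighted relevant fine fractions of bulk powders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SWeRF method: size-weighted relevant fine fractions of bulk powders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swerf)
```

## The problem

Occupational exposure to respirable crystalline silica (RCS) causes
silicosis, and under the EU CLP regulation (aligned with the UN GHS) a
product's hazard classification depends on how much *fine-fraction*
crystalline silica it contains: STOT RE category 1 at >= 10% w/w,
category 2 between 1 and 10%, no classification below 1%. But "respirable"
is defined for airborne dust, while classification applies to powders in a
bag. The size-weighted relevant fine fraction (SWeRF) resolves this by
asking: what mass fraction of the bulk powder *would* reach the lungs'
unciliated airways if it were made airborne and inhaled?

## The model

EN 481 gives the probability that an airborne particle of aerodynamic
diameter $D$ ($\mu$m) reaches the alveoli. Expressed relative to total
airborne particles it is the product of the inhalable efficiency and a
lognormal penetration complement:

$$R(D) = \tfrac{1}{2}\left(1 + e^{-\lambda D}\right)
  \left[1 - \Phi\!\left(\frac{\ln(D/m)}{\ln g}\right)\right],
  \qquad \lambda = 0.06\ \mu\text{m}^{-1},\ m = 4.25\ \mu\text{m},\ g = 1.5.$$

This parametrisation is fixed by the standard; its conformance anchors are
$R(1) = 97.1\%$ and $R(10) = 1.3\%$, which discriminate it from the bare
lognormal complement (that would give 99.98% at 1 $\mu$m). Probabilities are
handled as fractions in $[0,1]$ internally and become percentages only at
I/O boundaries.

SWeRF weights the powder's mass-based particle size distribution by this
curve:

$$\mathrm{SWeRF} = \sum_b P(b)\, R(D_b),$$

where $P(b)$ is the mass fraction in bin $b$ and $D_b$ is the bin's
representative aerodynamic diameter. Laser diffraction reports
spherical-equivalent diameters $d$ on a volume basis; for a material of
uniform density, volume and mass fractions coincide and
$D = d\sqrt{SG}$, with $SG$ the specific gravity (2.66 for quartz, 4.48 for
barite). For porous or hollow particles an *effective density* (skeleton
density corrected for internal porosity, kg m$^{-3}$) replaces
$SG \times 1000$ everywhere density enters.

When the crystalline silica shares the size distribution of the other
minerals (the homogeneity assumption), the constituent's fine fraction is
simply $\mathrm{SWeRF}_{CS} = f_{CS}\,\mathrm{SWeRF}$, and blends combine
linearly in mass at the component level — never by merging PSDs of
different densities.

```{r}
quartz <- material("quartz flour", specific_gravity = 2.66,
                   cs_mass_fraction = 1)
flour <- lognormal_psd(median = 3, gsd = 2)
res <- swerf_from_psd(flour, quartz) |> swerf_cs_calculated(quartz)
tidy(res)
```

## The sedimentation route

When the silica does *not* share the bulk size distribution, the fine
fraction is measured gravimetrically. A dispersed sample settles in a
column; after time $t$ the top $h$ of the column is pipetted off and its
residue weighed. For an initially homogeneous column and Stokes settling
(velocity $\propto D^2$), the fraction of size-$D$ particles surviving in
the extracted layer is

$$S(D) = \max\!\left(0,\ 1 - (D/D_c)^2\right),$$

whose integral over diameter is $2D_c/3$. Equating it with the integral of
the respirable convention fixes the cut diameter:

$$D_c = \tfrac{3}{2}\int_0^\infty R(D)\,dD \approx 6.42\ \mu\text{m}
  \ \text{(aerodynamic)}.$$

The settling time through $h$ follows from Stokes' law with buoyancy, with
the aerodynamic-to-physical conversion $d = D_c\sqrt{\rho_0/\rho_p}$
supplying the unit density $\rho_0$:

$$t = \frac{18\,\eta\,h\,\rho_p}
  {g\,(\rho_p - \rho_l)\,\rho_0\,D_c^2}.$$

The equations of the source method are stated there through their symbol
lists and the "equate the integrals" construction rather than as closed
forms; the adopted $S(D)$ and $D_c = 1.5\int R$ are pinned operationally by
the requirement that an ideal sedimentation experiment and the PSD
weighting agree (within $10^{-3}$) on a uniform PSD covering the separation
range — this equivalence is a standing test of the package. Whether the
original derivation used a pipette-withdrawal variant instead cannot be
settled from the published description; the adopted form is consistent with
both the symbol set and the equivalence property.

The measured estimator is $\mathrm{SWeRF} = mH/(Mh)$ ($M$ dispersed mass,
$m$ supernatant residue), and for a constituent quantified in the residue
by FT-IR or XRD, $\mathrm{SWeRF}_{CS} = \mathrm{SWeRF} \times f_{CS}$.
Raw ratios slightly above 1 — weighing noise in the homogeneous-extraction
limit — are clamped to 1 with a warning rather than rejected.

```{r}
plan <- sedimentation_plan(quartz, extraction_height_m = 0.05,
                           column_height_m = 0.20)
plan
swerf_from_measurement(
  data.frame(M_mg = 5000, m_mg = 100, H_mm = 200, h_mm = 40, f_cs = 0.28)
) |> tidy()
```

Two protocol details matter. The time is computed with the *extracted*
height $h$, not the full column $H$, matching the definition of $h$ in the
settling-time formula. And when $\mathrm{SWeRF}_{CS}$ is the target, the
density of quartz/cristobalite is used for $\rho_p$, not the bulk sample's.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| inhalable decay $\lambda$ | 0.06 | per $\mu$m | EN 481 inhalable convention |
| respirable median $m$ | 4.25 | $\mu$m | EN 481 respirable convention |
| respirable GSD $g$ | 1.5 | — | EN 481 respirable convention |
| viscosity $\eta$ | 1.002e-3 | kg m$^{-1}$ s$^{-1}$ | water at 20 °C |
| liquid density $\rho_l$ | 998 | kg m$^{-3}$ | water at 20 °C |
| unit density $\rho_0$ | 1000 | kg m$^{-3}$ | aerodynamic definition |
| dispersed mass | 5 | g | protocol default, 250 ml cylinder |
| solids loading | <= 1 | % v/v | unhindered settling (warns, not errors) |

Temperature is not modelled: viscosity and density are user inputs at the
working temperature. The convention parameters can be overridden through a
YAML configuration file (`read_swerf_config()`), though they should only be
changed to track a revision of the standard.

## Numerical choices

* **Quadrature.** $\int R$ uses adaptive quadrature (`stats::integrate`,
  relative tolerance $10^{-10}$) on $[0, 100]$ $\mu$m with a tail-mass
  guard; $R(100) < 10^{-9}$ for the defaults, and the value is insensitive
  to the limit beyond ~30 $\mu$m. A trapezoid oracle on a 0.01 $\mu$m grid
  agrees within $10^{-6}$ relative, and with the decay coefficient set to
  zero the integral collapses to the lognormal closed form
  $m\,e^{(\ln g)^2/2}$ within $10^{-9}$.
* **Bin representative diameter.** Geometric mean of the bin edges — the
  natural choice for the log-spaced binning of laser diffraction — with a
  0.01 $\mu$m floor on a zero lower edge. Evaluating $R$ at both edges and
  averaging was rejected: it biases coarse-binned PSDs. Discretisation
  error is bounded by a refinement-stability test (200 vs 2000 log-spaced
  bins agree within $10^{-3}$ absolute).
* **Discrete summation, not fitted-curve integration**, because
  instruments report binned data; the Dirac-limit test (a single narrow
  bin reproduces $R(D)$ within $10^{-4}$) and the refinement test bound
  the error from both ends.
* **Boundaries.** Classification thresholds compare full-precision values
  (rounding is display-only, so 0.96% never rounds into a hazard class);
  10.0% is category 1 (the ">= 10%" rule) and 1.0% is taken as the
  inclusive lower bound of category 2 — "between 1 and 10%" leaves the
  lower boundary formally open, and the inclusive reading is the
  precautionary one.
* **Degenerate inputs.** Empty PSDs, non-monotone edges, negative masses,
  $m > M$, $h > H$ and non-settling density pairs
  ($\rho_p \le \rho_l$) all error; fractions not summing to 1 renormalise
  with a warning; an already-aerodynamic PSD refuses a second conversion.
* **Statistics.** Repeatability uses the sample ($n-1$) standard
  deviation, and method agreement is the squared Pearson correlation: both
  choices reproduce the published summary values from the published
  columns (population SD would give 1.30 where 1.41 is printed;
  regression-through-origin $R^2$ reproduces neither printed $R^2$).

## What the synthetic generator emulates — and what it does not

`lognormal_psd()` builds binned lognormal volume distributions (256
log-spaced bins over $\pm 4$ GSD multiples by default, CDF differences with
tail mass folded into the end bins), the standard idealisation of milled
mineral granulometry. `spiked_blend()` reproduces the design of the spiking
study — a quartz-free dense base spiked with quartz flour, combined at
component level. `noisy_sedimentation_run()` applies multiplicative
Gaussian noise to the residue weighing $m$ only, the dominant gravimetric
error (tens of mg after evaporation); heights and the dispersed mass are
treated as exact. The repeatability emulation uses a 9% relative SD,
inferred from the published scatter (SD 1.41 on mean 15.4); that is a
fixture convention, not a claim about any laboratory. The repeatability
fixture itself emulates a flux-calcined diatomaceous earth with
$D_{50} = 9.3$ $\mu$m; its GSD (2.0) and effective density
(1400 kg m$^{-3}$, porous calcined particles) are not published and were
fixed once at field-typical values.

Passing tests on these fixtures show that the arithmetic, the convention
equivalence and the error propagation behave as specified. They do not
show that real powders are lognormal, that real suspensions are free of
flocculation, hindered settling or wall effects, or that laser-diffraction
optics (Mie vs Fraunhofer) are harmless — the published round robin
addresses those, and its per-laboratory data are not reproducible at desk
scale. Published absolute SWeRF values for the commercial products are
likewise out of reach because only their $D_{50}$, not their full PSD, is
printed.

## Problem sizes

The test suite works at desk scale throughout: PSDs of 200–3000 bins,
Monte-Carlo cross-checks of 8 random lognormal specs at $10^5$ draws, and
200 seed batches of 7 noisy replicates. The whole suite runs in a few
seconds.

## Known limitations

* Platy minerals (talc, mica, kaolin) need adapted dispersion; the model
  carries no shape factor.
* Hindered settling, flocculation and non-Stokes regimes are not
  modelled; the dilute-suspension (1% v/v) rule only warns.
* Hydrophobic or floating powders (cenospheres, surface-treated products)
  are outside the sedimentation route's validity.
* Number-basis PSDs and proprietary instrument binaries are not read.
* SWeRF is a classification quantity, not an exposure prediction; it says
  nothing about airborne concentrations during handling.
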