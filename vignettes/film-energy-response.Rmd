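---
title: "Absorbed-dose energy response of radiochromic films: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absorbed-dose energy response of radiochromic films: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcfilm)
```

## The problem

Radiochromic films are high-resolution 2D dosimeters whose active emulsion
darkens with absorbed dose.  Around a brachytherapy source the photon
spectrum softens rapidly with distance, and an emulsion whose effective
atomic number differs from water responds differently to that softened
spectrum than water does.  Since films are calibrated at a reference quality
(Co-60), measurements at other qualities need the *relative absorbed-dose
energy response correction*

$$R(d) = \frac{\left[D_{det}/D_{wat}\right]_{Q(d)}}
              {\left[D_{det}/D_{wat}\right]_{Co60}},$$

the detector-to-water dose ratio at the local beam quality $Q$ normalised by
the same ratio at the reference quality.  `rcfilm` computes $R$ along the
transverse axis (1–15 cm) of point Co-60, Cs-137, Ir-192 and Yb-169 sources
in cylindrical water, PMMA and polystyrene phantoms, for the active
emulsions of seven radiochromic film models (EBT, two EBT2 lots, RTQA, XRT,
HS, XRQA).

Only the *absorbed-dose* energy dependence is computed.  The *intrinsic*
energy dependence (detector reading per unit detector dose) is a property of
the film chemistry and readout and cannot be obtained from photon transport;
it is deliberately out of scope.

## The computational chain

1. **Elemental photon data** (`element_tables()`): per-element mass
   interaction coefficients (photoelectric, incoherent, coherent, pair) and
   mass energy-absorption coefficients $\mu_{en}/\rho$ on 0.008–1.6 MeV
   grids, log-log interpolated.  The Br and Cs K edges (13.47 and 35.98 keV)
   are represented by duplicated grid energies so interpolation never
   bridges an edge.
2. **Materials** (`builtin_registry()`, `mixture_coefficient()`): published
   elemental weight fractions and densities of the film layers and phantom
   media; the weight-fraction additivity rule for mixture coefficients;
   electron density $\langle Z/A\rangle = \sum_i w_i Z_i/A_i$; Mayneord
   effective atomic number $Z_{eff} = (\sum_i a_i Z_i^{p})^{1/p}$ with
   electron-number fractions $a_i$ and $p = 2.94$.
3. **Sources** (`builtin_sources()`): bare isotropic point emitters with
   discrete line spectra.
4. **Transport** (`simulate_transport()`): analog photon Monte Carlo in the
   homogeneous cylinder, with track-length fluence estimation in 0.5 mm
   $\times$ 0.5 mm full-azimuth shells on the transverse plane, 1 keV energy
   bins, 10 keV photon cutoff.
5. **Response** (`collision_kerma()`, `relative_response()`): the fluence
   spectrum of each shell is converted to collision kerma to water and to
   each film emulsion,
   $K = \sum_{bins} \Phi(E)\,E\,(\mu_{en}/\rho)(E)$, and
   $R(d) = [K_{film}(d)/K_{wat}(d)] / \mathrm{ref}$ with the reference ratio
   taken as the emission-weighted film-to-water $\mu_{en}/\rho$ ratio over
   the two Co-60 lines (`co60_reference_ratio()`; a fixed 1.25 MeV mode is
   also provided — the two differ by well under 1% because both energies sit
   on the Compton plateau).

Because no electrons are transported, collision kerma stands in for absorbed
dose everywhere (charged-particle equilibrium assumption); and because $R$
is a ratio of like-geometry kerma values, absolute-fluence errors and any
uniform scaling of a film's coefficient set cancel exactly.

## Where the elemental data come from

No photon cross-section library is part of the package's runtime
dependencies; the tables ship as plain-text CSV
(`inst/extdata/xsec_elements.csv`) generated once by
`data-raw/make_xsec_tables.py`:

* **photoelectric** — Cromer–Liberman photoabsorption
  ($\sigma = 2 r_e \lambda f''$);
* **incoherent** — Klein–Nishina weighted by the Waller–Hartree
  incoherent-scattering-function approximation $S(x,Z) = Z - F^2/Z$ built
  from IT92 atomic form factors (clamped beyond their $x \le 2$ Å$^{-1}$ fit
  range with an $x^{-3}$ tail);
* **coherent** — Thomson cross section weighted by $F^2(x,Z)$;
* **pair** — set to zero: below 1.5 MeV and $Z \le 55$ its contribution to
  $\mu/\rho$ is under 0.1%.  (The transport engine still implements the pair
  branch — local termination plus two back-to-back 0.511 MeV photons — and
  tests exercise it through toy tables.)
* **$\mu_{en}/\rho$** — energy-transfer-weighted photoelectric (with
  K-fluorescence escape for Br and Cs) plus the Klein–Nishina transfer
  integral, reduced by an approximate radiative fraction
  $g = 3.5\times10^{-4}\,Z\,T$.

The generated water values agree with the standard reference tables to
within 0.3% above 60 keV and ~3% at 10–30 keV, and the film-to-water
$\mu_{en}/\rho$ ratios at the Co-60 energy agree with published values to
within 0.7% for all seven films.  One known limitation: the
Cromer–Liberman photoabsorption falls too steeply above roughly 300 keV for
high-Z elements, which depresses the Cs photoelectric coefficient by tens of
percent near 1 MeV; because photoelectric is then a sub-percent fraction of
the Cs total, the effect on any film/water ratio is below 1%.

## Transport model and its approximations

* Analog sampling throughout (no variance reduction): exponential free
  paths from the total attenuation coefficient; channel selection
  proportional to the partial coefficients.
* Compton scattering uses the free-electron Klein–Nishina distribution
  (rejection sampling on $\cos\theta$ with envelope 2); electron binding
  affects the sampled angles only below ~50 keV in low-Z media and is
  neglected in the sampler, while the channel *probability* does include the
  binding correction through the tabulated incoherent coefficient.
* Coherent scattering samples $x^2$ from the tabulated cumulative squared
  mixture form factor (inverse-CDF) with a Thomson angular rejection — the
  standard approach; it matters only for the low-energy fluence shape.
* No fluorescence after photoelectric absorption in the phantom (the K
  energies of H, C, O are far below the 10 keV cutoff).
* Photons falling below 10 keV are terminated on the spot.

Uncertainties: histories are split into 10 equal batches and every reported
1σ is the standard error of the batch means.  Film and water kerma derive
from the *same* tally, so `relative_response()` forms $R$ per batch and the
correlation through the shared fluence is handled exactly; a monoenergetic
unscattered fixture therefore reproduces the analytic
$R(E)$ (`analytic_response_curve()`) to numerical precision, which is one of
the package's acceptance properties.

Numerical details worth knowing: grid-node lookups are bit-exact (including
the top node); an emission energy that falls exactly on an energy-bin edge
is tallied in the bin below it; zero-valued coefficient intervals
interpolate linearly so they stay exactly zero; a tally shell with zero
fluence yields `NA` mean energy (flagged), never zero.

## Study conditions and problem sizes

The defaults mirror the study geometry: 20 cm radius × 40 cm high cylinder,
source at the centre, shells at 1–15 cm, 0.5 mm × 0.5 mm shell cross
section, PCUT-style 10 keV cutoff, 1 keV bins.  The reference work ran up to
$10^9$ histories; this package's validation suite runs $2\times10^6$–
$4\times10^6$ histories per source (seconds each with the compiled engine)
and the acceptance script $2\times10^6$–$10^7$, which puts 1σ statistical
errors on $R$ in the 0.5–2% range at 15 cm — ample for the few-percent
comparisons of interest, since $R$ is a kerma ratio that is forgiving of
absolute-fluence error.

## Source spectra: the deliberate simplification

Sources are **bare isotropic point emitters**.  Co-60 is two equally
weighted lines (1.17, 1.33 MeV) and Cs-137 a single 0.662 MeV line, as in
the reference study.  For Ir-192 and Yb-169 the study did not reprint its
input spectra, so the package embeds the principal gamma and K x-ray lines
with intensities from standard decay data, normalised
(`builtin_sources()$ir192$reference` records the provenance).

This is the package's dominant approximation, and its fingerprint is
visible in the validation numbers.  Encapsulated source models filter and
scatter the emission spectrum: a steel capsule preferentially removes the
~50 keV Tm K x-rays of Yb-169 — which sit exactly at the peak of the
analytic $R(E)$ for the Cs/Br emulsion XRQA ($R \approx 50$) — and adds a
soft scatter component to the Cs-137 line.  Consequently the package
reproduces published $R$ and mean energies within a few percent for Co-60
(and for all low-Z films on every source), but for the high-Z XRT/XRQA
emulsions it overestimates $R$ on Yb-169 by ~15–35% and underestimates the
Cs-137 1 cm value by ~7%.  The in-phantom fluence-weighted mean energies
make the cause explicit: 1.159 vs 1.150 MeV (Co-60, 1 cm) but 0.085 vs
0.103 MeV (Yb-169, 1 cm).  Users who have an emergent (encapsulated-source)
line spectrum can supply it via `read_spectrum_csv()` and the discrepancy
collapses to the transport approximations above.

## Printed-table conventions

Two conventions in the published tables deserve note because the package
had to choose:

* The XRQA composition row sums to 1.035.  `material()` accepts such rows
  and every mixture quantity renormalises to unit sum — except that the
  published $\mu_{en}/\rho$ ratio column for the high-Z films is only
  reproduced with the *as-printed* (unnormalised) fractions, which is why
  `mixture_coefficient()` and `co60_reference_ratio()` expose
  `normalize = FALSE`.  Uniform rescaling cancels in $R$, so simulated
  response curves are unaffected either way.
* The published $\langle Z/A\rangle$ ratio column is the ratio of the
  3-decimal table entries (this reproduces every row, including two that
  are irreproducible from the printed compositions themselves).
* The Mayneord exponent 2.94 reproduces every published $Z_{eff}$ entry
  except XRQA's (computed 32.3 vs printed 34.5); no single exponent
  consistent with the other rows reproduces that one value.  The exponent
  is an argument of `effective_atomic_number()` so other conventions can be
  explored.

## What the fixtures prove (and what they do not)

The toy worlds (`pure_absorber_world()`, `water_twin_film()`,
`make_toy_table()`) give closed-form oracles — uncollided fluence
$e^{-\mu\rho r}/4\pi r^2$, kerma $E\,(\mu_{en}/\rho)\,\Phi$, and the exact
$R \equiv 1$ of a water-composition film — that pin down the estimator
normalisation, the kerma conversion and the ratio structure independently
of any physics tables.  Passing them shows the *machinery* is right; the
fidelity to real film response additionally rests on the elemental data and
the bare-spectrum approximation discussed above, and is checked separately
against the published endpoint values.  None of this validates the
intrinsic (chemical) energy dependence of real films, the effect of the
non-active film layers (the registry stores the layer stacks as metadata
only), source anisotropy, or positions off the transverse plane.

## A worked example

```{r example, eval = FALSE}
tl <- simulate_transport("co60", phantom_spec("water"),
                         shell_tally_spec(distances = c(1, 15)),
                         histories = 4e6, seed = 1001)
kw <- collision_kerma(tl, "water")
kf <- collision_kerma(tl, "xrt")
relative_response(kf, kw, co60_reference_ratio("xrt"))
#>   distance_cm        R        sigma
#> 1           1 1.019662 0.0003399005
#> 2          15 1.816164 0.0242048002
```

The published endpoints for this film and source are 1.027 and 1.845.
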