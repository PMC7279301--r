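---
title: "Estimating protein surface coverage from XPS C1s spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protein surface coverage from XPS C1s spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpsprot)
```

## The problem and the model

X-ray photoelectron spectroscopy probes the top 3–6 nm of a surface. When a
protein is immobilized on a polymer at low density, its survey-level
nitrogen signal can fall below the XPS detection limit (~0.3–0.4 at.%)
while the carbon 1s region still carries its fingerprint: proteins are
amide-rich (backbone N–C=O near 288.1 eV) and amine-rich (C–N near
286.2 eV), whereas a polyester substrate concentrates intensity in the
aliphatic (285.0 eV) and ester (289.0 eV) regions.

`xpsprot` exploits this in two steps.

**1. Sequence → spectrum.** Every carbon of every standard residue is
assigned to one of ten chemical environments (`carbon_environments()`).
Summing counts over the sequence and dividing by total carbon gives
environment fractions $f_{\mathrm{env}}$; the simulated spectrum is the
fraction-weighted sum of unit-area lines,
$$S_{\mathrm{protein}}(E) \;=\; \sum_{\mathrm{env}} f_{\mathrm{env}}\,
  G\!\left(E;\ \mathrm{BE}_{\mathrm{env}},\ \mathrm{FWHM}\right),$$
max-normalized to 1. Components are weighted by carbon fraction only: no
relative-sensitivity or photoelectron-attenuation weighting is applied
(depth effects are a known confound, see *Limitations*).

**2. Spectrum → coverage.** The measured C1s spectrum of the
protein-bearing surface is modelled as a two-component mixture of the
(max-normalized) substrate and protein spectra,
$$S_{\mathrm{res}}(E) = (1-x)\,S_{\mathrm{substrate}}(E) +
  x\,S_{\mathrm{protein}}(E),$$
and `fit_coverage()` estimates $x$ by minimizing a similarity objective.
An independent elemental estimator cross-checks the result from survey
ratios alone:
$$\mathrm{conc} = \frac{(N/C)_{\mathrm{experiment}}}
  {(N/C)_{\mathrm{protein}}} \times 100\%
  = (N/C)_{\mathrm{exp}} \times (C/N)_{\mathrm{protein}} \times 100\%.$$

$x$ is reported strictly as the mixing fraction of the model above.
Whether it measures geometric surface coverage or an analyzed-volume
fraction is left open deliberately: the escape depth of C1s photoelectrons
exceeds that of N1s, so the two estimators need not agree, and their gap is
itself diagnostic (28% elemental vs 11% spectral for fibronectin-class
data is the published scale of that gap).

## The chemistry table and its assignment policy

The per-residue table ships as a plain-text file
(`inst/extdata/residue_chemistry.tsv`) so the chemistry can be audited or
replaced without reading code. Residues are counted *in chain* (free amino
acid minus one water). The default assignment policy is:

* backbone C$\alpha$ → C–N; backbone carbonyl → N–C=O;
* pure hydrocarbon side-chain carbons → CH$_x$;
* Ser/Thr C$\beta$ and the Tyr ring C–OH carbon → C–OH;
* Cys C$\beta$, Met C$\gamma$/C$\epsilon$ → C–S;
* Lys C$\epsilon$, Pro C$\delta$, Arg C$\delta$ → C–N; the Arg guanidinium
  carbon → C=N;
* His C$\gamma$/C$\delta_2$ → C=C–N, His C$\epsilon_1$ → C=N; Trp ring
  carbons bonded to the ring nitrogen → C=C–N;
* other aromatic carbons → C=C;
* Asp C$\beta$ / Glu C$\gamma$ → C–C(O)O; their carboxyl carbons → COOH;
  Asn/Gln side-chain amide carbons → N–C=O.

This reproduces the ten-environment scheme of standard C1s chemical-shift
practice. No authoritative per-residue table is published for this
workflow, so the policy is a documented reconstruction — and it is
pluggable: pass an edited table to `residue_chemistry_table(path)` and
every downstream computation follows it. Protonation states are not
distinguished (COOH vs COO⁻), and termini are handled once per chain: the
C-terminal carbonyl is counted as COOH instead of amide, the N-terminal
amine changes no carbon class, and the chain's water is restored in the
element totals. For a 100+-residue protein the correction is negligible;
for free amino acids it is exact (`composition_profile("A")` returns
alanine's C$_3$H$_7$NO$_2$).

## Component table

Default positions (eV): C=C 284.7, CH$_x$ 285.0, C–S 285.4, C–C(O)O 285.5,
C=C–N 285.9, C–N 286.2, C–OH/C–O 286.5, C=N 286.9, N–C=O 288.1,
COOH/ester 289.0; FWHM 1.1 eV for all components; Gaussian line shape. A
Gaussian–Lorentzian sum shape (`shape = "gl"`, `gl_mix` = Lorentzian
fraction) is available because curve-fitting practice often uses it, but
every validation in this package uses the pure Gaussian. The table is a
CSV (`inst/extdata/component_table.csv`) and fully overridable; binding
energies are constrained to [283, 292] eV.

Grid convention: ascending binding energy, default 280–294 eV at 0.05 eV
steps. Plotting uses the descending-BE display convention; storage is
always ascending.

## Fitting choices

* **Objective.** "Best similarity" is not a defined statistic, so the
  default objective is the RMSE between model and measurement on their
  common grid, with $R^2$ and the maximum absolute deviation reported
  alongside; the objective is pluggable (any `f(model, measured)`).
* **Scan then refine.** The objective is cheap and one-dimensional, so
  `fit_coverage()` scans x ∈ [0,1] at 0.0025 and golden-section-refines
  within ±2 steps. The full scan curve is kept: a valley in which ≥ 20% of
  the scan lies within 1% of the objective range above the minimum flags
  the estimate as *weakly identified* (a numerically flat curve, range
  ≤ 1e−12 on unit-normalized intensities, is always flagged).
* **Renormalization.** Both inputs are max-normalized, and the mixed model
  is re-max-normalized before comparison, consistent with comparing
  normalized intensities; switch with `renormalize_model = FALSE`.
* **Rigid-shift search.** Calibration by shifting the apex of the main
  peak to 285.0 eV is exact only when the apex is a pure aliphatic line.
  For a substrate+protein blend the apex is displaced by peak overlap (the
  synthetic PCL/apolipoprotein mixture apex sits near 285.09 eV), which
  biases the coverage by ≈ +0.04 per −0.1 eV of miscalibration. When the
  charge reference is ambiguous, `shift_search = δ` jointly optimizes a
  rigid energy shift within ±δ eV together with x; with it, the full noisy
  synthetic pipeline (background + 0.3 eV miscalibration) recovers the
  true coverage within 0.01. It is off by default so that the plain
  procedure remains the reference behaviour.

## Spectral preprocessing

* **Shirley background.** Iterative integral background: $B(E)$ rises in
  proportion to the cumulative background-corrected signal on the
  low-binding-energy side, pinned to endpoint levels estimated as the mean
  intensity within ±0.2 eV of each window edge. Defaults: relative
  tolerance 1e−6, 50 iterations; non-convergence is flagged in the result
  and provenance, never silent. Negative corrected intensities are kept
  (and counted) rather than clipped, so later max-normalization is
  unbiased; `clip_negative = TRUE` is explicit.
* **Calibration.** Rigid shift placing the main-peak apex (parabolic
  interpolation through three channels, so finer than the grid step) at
  285.0 eV; idempotent to grid-step/10 and self-inverse to < 5 meV.
* **Resampling** is linear interpolation with extrapolation refused;
  **normalization** requires a positive maximum. Every step appends to the
  spectrum's provenance in order.
* The energy window for fitting is not standardized; it is configurable
  everywhere and recorded in provenance.

## The synthetic-data generator: what a green test establishes

`generate_measurement()` draws one synthetic acquisition from a fully
stated scenario: substrate preset ("pcl" = the theoretical
−(CH₂)₅−C(O)O− repeat-unit composition; "pcl-cooh" = a plasma-polymer
stand-in), a packaged protein, true coverage $x$, expected peak counts
(default 10⁴, a typical high-resolution C1s acquisition), an optional
Shirley-like step background (height a stated fraction of peak counts), a
rigid miscalibration, and Poisson counting noise — the physical model for
a pulse-counting detector (a Gaussian option exists for completeness). A
mandatory seed makes every draw reproducible, and the truth record carries
every knob, so downstream estimates are tested as estimator-versus-truth.
No synthetic spectrum is ever asserted against a published figure.

The generator emulates counting statistics, inelastic background and
charge-referencing error. It does **not** emulate instrument broadening
beyond the fixed FWHM, substrate peak-shape distortion by protein–surface
interaction, fiber-geometry shadowing, or depth-dependent attenuation. A
green recovery test therefore establishes that the estimator is unbiased
to ≤ 0.01 under the stated noise model — not that real measured spectra
obey the two-component model; the published angiogenin-on-plasma-polymer
case, where extra 286.5 eV intensity degrades the attainable fit, is the
standing counter-example, and the package reproduces the *diagnostic*
(raised minimum objective, lower $R^2$) when a distorted substrate is
supplied.

Preset constants that are package choices, not published values: the
plasma-polymer ("pcl-cooh") fractions CH$_x$ 0.65, C–O 0.13, C=O 0.09
(carried on the amide slot with its binding energy overridden to
287.4 eV, since a ketone has no slot in the protein environment set),
C–C(O)O 0.04, ester/COOH 0.09 — chosen to give O/C ≈ 0.40, near the
measured 0.38 for such coatings.

## Sequence fixtures and their provenance

The packaged sequences were assembled offline and are labelled synthetic
in their filenames and headers. The apolipoprotein A-I precursor, tandem
Z-domain and mature angiogenin entries are transcriptions of well-known
published sequences; verify them against their database accessions before
quantitative use. The recombinant angiogenin chimera is built as
leader + ZZ + mature angiogenin with a configurable 8-residue placeholder
leader (`protein_fixture("hrang", leader = ...)`), because the real
artificial leader is unpublished. The fibronectin entry is a
*composition-matched stand-in*: a deterministic sequence whose residue
composition reproduces fibronectin's published elemental signature
(C/N = 3.58); tests against it validate the composition arithmetic, not
database provenance.

## Presentation rules

Ratios are presented at two decimals and percentages as integers with the
fractional part truncated — `eq_elemental_concentration(0.08, 3.58)`
returns 28.64 and presents 28%, matching the printed convention for this
workflow (rounded survey inputs slightly overestimate the unrounded
computation, 5.6/71.3 × 3.58 × 100 = 28.1). Full-precision values are
always returned alongside the presentation.

## Known limitations

* Strictly two components: no multi-protein mixtures, and component
  positions/widths are not refined against the data (classical peak
  fitting is out of scope).
* No attenuation-depth weighting; C1s- and N1s-derived estimates can
  legitimately disagree, and the elemental estimator inherits the
  nitrogen detection limit.
* The chemistry table is a reconstruction of standard practice; for
  residues with ambiguous assignments (e.g. carbons alpha to carboxyls)
  an alternative policy can shift environment fractions by a few percent
  of carbon — use the pluggable table to bound that sensitivity.
* Apex calibration is biased under peak overlap; prefer `shift_search`
  when the reference is ambiguous.
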