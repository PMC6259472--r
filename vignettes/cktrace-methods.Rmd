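---
title: "Measuring cytokinin biosynthetic rates from deuterium-labeling MRM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cytokinin biosynthetic rates from deuterium-labeling MRM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cktrace)
```

## The measurement

When plants grow on medium containing heavy water, deuterium enters
general metabolism and newly synthesized molecules are born labeled while
the pre-existing pool is not. The fraction of labeled molecules in a
metabolite pool after a fixed incubation therefore reports the pool's
relative biosynthetic rate — strictly, its degree of labeling, not an
absolute flux. For cytokinins the readout is a set of MRM channels on a
unit-resolution triple quadrupole: for each riboside analyte one monitors
the transitions (P+j) → (F+j) for j = 0..3, where P is the protonated
riboside precursor, F the protonated free-base product ion, and j the
isotopomer index. Because both ions shift together, only isotopes residing
in the base fragment are registered; the ribose moiety (whose labeling
reflects sugar metabolism, not cytokinin biosynthesis) leaves as the
neutral loss.

Two complications make the raw channel areas uninterpretable on their own.
First, natural heavy isotopes (1.07% ¹³C above all) populate I₁–I₃ even
with no label at all: a C₁₀ fragment has an M+1 abundance of ~12.8% of
M+0. Second, labeled molecules themselves carry natural heavy isotopes, so
a 1-label molecule contributes to I₂ as well as I₁. Deconvolving these
overlaps is the package's core computation.

## The model

Let p = (p₀, …, p₃) be the natural isotopologue pattern of the product-ion
formula, aggregated by integer mass shift (the unit-resolution view; the
instrument cannot distinguish ¹³C from ¹⁵N at the same nominal shift).
Let xⱼ be the amount of molecules carrying exactly j deuterium labels in
the fragment. The expected channel intensities are

$$ I_i \;=\; \sum_{j \le i} p_{i-j}\, x_j , $$

i.e. **I** = C **x** with the lower-triangular correction matrix
C[i,j] = p₍ᵢ₋ⱼ₎. The tracer:tracee ratio is

$$ t/t \;=\; \frac{x_1 + x_2 + x_3}{x_0}. $$

`estimate_tt()` solves for **x** per replicate by non-negative least
squares (NNLS; Lawson–Hanson via `pracma::lsqnonneg`) and aggregates
replicate t/t values to a mean and sample (n−1) SD, matching how replicate
tables are conventionally reported. An alternative `"subtraction"`
estimator performs the classical ordered correction — forward substitution
through the triangular system, equivalent to subtracting I₀·p₁/p₀ from I₁
and so on. The two agree to numerical precision on noiseless data (a
tested contract); under noise NNLS is preferred because it handles
negative excess by constraint rather than by post-hoc clipping, at the
cost of a small positive bias near t/t = 0.

### Approximations, stated

* **Product-ion correction.** The correction uses the product-ion formula
  (base fragment including any retained side-chain propionyl), not the
  precursor. Isotopes in the neutral loss divert signal out of the
  monitored ladder for *all* channels roughly equally, acting as a common
  scale factor that cancels in t/t. This is an approximation, good to the
  extent the ladder is short relative to the neutral loss's pattern.
* **Shared column pattern.** All columns of C reuse the same natural
  pattern although a j-label molecule has j fewer hydrogens subject to
  natural variation. The neglected term is of order the natural ²H
  abundance (1.15 × 10⁻⁴) — far below MRM precision.
* **Window truncation.** Labels beyond the monitored window (e.g. a fully
  D₆-labeled side chain at +6) are invisible to the I₀–I₃ ladder, so t/t
  is in that sense a lower bound. The window `k` is configurable;
  enlarging it beyond the label span leaves t/t unchanged on clean data
  (tested).

## Mass arithmetic conventions

Exact masses are neutral-atom sums of principal-isotope masses from the
pinned table in `extdata/isotopes.tsv` (IUPAC-style values; the file is
checksum-pinned in the tests). No electron mass is subtracted for cations:
calculated m/z values for fragment identification are conventionally
quoted this way in this field at the ~5 ppm fidelity level, and the
package bit-matches that convention (C₅H₉⁺ → 69.0704). Deuterium is its
own symbol `D` with a single isotope at abundance 1 — a label atom, never
a natural-variation source. Nominal masses are integer mass-number sums
(D = 2), the quantity a unit-resolution quadrupole displays.

The displayed ppm error of an experimental value is computed against the
calculated m/z *rounded to 4 decimal places*, matching how both values are
printed in fidelity tables.

## The compound registry and transition design

The registry holds the 11 isoprenoid cytokinins (iP, tZ, cZ, DHZ as free
bases; their ribosides; and the 5'-monophosphates except for DHZ) with
formulas built by residue arithmetic: riboside = base + C₅H₈O₄,
nucleotide = riboside + HPO₃. Propionylation adds C₃H₄O per free hydroxyl
— three on a riboside sugar, plus one on a hydroxylated side chain — which
is forced by the observed masses (504 = 336 + 3×56 for pro-iPR;
576 = 352 + 4×56 for pro-tZR) and implies the reagent acylates hydroxyls
only, not ring nitrogens. Likewise the derivatized zeatin product ion at
276 = 220 + 56 forces the rule "the fragment keeps side-chain
substituents and loses sugar substituents." Nucleotides are not
derivatized or monitored directly: the supported workflow dephosphorylates
them enzymatically and measures the riboside, which is why
`propionylate("iPMP")` is an error, not a formula.

iP-type analytes additionally fragment to a diagnostic isoprenyl cation at
m/z 69 (C₅H₉⁺; 75 with six side-chain deuterons). The registry exposes
this via `sidechain_fragment()`; side-chain transitions are not added to
the default ladders because only the base-fragment ladders are the
established quantitative scheme — the 204→69 route is exposed as metadata
for method development.

Zeatin shorthand: `"ZR"`/`"pro-ZR"` resolve to the trans isomer. cis and
trans zeatins share formulas and transitions; chromatography, which is out
of this package's scope, separates them.

## The synthetic-data generator

`simulate_measurement()` draws I = C **x** scaled to a total signal
(default 10⁶ counts, a realistic summed MRM peak area for picomole-scale
injections), then applies Poisson counting noise and/or multiplicative
Gaussian noise with a configurable CV. Defaults encode the study
conditions the estimator is validated under: n = 5 replicates and CV ≈ 1%
for injection-replicate recovery checks (observed replicate SDs of t/t
around 0.1–0.2 at t/t ≈ 1.3–1.7 correspond to a few percent CV), t/t
setpoints near 1.3–1.7 as measured for iP-type pools after induction, and
all tracer mass in the single-label class x₁ — the dominant class for
short incubations at 30% D₂O within a 4-channel window — with a
configurable `tracer_split` otherwise. Seeds are mandatory; simulations
are bit-reproducible and leave the caller's RNG state untouched.

What the generator does **not** emulate: chromatographic peak shape and
integration error, ion-suppression and matrix effects, detector
saturation, isotope effects on fragmentation, and mechanistic
D-incorporation chemistry (which would couple the label-class fractions to
pathway structure). Passing recovery tests therefore shows the *inverse
computation* is correct and stable under realistic counting/injection
noise — not that any instrument is calibrated.

## Numerical choices

* NNLS is solved at unit scale (areas normalized to sum 1, solution
  rescaled) — areas spanning 10⁰–10⁷ otherwise trip the active-set
  solver's iteration cap. t/t is scale-invariant, so this is exact.
* Patterns are computed by per-element polynomial convolution truncated at
  k; the per-element distribution is the n-fold self-convolution of the
  single-atom isotope distribution. The test suite checks this against an
  independent exhaustive multinomial-enumeration oracle to 10⁻¹⁰ and
  against binomial closed forms for pure-C and H₂ cases.
* Degenerate inputs fail loudly: all-zero measurements, zero tracee
  fraction (saturated labeling has no finite t/t), negative areas, unknown
  analytes, and nucleotide derivatization are all named errors. Batch
  processing logs and skips a failing analyte instead of aborting.
* The t/t monotonicity property (more mass in a labeled channel never
  lowers t/t) holds exactly for NNLS on measurements consistent with
  non-negative label classes, and for the subtraction estimator on any
  input. For physically inconsistent inputs (a labeled channel *below* its
  natural-abundance floor) the NNLS active set can produce small
  non-monotonicities; such inputs indicate an integration problem
  upstream.

## Problem sizes in the test suite

Property-style tests use 1000 randomized deconvolution cases (500 scale
invariance, 500 monotonicity), 1000-draw noise-recovery batteries, and
1000-replicate Poisson calibration checks; pattern-oracle comparisons run
exhaustive enumeration up to C₁₃H₁₈N₅O₂⁺ (≈10³ isotope assignments).
These sizes give comfortable statistical resolution for the asserted
tolerances while keeping the full suite under half a minute.

## Known limitations

* t/t compares labeled to unlabeled molecules within the monitored
  fragment and window; it is not an absolute biosynthesis flux and does
  not model precursor-pool enrichment (the 30% D₂O feed) or time-course
  kinetics.
* Only [M+H]⁺ chemistry, positive mode, and unit-resolution ladders are
  supported; no isotope fine structure.
* Glucosides and aromatic cytokinins are outside the registry.
* Whether replicate SDs describe biological or injection replicates is the
  caller's bookkeeping: replicate ids are opaque to the package.
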