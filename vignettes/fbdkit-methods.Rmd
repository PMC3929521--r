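---
title: "Models and methods in fbdkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fbdkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbdkit)
```

fbdkit implements a quality-by-design workflow for chromatographic method
development and nanoparticle formulation assessment. This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where the literature leaves a genuine choice open.

## Experimental designs

Screening uses the standard published Taguchi orthogonal arrays L4, L8 and
L9. Orthogonality — every pair of columns containing each level combination
equally often — is what lets main effects be estimated independently from
very few runs; `main_effects()` computes the mean response at the high level
minus the mean at the low level of each factor, so its sign is the direction
of the effect and it is invariant to run order.

Response surfacing uses the face-centred central composite design: the
2^k factorial corners, 2k axial points on the faces (coded ±1, not a
rotatable α), and replicated centre points. With k = 2 and five centre
replicates this is the classical 13-run design bundled as a fixture. The
centre replicates are the only replicated rows and therefore carry the
entire pure-error estimate — four degrees of freedom in the bundled design.

Coded levels −1/0/+1 are *labels bound to user-supplied actual levels*, not
an arithmetic scale. A pH factor studied at 2.5/3.5/4.0 has its centre off
the midpoint, so `coded_to_actual()` interpolates piecewise-linearly on the
two segments [low, centre] and [centre, high]. This preserves the study's
usable level mapping without inventing equidistant levels; the price is that
the coded-to-actual map is not a single affine transform, which is why the
model is **always fit on coded units** and actual settings are derived only
when reporting. Run-order randomization is seeded and recorded in the
design table so a design can be reproduced exactly.

## The quadratic response-surface model

`fit_rsm()` fits the full second-order polynomial

$$ y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j + \sum_i b_{ii} x_i^2 $$

by ordinary least squares via a QR decomposition of the package-built model
matrix (1 + 2k + k(k−1)/2 columns). The assumptions are the usual ones:
additive i.i.d. Gaussian noise and a response smooth enough over the studied
region for a quadratic to capture its curvature. On the FCCD the linear
columns are orthogonal to the rest of the model, so the linear coefficients
equal $\sum x_i y / \sum x_i^2$ and do not shift when quadratic terms are
added or dropped — a property the test suite asserts. A rank-deficient
design raises an error naming the aliased terms rather than silently
dropping them.

`anova()` on a fit partitions SS(total) = SS(model) + SS(residual) and
splits the residual into lack of fit and pure error using replicated design
points. The lack-of-fit F statistic compares model inadequacy against
replicate noise; a *large* F (small p) means the quadratic is inadequate.
Note that with very tight centre replicates — the bundled retention-time
data have a centre spread of ~0.02 min against a residual SD of 1.6 —
lack-of-fit F values become huge even for a usable model; the package
reports the standard orientation and encodes no pass/fail rule on it.

Coefficients are kept in full double precision; printing rounds to three
decimals, the convention used when such polynomials are reported.

## Desirability optimization

The study goal — minimize analysis time while maximizing resolution and
keeping asymmetry near 1 — is a multi-response problem with no single
printed combiner, so the package adopts the Derringer–Suich formalism:
linear ramps map each predicted response to d ∈ [0, 1] (minimize, maximize
or two-sided target), and the overall desirability is the weighted
geometric mean $D = (\prod d_i^{w_i})^{1/\sum w_i}$. The geometric mean
makes D = 0 wherever any single goal is fully unmet, and uniform rescaling
of all weights cancels. Weights act only in the combination, not inside
the ramps, which is exactly what makes that invariance hold.

The optimizer is an exhaustive grid search over the coded region (default
201 points per axis, ~2.5 ms per goal on a 2-factor problem). For a 2-D
problem exactness and auditability beat speed: the reported optimum is
reproducible by brute-force enumeration over the same grid, and the test
suite does precisely that. An all-zero desirability surface is reported as
such, not raised as an error, since it is a legitimate (if unwelcome)
finding about the goals.

## Validation statistics

Calibration is unweighted least squares of peak area on concentration by
default (1/x and 1/x² weighting available), matching how linearity is
normally assessed over a working range. LOD and LOQ follow the ICH
formulas 3.3 σ/S and 10 σ/S. σ is deliberately taken as the **residual
standard deviation of a low-concentration calibration line** (a separate
six-standard curve near the limits), the ICH-sanctioned reading of
"standard deviation of the response"; an SD-of-blank estimate can be passed
instead. Whatever σ is used, LOQ/LOD = 10/3.3 identically — so a printed
pair whose ratio differs from 3.03 cannot have come from these formulas,
and the package makes no attempt to reproduce such a pair.

Precision uses the sample (n−1) standard deviation throughout, since QC
replicate sets are samples, and %RSD = 100·SD/mean is scale invariant.
Accuracy is the exact ratio 100·observed/nominal. Acceptance flags follow
the bioanalytical 15% rule, relaxed to 20% at the LLOQ. When recomputing
cells of a printed QC table, agreement is checked to within last-digit
truncation (|Δ| ≤ 0.01): published tables of this kind truncate rather
than round (97.625 printed as 97.62), and the fixtures reproduce that
systematically.

System suitability reports both plate-number conventions — N = 16(tR/w)²
from the base width and N = 5.54(tR/w₅₀)² from the half-height width —
because published tables list both. The tailing factor uses the USP
5%-height convention T = w₀.₀₅/(2f); the 10%-height asymmetry factor is a
distinct quantity and is not conflated with it. Resolution is
Rs = 2(tR₂ − tR₁)/(w₁ + w₂) on base widths.

## Release kinetics

Encapsulation efficiency is inferred by difference,
EE% = 100(added − free)/added, so EE% + 100·free/added = 100 exactly; drug
loading is 100·drug-in-NP/NP-weight.

Dissolution sampling with replacement dilutes the medium: each 1 mL
aliquot removed carries drug away and is replaced by fresh buffer. The
standard additive correction
$$ C_n^{corr} = C_n + \frac{V_a}{V_m} \sum_{i<n} C_i $$
restores the removed mass before converting to percent of dose. The
protocol describes the sampling but no formula; this correction is exact
for a well-stirred vessel, which the tests verify with a forward
mass-balance simulator: concentrations generated by simulating the
withdraw-and-replace protocol are corrected back to the true release
schedule to machine precision. Time units (days for the 15-day release
study, hours for PK) are carried explicitly and never converted silently.

Model fitting linearizes each candidate: Q vs t (zero order), ln(100 − Q)
vs t (first order), Q vs √t (Higuchi), with R² reported from the
linearizing regression. The zero-order fit keeps a free intercept by
default so an initial burst shows up as Q₀ > 0 (forced-through-origin is
available). Points where a transform is undefined (Q ≥ 100 under first
order) are excluded with a warning rather than poisoning the fit.

The release generator produces Q(t) = B(1 − e^{−rt}) + k₀t capped at
100%, with defaults B = 15%, r = 5/day and k₀ = (80 − 15)/15 ≈ 4.33 %/day:
a burst essentially complete within day 1 and ~80% cumulative release at
day 15, the sustained-release scenario the package is built around. The
burst rate 5/day was chosen once so the burst phase is numerically and
visually distinct from the zero-order phase. When recovering k₀ from such
a profile, the zero-order model is fitted to the post-burst phase
(t ≥ 1 day), where the burst term contributes only e^{−5} ≈ 0.7% of B.

## Non-compartmental pharmacokinetics

`nca()` computes Cmax and tmax by direct maximum (earliest time on ties),
λz by OLS of log concentration on time over a terminal window, linear
trapezoidal AUC and AUMC with the standard tail extrapolations, t½ =
ln2/λz and MRT = AUMC₀–∞/AUC₀–∞. The terminal-window rule is the common
best-fit convention: every suffix of ≥3 positive points strictly after
tmax is fitted and the window with maximal adjusted R² wins; an explicit
time window overrides it. The linear trapezoid was chosen as the simplest
defensible default (log-linear-down methods change AUC by well under the
reproduction tolerances used here); concentrations below a supplied LOQ
are treated as missing after the first sample; dose normalization is not
applied because the package's comparisons are between same-dose groups.

The identities MRT·AUC = AUMC, t½·λz = ln2 and AUC₀–∞ ≥ AUC₀–t hold for
every successful analysis by construction and are asserted property-style
over simulated cohorts. Group comparison is the two-tailed Welch unpaired
t test (unequal variances, Welch–Satterthwaite df), delegated to
`stats::t.test` and cross-checked in the tests against the published
formulas directly; for two zero-variance groups with equal means p = 1 by
convention.

The PK generator is the one-compartment oral-absorption (Bateman) model
with multiplicative log-normal noise — chosen over additive Gaussian so
simulated concentrations stay positive. Its analytic tmax, Cmax and
AUC₀–∞ = D/(V/F·ke) are attached as metadata, enabling closed-loop
recovery tests (λz within 2% of the generating ke at the study's sampling
schedule; trapezoidal AUC within 1% at dense sampling).

## What the simulators do and do not show

Every generator is deterministic under a fixed seed (applied locally, so
the caller's RNG stream is untouched) and documents its ground truth in an
attribute. They emulate the *shape* of real data — quadratic surfaces with
homoscedastic noise, Bateman profiles, burst + zero-order release,
exponentially modified Gaussian peaks — but not matrix effects, assay
carryover, heteroscedastic detector noise, inter-occasion variability or
nanoparticle polydispersity. A passing recovery test therefore shows the
estimators are correct for their stated models, not that the models fit
any particular laboratory's data.

Problem sizes in the test suite were picked for tight Monte-Carlo
resolution at interactive speed: 500 replicates for the unbiasedness
check of the surface fit, 0.25 h sampling over 400 h for dense-AUC
convergence, and a 101–201 point grid per axis for optimizer audits.

## Known limitations

- Only face-centred CCDs (α = 1); no rotatable or Box–Behnken designs,
  no D-optimal augmentation, and only the L4/L8/L9 screening arrays.
- No stepwise term selection, ridge/Bayesian fitting, or canonical
  analysis of the stationary point.
- Release models are the three classical linearizations; no
  Korsmeyer–Peppas or mechanistic diffusion–erosion models.
- NCA is model-free by design; no compartmental fitting or
  bioequivalence statistics.
- Peak descriptors are consumed as numbers; the package does not
  integrate raw chromatogram traces.
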