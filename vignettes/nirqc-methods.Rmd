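---
title: "In-silico development and validation of a NIR QC method for a two-API capsule blend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico development and validation of a NIR QC method for a two-API capsule blend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirqc)
```

## The problem

A fixed-dose antimalarial combination — artesunate (AS) plus azithromycin
(AZ) — is filled as a powder blend into hard gelatin capsules (HGC). Both
actives are present at high mass fraction (AZ ~51%, AS ~37% w/w with
microcrystalline cellulose and colloidal silica as excipients), which makes
near-infrared diffuse-reflectance spectroscopy a practical content-control
technique: no solvent, no sample destruction, one spectrum per capsule
fill. The price is chemometric machinery: multiplicative scatter and
baseline drift must be removed, content must be estimated by multivariate
regression (PLS1, one model per API), method *specificity* must be shown by
an identification model that rejects wrong or degraded products, and
*accuracy* must be demonstrated by β-expectation tolerance intervals held
inside fixed acceptance limits (±5% relative).

`nirqc` implements this whole workflow as reusable, tested functions, and —
because no raw spectra from the original study are publicly deposited —
couples it to a synthetic spectra generator that emulates the statistical
structure the analysis relies on. Every headline quantity in this vignette
and in the README is computed by the package itself at run time.

## Blend designs

Designs are pure arithmetic on the label composition. For a varied API at
level $L$% of label in a blend of total mass $M$:

$$m_\mathrm{varied} = \frac{L}{100}\, w_\mathrm{v} M, \qquad
  m_\mathrm{fixed} = w_\mathrm{f} M, \qquad
  m_\mathrm{placebo} = M - m_\mathrm{varied} - m_\mathrm{fixed},$$

where $w_\mathrm{v}, w_\mathrm{f}$ are the label mass fractions. The
placebo is the *qsp* fill, so masses sum to $M$ exactly and the design is
infeasible when the placebo would go negative. The default calibration
design spans 80–120% of label in 5% steps (nine levels) with six
calibration and three validation vials per level — 54 and 27 samples. The
published weighing tables for this design agree with the nominal arithmetic
to within 0.5% relative on the API masses (one historically overfilled row
reaches ~2%), which is the tolerance our tests assert.

## The synthetic spectra generator

Each component has a stand-in pure spectrum: a sum of Gaussian bands
$A(\nu)=\sum_b h_b \exp(-(\nu-c_b)^2/2\sigma_b^2)$ on a uniform grid. The
instrument range is 4000–9999 cm⁻¹; the digitization interval is 4 cm⁻¹
(1500 points), a conventional choice of interferogram zero-filling for an
8 cm⁻¹ optical resolution. Gaussian band shapes (rather than
Lorentzian/Voigt) keep every downstream closed-form test exact.

A recorded blend spectrum is

$$A_\mathrm{obs}(\nu) = g \sum_i f_i A_i(\nu) + b_0 + b_1 \tilde\nu +
  \varepsilon(\nu),$$

with mass fractions $f_i$, a per-spectrum log-normal gain $g$
(scatter/packing density), a random linear baseline in the normalized
wavenumber $\tilde\nu$, and iid additive noise — exactly the disturbances
SNV and derivative pre-treatment are designed to remove, which makes the
benefit of pre-treatment demonstrable (and tested). Component masses are
perturbed by a relative weighing error before conversion to fractions, and
every recorded sample spectrum is the mean of three independent draws with
identical fractions, emulating triplicate recording with repacking of the
vial between scans. Default noise levels: gain SD 0.5%, baseline offset and
slope SD 5×10⁻⁴ AU, additive SD 1×10⁻⁴ AU, weighing SD 0.15%; the
multi-series validation study adds a between-series gain SD of 0.3% as a
day/operator effect.

Band positions sit at plausible C–H/O–H overtone and combination regions
and are balanced so the blend spectrum at label composition is dominated by
the AZ features, as observed for the real formulation. The degradant
dihydroartemisinin (DHA) reuses the AS band pattern shifted by +30 cm⁻¹
with 10% lower heights: a spectral *displacement*, not a mere intensity
change, so specificity is a genuine subspace question. The AS bands inside
the analysis regions are deliberately narrower (55–120 cm⁻¹ SD) than the AZ
bands: a 30 cm⁻¹ shift of a narrow band produces a clear first-derivative
signature. What the generator does **not** model: radiative-transfer and
particle-size physics (Kubelka–Munk), instrument line shape, wavelength
drift, nonlinear detector response, and chemical interactions between
components. Passing tests therefore show correctness of the *statistical
pipeline* under its own assumptions, not instrument-transferable
performance on real powders.

All randomness flows from one study seed set once at the start of a run;
stages draw sequentially from the single R stream, so a run is
bit-reproducible from `(config, seed)`.

## Pre-processing

The retained treatment is dual-region: on 5311–6811 cm⁻¹, SNV (per-spectrum
standardization with the $n-1$ SD) followed by a first Savitzky–Golay
derivative (11-point window, second-order polynomial); on 7200–9999 cm⁻¹,
raw absorbance. Features are concatenated and mean-centered; centering is
learned on the calibration set only and *always* re-applied from stored
means (an explicit leakage test asserts this). Numerical choices:

* SNV before the derivative — the conventional order where the wording of
  combined treatments is ambiguous; both stages are configurable.
* SG edge policy: the $(w-1)/2$ edge points of each region are dropped so
  every retained point uses the exact central-window convolution
  coefficients (from `signal::sgolay`); region 1 thus contributes
  375 − 10 = 365 features and region 2 700.
* Derivatives are per cm⁻¹ (coefficients divided by the grid spacing), so
  results do not depend on the digitization interval.
* Region bounds are closed intervals on the digitized grid.
* No block scaling between the two differently treated regions: the SNV +
  derivative block has much smaller numeric range than the raw block, and
  PLS weights accommodate that; an autoscaling variant was considered and
  left out to keep the treatment identical to the two-block original.
* Mean-centering happens after region concatenation (fit-time column
  means); centering before versus after concatenation is algebraically
  identical here since both are column-wise.

## PLS1 calibration

One model per API (no PLS2 — the two contents are deliberately decoupled by
the one-API-varied designs). The NIPALS PLS1 factorization is implemented
directly: for each factor, $w = E^\top f/\lVert E^\top f\rVert$, $t = Ew$,
$p = E^\top t/t^\top t$, $q = f^\top t/t^\top t$, then deflation
$E \leftarrow E - tp^\top$, $f \leftarrow f - tq$. For a single response
each factor is one exact step, so no inner iteration is needed; a
rank-deficiency guard stops factor extraction when $\lVert E^\top f\rVert$
vanishes. The regression vector is $b = W(P^\top W)^{-1}q$ and predictions
are $\hat y = \bar y + (x - \bar x)^\top b$. At full rank the predictions
coincide with ordinary least squares, which the tests exploit as an
independent oracle (together with scikit-learn's NIPALS implementation on a
small fixture).

The factor count is chosen by venetian-blinds cross-validation (6
interleaved folds, stratified by concentration level so each fold holds one
vial of every level), minimizing RMSECV with ties resolved toward fewer
factors; the search runs to 8 factors. The external validation set is never
used for selection — RMSEP on it is reported separately in the merit table
(factors, $r$, residual extremes, RMSEC, RMSEP), mirroring the usual
figures of merit.

## Specificity

A single PCA identification model is fitted to all calibration spectra
(both designs) after the same pre-processing. Acceptance requires both a
score-space Mahalanobis distance within the $\sqrt{\chi^2_{k,0.999}}$
radius and an orthogonal residual norm within mean + 5 SD of the training
residuals. The component count defaults to **4**: the training cloud has
two composition degrees of freedom (one per varied API), and the raw
spectral block contributes two further systematic directions — baseline
offset and slope — that would otherwise inflate the residual threshold and
mask a small degradant signal. With 4 PCs the training residual is pure
noise and the 10% DHA spike (3.7% DHA w/w) sits a factor ~2 above the
residual cut-off, while placebo and pure-API challenges fail already on
score distance. The first two PCs still explain ~99.9% of training
variance, consistent with the published two-PC scores plot. The original
instrument software's proprietary rejection rule is not reproducible; only
this qualitative behavior (full proof-set rejection, ≥95% genuine
acceptance) is claimed, and it is what the test suite asserts over 20
seeds.

## Accuracy profiles

The validation study re-prepares 80/100/120% blends in $p = 3$ independent
series of $n = 3$ replicates (the series × replicate reading of
"three replicates on three days by two persons"; the layout is
configurable but must be balanced — unbalanced data are rejected with an
error). Per level, relative errors $e = 100(\hat y - y_\mathrm{true})
/ y_\mathrm{true}$ are decomposed by one-way random-effects ANOVA (method
of moments): $s_W^2 = MS_\mathrm{within}$, $s_B^2 = \max(0,
(MS_\mathrm{between} - MS_\mathrm{within})/n)$ — negative estimates are
truncated at zero by convention. The β-expectation tolerance interval uses
the Mee/Satterthwaite form: with $R = s_B^2/s_W^2$,

$$B^2 = \frac{R+1}{nR+1}, \qquad
  \nu = \frac{(R+1)^2}{\dfrac{(R+1/n)^2}{p-1} + \dfrac{1-1/n}{pn}}, \qquad
  \mathrm{limits} = \bar e \pm t_{\nu,(1+\beta)/2}\,
  s_{IP}\sqrt{1 + \frac{1}{pnB^2}},$$

with $s_{IP}^2 = s_W^2 + s_B^2$. Limits $R \to \infty$ ($s_W^2 = 0$):
$B^2 \to 1/n$, $\nu \to p-1$; both variances zero give the degenerate point
interval. Several β-expectation variants exist in the validation
literature; this one is implemented because its Monte-Carlo coverage is
verifiably close to β (a 400-study × 250-future-draw simulation in the test
suite checks |coverage − 0.95| < 0.03 at $p=n=3$). β defaults to 0.95 — the
customary choice where none is stated — and the acceptance limit λ to ±5%,
the pharmaceutical-assay convention for this dosage form. The procedure
passes when every level's interval lies inside (−λ, +λ).

## Problem sizes and determinism

A full `run_full_study()` — two 54-sample calibrations, two 27-sample
external validations, a 54-spectrum identification training set, challenge
and genuine specificity sets, and two 27-measurement validation studies on
the 1500-point grid — takes about a second on one core; the test suite
keeps its Monte-Carlo blocks (coverage simulation, 20-seed specificity
sweep) at sizes that run in seconds while still pinning the distributional
claims. Determinism is tested by re-running the study at the same seed and
requiring identical output.

## Known limitations

* The generator's linear mixing ignores inter-component spectral
  interactions and moisture; real validation data will show larger biases
  than the sub-percent figures typical of the synthetic study.
* The merit figures of the synthetic study (RMSEC/RMSEP of a few
  hundredths of a percent of label) are tighter than those achievable on
  real powders; they scale directly with the configured noise model.
* Only balanced validation designs are supported, matching the study
  layout.
* The PCA thresholds assume approximately Gaussian training scores;
  strongly clustered calibration designs would make the chi-square radius
  conservative.
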