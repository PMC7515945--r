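---
title: "Cerenkov luminescence margin assessment: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerenkov luminescence margin assessment: models, phantom and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliMargin)
```

## The problem

After radical prostatectomy, a *positive surgical margin* (PSM) — tumour
reaching the inked surface of the excised specimen — predicts biochemical
recurrence, but margin status is normally known only days later from
histopathology. Cerenkov luminescence imaging (CLI) offers an
intraoperative alternative: after intravenous injection of a
⁶⁸Ga-labelled PSMA ligand, beta particles emitted in PSMA-avid tumour
deposits produce faint broadband Cerenkov light that a cooled
photon-counting camera can image on the excised specimen, view by view.
Because short-wavelength light is attenuated far more strongly by tissue
than red light, a hotspot that *persists* when the acquisition is
repeated through a 550 nm shortpass filter must originate close to the
cut surface — the optical surrogate for a PSM.

`cliMargin` implements this analysis end to end for method developers and
physicists: the isotope/Cerenkov physics, a ground-truthed synthetic
specimen-image generator, the deterministic processing chain, ROI-based
radiance quantification with decay and activity corrections, the
persistence classifier, and staff-dosimetry bookkeeping. No clinical
images ship with the package; every claim the test suite makes is
demonstrated on the synthetic phantom.

## Physics layer

**Beta spectra.** Decay spectra use the allowed-transition shape
$dN/dE \propto F(Z,E)\, p\, W\, (Q-E)^2$ with momentum $p$, total energy
$W$, endpoint $Q$, and the non-relativistic Fermi function
$F = 2\pi\eta / (1 - e^{-2\pi\eta})$, $\eta = \mp Z\alpha/\beta$ (minus
for positrons, whose low-energy emission is Coulomb-suppressed; $Z$ is
the daughter's atomic number). This is deliberately the simplest shape
that is adequate for yield *ratios*; it is cross-checked in the tests
against an independent fine-grid quadrature of the same formula.

**Threshold and yield.** Cerenkov emission requires $\beta n > 1$, i.e.
kinetic energy above
$E_{th} = m_ec^2\,(1/\sqrt{1-n^{-2}} - 1)$ — about 264 keV in water
($n = 1.33$). The photon number per decay integrates the Frank–Tamm
emission along the particle's slowing-down path (continuous-slowing-down
approximation):

$$N(E_0) = \int_{E_{th}}^{E_0} \frac{2\pi\alpha\,(1/\lambda_1 - 1/\lambda_2)
\left(1 - \tfrac{1}{\beta^2 n^2}\right)}{S(E)}\,dE,$$

with $S(E)$ the collision stopping power of water, supplied as a compact
log–log-interpolated table (10 keV–3 MeV) and replaceable by any function
of the same signature. `cerenkovYield()` draws initial energies from the
spectrum Monte-Carlo-style (seeded, reproducible) and reports the mean
photon number together with its standard error. With these defaults the
⁶⁸Ga : ¹⁸F yield ratio in water over 400–800 nm comes out near 30; given
that the published "≈ 22×" figure folds in an unspecified detector
spectral response, the package's tests assert only order-of-magnitude
agreement (a 10–40 band) plus the exact physics limits (zero yield below
threshold, monotonicity in endpoint and band width).

**Decay and attenuation.** `decayFactor(t, T½) = 2^{-t/T½}` uses the
clinical rounded ⁶⁸Ga half-life of 68 min (configurable through the YAML
isotope registry, where ⁸⁹Zr and ⁹⁰Y are also provided). Depth-dependent
optical transmission is Beer–Lambert, $e^{-\mu_{\text{eff}} d}$, with
band defaults $\mu_{\text{eff}} = 10\ \text{cm}^{-1}$ below 550 nm and
$2\ \text{cm}^{-1}$ for the unfiltered (red-dominated) band. These are
order-of-magnitude soft-tissue values and are declared configuration, not
ground truth; only their *ordering* carries scientific weight, and only
that ordering is asserted in tests.

## The synthetic specimen phantom

Each of the six specimen views (left/right, anterior/posterior,
basal/apical) is an independent 2-D field: a uniform benign surface
radiance plus Gaussian lesions. A lesion's lateral profile convolves its
intrinsic extent with positron-range blur, an isotropic Gaussian whose
*mean radial displacement* equals the isotope's mean positron range
(2.8 mm for ⁶⁸Ga), i.e. $\sigma = \text{range}/\sqrt{\pi/2}$. Its depth
below the excision surface attenuates its light per band; depth 0 is the
ground-truth PSM, depths under 0.1 mm are labelled CLOSE (the near-margin
band reported separately by the classifier's scoring), anything deeper is
NSM.

Rendering follows the physical signal chain: expected counts =
radiance × camera calibration × activity scaling × decay at frame start ×
filter throughput × exposure; Poisson counts are then degraded by
Gaussian read noise, a constant dark offset, sparse gamma strikes
(Poisson count with mean rate × exposure; exponential amplitudes
truncated above 5× read noise), a fixed defective pixel at full scale on
every frame, binning by block summation, and clipping to the bit depth.
One master seed expands deterministically into per-frame seeds, so whole
studies are reproducible frame by frame.

Defaults and why:

* **117 µm unbinned pitch** — 2×2 binning then gives the clinical 234 µm.
* **256 × 256 unbinned sensor** — compact but large relative to lesions.
* **benign radiance 500 p/s/cm²/sr at the 100 MBq reference** — produces
  well-exposed frames (hundreds of counts per binned pixel) at the
  favoured 150 s / 8×8 protocol.
* **camera calibration 10⁻⁴ counts·s⁻¹·px⁻¹ per unit radiance** — a
  plausible étendue for a photon-counting specimen imager; no published
  device constant exists, and every TBR is invariant to it.
* **uptake ratio 8** — the lesion:benign activity-concentration ratio.
  PSMA PET uptake ratios in high-grade tumour are typically well above
  the TBRs seen optically; with the device's σ = 3 px smoothing at 8×8
  binning a ratio of 8 yields measured filtered TBRs around 3–4 for
  surface lesions, the clinically reported range.
* **filter throughput 0.545** — the fraction of a $1/\lambda^2$ Cerenkov
  spectrum between 400 and 550 nm relative to 400–800 nm, so filtered
  frames are dimmer in both tumour and background, as observed clinically.
* **decay applied at frame start**, not mid-exposure — under 2% error for
  150 s at a 68 min half-life.

What the phantom does *not* emulate: 3-D specimen geometry (views are
independent fields), ambient-light leakage, PSMA-expression
heterogeneity, specimen-surface curvature, or a specific commercial
camera's calibration. Tests passing on the phantom therefore validate the
*pipeline logic and its physics-driven contrasts*, not absolute clinical
radiance levels.

## Processing chain

The on-device gamma-strike suppression is a 3×3 median followed by a
σ = 3 px Gaussian. The order is a deliberate choice: the source lists
both filters without stating order, and running the median first removes
impulses before any linear smoothing could spread them; the order is
configurable. Both filters use reflect (symmetric) boundary handling to
avoid dark rims at the field edge; a constant raster passes through
unchanged and the raster maximum can never increase.

Background subtraction requires a settings-matched empty-tray frame
(same exposure, binning, filter) — a mismatch is a hard contract error,
because that matching is what makes the dark offset and the
defective-pixel artefact cancel. Negative differences are clamped to zero
(radiance is physical); a signed diagnostic output is available. Binning
sums blocks and crops non-divisible trailing rows/columns (never pads).
Radiance calibration is linear, `counts / (calibration × exposure)`, with
calibration 1 by default (arbitrary-units radiance; all TBRs cancel it).

## Quantification

ROI means are arithmetic means over explicit pixel masks (supplied as
masks, polygons rasterized by the even-odd rule at pixel centres, or the
automatic lowest-half surrogate for benchmarks). Decay correction
references the injection time — the only timestamp available for every
patient — and activity normalization rescales to a 100 MBq reference, the
protocol's nominal injection, keeping p/s/cm²/sr units. Cohort
dispersions use the population (divisor *n*) standard deviation because
that convention reproduces the published "mean ± sd" cohort lines
(83 ± 19 MBq; cleaved-prostate TBR 3.6 ± 1.4 filtered, 2.1 ± 0.4
unfiltered); the sample convention is available behind a flag.

## The persistence classifier

Clinically, hotspots are marked visually; the package's surrogate is
fully parameterized and declared as such: pixels above
`background mean + k·sd` (default `k = 3`), 4-connected components of at
least `minArea = 4` binned pixels. Because that threshold sits just above
background, a smooth hotspot's component includes its faint tail, so TBRs
are measured over the component's *half-maximum core* — the compact ROI a
reader would draw. A hotspot is *persistent* when its TBR over the same
core on the shortpass-filtered map reaches `tauPersist` (default 2.0,
chosen because the histopathology-positive hotspots in the published
cohort all had filtered TBRs of 2.5 or more, and configurable precisely
because a quantitative threshold is the open clinical question). A view
is `PSM_suspected` iff at least one hotspot persists; the specimen-level
verdict is the OR over views. Whether *visual* or *quantitative*
persistence should govern is unresolved in the source material
(one patient had a faint filtered hotspot but a high quantitative TBR);
both modes are reachable — the quantitative rule is the default, and with
no filtered acquisition the classifier falls back to the unfiltered TBR
and flags the verdict low-confidence.

## Benchmark study conditions

Two simulation experiments back the package's property-level claims; the
test suite and `scripts/acceptance.R` run both.

**Persistence recovery.** Twenty single-lesion studies at depths
{0, 0.05, 3, 6} mm, 150 s / 8×8, default parameters. Surface lesions must
be called PSM (sensitivity ≥ 0.9 asserted), lesions 3 mm or deeper NSM
(specificity ≥ 0.8), the sub-0.1 mm CLOSE band is tallied separately
(those views *are* called PSM — the same near-margin behaviour reported
clinically as "false positives" with tumour < 0.1 mm from ink), and the
filtered/unfiltered contrast ratio must fall strictly with depth, the
physical signature $e^{-(\mu_1-\mu_2)d}$ the rule exploits.

**Protocol optimisation.** The clinical protocol scan (binning 2/4/8 at
150 s; exposure 30/60/150/300 s at 8×8, shortpass filter) is reproduced
on a deliberately photon-starved phantom: benign radiance 5 p/s/cm²/sr,
which puts the background *below the read-noise floor* at the weak end
(30 s, 2×2). There the zero-clamped background subtraction inflates the
measured background mean and biases TBR low; binning and exposure lift
the signal above the noise floor and recover the true contrast. This is
the package's mechanistic account of why coarser binning and longer
exposures improved TBR clinically. Two deviations from the default
phantom serve this experiment: the lesion gets a 5 mm lateral σ (clinical
tumours exceed 1.5 cm; a 2 mm lesion is confounded by the σ = 3 px
smoothing, whose *physical* width grows with binning) and the sensor is
enlarged to 512×512 so the background ROI averages many independent
noise patches after smoothing. Across 50 seeded replicates the endpoint
improvements TBR(8×8) ≥ TBR(2×2) and TBR(300 s) ≥ TBR(30 s) hold in
well over 80% of replicates; the full four-point chain orderings hold in
a majority but not overwhelmingly, because the 150→300 s and 4×4→8×8
steps sit near the TBR asymptote where replicate noise dominates —
mirroring the marginal clinical gain from 150 to 300 s.

Problem sizes throughout (256–512 px sensors, 20-study cohorts, 50
replicates, 10⁵ Monte-Carlo particles) are the package's chosen desk
scale: large enough for stable statistics, small enough that the whole
suite runs in about a minute.

## Dosimetry

`maxProcedures()` is `floor(limit / dose)` with a 1 mSv default annual
limit — the unique round ICRP-style limit consistent with both published
extrapolations (62 procedures for the scrub nurse at 0.016 mSv, 200 for
the surgeon at 0.005 mSv); classified-worker limits (6, 20 mSv) are a
parameter away. Physical dose-rate modelling from activity, distance or
shielding is out of scope.

## Numerical and I/O choices

* Counts are stored as bit-exact 16-bit TIFF; radiance maps as 32-bit
  float TIFF normalized by a scale factor recorded in the JSON sidecar
  (the TIFF writer stores only [0, 1] faithfully).
* Timestamps are ISO-8601 with explicit offsets; elapsed minutes are
  computed exactly, and tests that demand 10⁻¹² round-trips use
  whole-second epochs since POSIXct stores seconds as doubles.
* Study configurations are versioned YAML; unknown keys are errors
  (fail-fast), and a frame without a settings-matched background aborts
  processing with the frame named.
* RNG discipline: every stochastic function takes a seed and restores the
  caller's RNG state; per-frame seeds derive from the master seed through
  a documented `set.seed`/`sample.int` expansion.
* CSV reports round radiances to 4 significant figures and TBRs to one
  decimal, the clinical table convention.

## Known limitations

Depth cannot be *estimated* from the two-band data — the package
classifies near-surface vs deep, it does not invert attenuation (a known
open challenge for CLI). The hotspot detector is a surrogate for visual
reading, not a model of it. Absolute radiances are in arbitrary units
unless the user supplies a device calibration. The beta-spectrum and
stopping-power models are adequate for ratios and trends, not for
absolute dosimetry-grade yields.
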