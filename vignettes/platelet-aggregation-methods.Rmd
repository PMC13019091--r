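---
title: "Methods: single-event platelet aggregation scoring and its validation"
author: "plateletIFC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-event platelet aggregation scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plateletIFC)
```

# The measurement and the score

In imaging flow cytometry of labelled whole blood, every acquired object
is a spatially resolved multi-channel image.  Platelet events are
identified by the constitutive marker CD42b (GPIbα); CD62P (P-selectin)
indicates degranulation.  Each platelet event contains one or more
platelets, and the analysis classifies it as a singlet, doublet, triplet
or multiplet (four or more platelets; the fourth class is open-ended).

The weighted platelet aggregation score of one measurement with class
counts $m_1..m_4$ and $N = \sum_k m_k$ platelet events is

$$\mathrm{WPA} = \left(\frac{1\,m_1 + 2\,m_2 + 3\,m_3 + 4\,m_4}{N} -
1\right)\times 100\%.$$

Subtracting the singlet baseline anchors an all-singlet measurement at
0%; an all-multiplet measurement scores 300%.  Two choices deserve
mention.  The multiplet weight is fixed at 4 regardless of the true
aggregate size, because aggregates of ≥4 platelets are indistinguishable
in the four-class output and the 0–300% range forces the weight.  The
denominator is the number of platelet *events* (complexes), not of
constituent platelets.  Internally the score is computed at full
precision; we report it at 0.1-percentage-point granularity.

# What the synthetic generator emulates

No public single-event data accompany this kind of study, so the
package ships a generator whose defaults encode the study conditions the
analysis assumes:

* **Cohort**: 96 donors, 61 male : 35 female, ages uniform on 18–60
  years (median ≈ 39), measured in technical duplicate at baseline and
  after ADP stimulation, in acquisition batches of 12 donors per date.
* **Composition**: ~10,000 CD42b⁺ events recorded per measurement; a
  configurable fraction (default 0.139) are platelet–erythrocyte
  coincidence images excluded downstream, leaving ≈8610 platelet
  complexes that split on average 8400/200/10/1 into
  singlets/doublets/triplets/multiplets.  The recorded-event total and
  the class-count total differ in the source material without an exact
  reconciliation, which is why the coincidence fraction is exposed as a
  free parameter rather than fixed.
* **ADP response**: the doublet/triplet/multiplet means are multiplied
  by 2.5/7/5 and the singlet mean is depleted by the platelets consumed,
  $2\Delta m_2 + 3\Delta m_3 + 4\Delta m_4$.  With the default means
  this moves the closed-form WPA from ≈2.6% to ≈8%.
* **Dispersion**: donor-level class probabilities follow a Dirichlet
  perturbation with one parameter $\varphi$ (counts are then
  multinomial).  The default $\varphi = 1/460$ was chosen so that the
  cohort standard deviation of baseline WPA is ≈0.8 percentage points.
  At $\varphi = 0$ the generator is fully deterministic: counts are the
  largest-remainder rounding of the configured means, so closed-form
  expectations propagate exactly through the pipeline (several tests
  rely on this).
* **Fluorescence**: per-event CD42b and CD62P MFIs are log-normal,
  scaled by the number of platelets in the event, with a shared
  donor-level log-scale random effect; ADP adds a location shift to
  CD62P only.  Erythrocyte CD42b autofluorescence sits orders of
  magnitude below the platelet signal.  An optional linear attenuation
  of CD62P with aggregate size (epitope masking in basal aggregates) is
  available but disabled by default, since its scaling is not
  established.
* **Whole blood**: platelet events are ~1% of all objects; the rest are
  CD42b-negative erythrocytes, which is what conditional gating removes
  ("99% data reduction").
* **Planted effects** for parameter-recovery experiments: a male-only
  per-year multiplicative increase of the doublet–multiplet means and an
  age-related decline of total platelet events, both centred at age 39
  and disabled by default.

What the generator does **not** emulate: real optics (no proper PSF,
spectral bleed-through or compensation), erythrocyte biconcavity beyond
a dimmed-centre annulus, platelet shape change on activation, or
instrument drift within a day.  Passing tests therefore demonstrate that
the pipeline recovers known structure from data with this statistical
shape — not that the classifier would transfer to real instrument images
without retraining.

## Event images

Events are rendered at 48×48 px and 0.33 µm/px, matching the apparent
platelet size at 60× magnification.  Platelet diameters are uniform on
2–3 µm.  Aggregates are built by attaching each new platelet tangent to
a uniformly chosen existing member with ±10% jitter on the centre
distance; a candidate position that would land on a *non-parent* member
is rejected, since a 2D projection in which one platelet hides another
would make the ground-truth label meaningless.  Each platelet has a
dome-shaped intensity profile (bright centre, positive over the whole
footprint), as a projected cell body rather than a uniform disc — this
also gives tangent aggregates genuine per-platelet intensity peaks.
The forward model is isotropic Gaussian blur (0.7 px; out-of-focus
events use 3× the width), Poisson shot noise on the signal, and additive
Gaussian read noise (SD 2 counts).  Setting `shotNoise = FALSE,
readNoiseSd = 0` yields deterministic noiseless renderings used by the
test oracle.

# Gating

The gate keeps events that are CD42b-positive, in camera focus and — by
default — not co-imaging an erythrocyte, counting each exclusion in that
order so the partition always sums to the input.  The focus score is the
RMS of the discrete brightfield gradient normalised by mean intensity
(zero for uniform images, invariant to intensity rescaling, and
monotonically decreased by Gaussian blur).

Thresholds may be numeric or `"auto"`: an Otsu minimum-within-class
split on log CD42b MFI, and the 5th percentile of focus scores among
CD42b-positive events.  Auto thresholds are meaningful only on a stream
that actually contains both populations; `runPipeline()` therefore
resolves them on a simulated whole-blood calibration stream — the way
gates are placed on the instrument — and applies the resolved numeric
cut-offs to the recorded cohort events.  This also fixes the semantics
of idempotence: re-gating the gate's own output with the *resolved*
configuration retains everything, whereas re-running `"auto"` on an
already-gated (unimodal) stream would re-estimate an arbitrary split.
The resolved thresholds are returned in the `GatingReport`.

# The classifier and its oracle

The network follows the published topology — the input is convolved and
max-pooled twice, flattened, and passed through a fully connected layer
into a 4-way softmax — with sizes chosen minimal for CPU training:
48×48 CD42b input, conv 3×3×16, pool 2×2, conv 3×3×32, pool 2×2,
flatten, FC 64, softmax; cross-entropy loss, Adam (10⁻³), batch 32, 12
epochs.  Only the CD42b channel is used: aggregation is a morphology
question, and feeding the activation marker would leak the stimulation
condition into the class decision.  Raw acquisitions are ~97.5%
singlets, so training batches are resampled to uniform class frequency;
a stratified 20% split is held out and its accuracy stored in the model.
Images are normalised to unit maximum, making classification invariant
to staining intensity.  Weight initialisation and batch order come from
R's RNG under the configured seed, and the C++ core is deterministic, so
training is reproducible.

`oracleClassify()` provides ground truth independently of the network:
the annotation when present (min(nPlatelets, 4)), otherwise — for
noiseless renderings only — peak detection on the CD42b channel (greedy
non-maximum suppression with a minimum separation of 1.15 µm, just under
the smallest platelet diameter).  On zero-noise held-out sets the
trained model is required to agree with the oracle on ≥95% of events.

# Quality control

Stage 1 (replicate concordance): for each donor and condition the two
technical replicates of the WPA must both lie within 70–130% of the
replicate-pair mean.  The band is read as a closed interval — a
replicate at exactly 70% is kept — and any failure removes the donor
entirely.  Donors with a missing replicate are flagged incomplete and
counted separately.  Whether the band should apply per condition or
jointly is not specified in the source; it is applied per condition with
donor-level exclusion on any failure.

Stage 2 (ROUT, Q = 1%): the per-acquisition-date means of baseline WPA
over the stage-1 survivors are tested with the published ROUT procedure
specialised to a constant model with K = 1 parameter: robust centre =
median; RSDR = 68.27th percentile of the absolute residuals × n/(n−K);
residuals tested from most to least extreme against two-tailed t-tails
(df = n−K) at stepwise levels $\alpha_i = Q(n-i+1)/n$, stopping at the
first non-significant residual.  This follows the original publication
of the method rather than any proprietary implementation.  Baseline is
the reference condition (configurable).  Exclusion granularity is
ambiguous in the source ("data from nine additional donors"), so both
modes exist: the default removes every donor on a flagged date;
`"donor"` mode tests per-donor reference means instead.  ROUT needs a
minimum group size (default 3) and, in practice, close to ten values
before a single gross outlier clears the stepwise test — with only three
date means the outlier inflates the RSDR enough to mask itself.

# Statistical layer

Two-group contrasts check normality per group (Shapiro–Wilk, α = 0.05)
and use Welch's t when both pass, otherwise Mann–Whitney (exact null for
combined n ≤ 20 without ties; tie-corrected normal approximation
otherwise — with ties an exact null does not exist, so the approximation
is used even at small n).  Reporting follows the same check: mean ± SD
for normal data, median with a distribution-free order-statistic 95% CI
otherwise.  Age trends are ordinary least squares on raw values with
R² = squared Pearson correlation and a t-based two-sided p (df = n−2),
run on all donors and within sex strata.  Condition response reports
per-class cohort means, ADP/baseline fold changes (undefined — not
infinite — when a baseline mean is zero) and paired contrasts on donor
means.  Deliberately, **no multiple-testing correction** is applied, to
mirror the reporting convention of the study design this reproduces;
treat marginal p-values accordingly.

# Numerical choices and problem sizes

* Largest-remainder apportionment turns expected class means into
  integer counts at zero dispersion; ties go to the largest fractional
  part.
* Otsu's threshold is computed on a 512-bin histogram of log MFIs; the
  default MFI model separates the erythrocyte and platelet modes by
  ≈5.3 log units, comfortably inside the regime where the bimodal split
  beats splitting the majority mode.
* Sub-stream seeds are derived from the master seed by a fixed
  polynomial hash of (donor, condition, replicate) counters, so results
  do not depend on iteration order and a baseline-only simulation
  reproduces the baseline half of a full run exactly.
* Classification ties break toward the smaller class index; probability
  vectors sum to 1 within 10⁻⁶.
* Validation experiments are sized for a single CPU: the reference
  classifier trains on 2000 images; end-to-end recovery uses 20 donors ×
  2 replicates × ~860 platelet complexes per measurement; whole-blood
  gating uses 10⁵ events; null calibration uses 500 measurement-level
  cohorts of 24 donors; slope recovery uses 20 cohorts of 80 donors.

# Known limitations

Cohort-specific results of the original study (exclusion tallies,
specific R² and p-values) depend on raw donor data that are not publicly
available and are explicitly out of scope; the package validates the
*method* on synthetic ground truth instead.  The CNN is trained on the
package's own renderer and will not transfer to real IFC images without
retraining.  Multiplets are capped at weight 4, so the WPA saturates for
large aggregates.  ROUT with very few groups (n < ~8) has little power
against single gross outliers, and the no-correction policy of the
statistical layer is inherited by design.
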