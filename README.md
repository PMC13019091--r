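# plateletIFC

Single-event platelet aggregation analysis for imaging flow cytometry
(IFC) of antibody-labelled whole blood.

Bulk assays such as light transmission aggregometry report one turbidity
number per sample and miss subtle shifts in the aggregate population.
When whole blood stained for CD42b (GPIbα, a constitutive platelet
marker) and CD62P (P-selectin, an activation marker) is run on an imaging
flow cytometer, every acquired object is a small multi-channel image, so
each platelet event can be classified individually as a **singlet**,
**doublet**, **triplet** or **multiplet** (≥4 platelets).  This package
implements that analysis end to end, together with a synthetic-data
generator that emulates the statistical structure of such a study
(donor cohorts with technical duplicates, ADP stimulation, acquisition
batches) so every stage can be validated against known ground truth.

The core score is the **weighted platelet aggregation (WPA)**: with
per-measurement class counts m₁..m₄ and N = m₁+m₂+m₃+m₄ platelet events,

    WPA = ((1·m₁ + 2·m₂ + 3·m₃ + 4·m₄) / N − 1) × 100%

so 0% means exclusively singlets and 300% exclusively multiplets.

The pipeline stages, each usable on its own:

| Stage | Function | What it does |
|---|---|---|
| simulate | `simulateCohort()`, `simulateMeasurement()`, `renderEvent()` | synthetic cohorts, event streams and event images with ground truth |
| gate | `gateEvents()`, `focusScore()` | conditional gating: CD42b⁺, in-focus, no platelet–erythrocyte coincidence |
| classify | `trainClassifier()`, `classifyEvents()`, `oracleClassify()` | 4-class CNN (two conv+pool stages) on the CD42b channel |
| score | `computeWPA()`, `summarizeMeasurement()` | class counts → WPA and measurement MFIs |
| QC | `applyQC()`, `routOutliers()` | 70–130% technical-replicate concordance, then ROUT (Q = 1%) on acquisition-date means |
| stats | `cohortStatistics()`, `contrastGroups()`, `ageRegression()`, `conditionResponse()` | Welch/Mann-Whitney contrasts, age regressions, ADP fold changes |

`runPipeline()` chains them and writes every stage's output (CSV/JSON)
plus a checksum manifest, so runs are reproducible bit for bit from one
master seed.

## Worked example

```r
library(plateletIFC)

## the reported baseline composition: ~8400 singlets, 200 doublets,
## 10 triplets, 0 multiplets per measurement
computeWPA(ClassCounts(8400, 200, 10, 0))
#> [1] 2.555168

## a small synthetic cohort, measured in duplicate at baseline and
## after ADP stimulation
sc <- simulateCohort(cohortConfig(nDonors = 6, seed = 7))
sc
#> SyntheticCohort: 6 donors (4 male, 2 female), 24 measurements
head(measurements(sc)[, c("donor_id", "condition", "replicate",
                          "m1", "m2", "m3", "m4", "true_wpa")], 4)
#>   donor_id condition replicate   m1  m2  m3 m4  true_wpa
#> 1     D001  baseline         1 8327 255  28  0  3.612079
#> 2     D001  baseline         2 8345 228  37  0  3.507549
#> 3     D001       ADP         1 7350 607 221  0 12.827097
#> 4     D001       ADP         2 7355 610 213  0 12.668134

## whole-blood gating: ~99% of objects are CD42b-negative erythrocytes
stream <- simulateWholeBlood(cohortConfig(seed = 7), nEvents = 20000)
gateEvents(stream, gatingConfig())$report
#> GatingReport
#>   input:                 20000
#>   outside CD42b gate:    19800
#>   out of focus:          10
#>   coincidence excluded:  27
#>   retained:              163 (99.2% excluded)
```

A baseline measurement therefore scores a WPA near 2.6%, and ADP
stimulation (doublet/triplet/multiplet means × 2.5/7/5, singlets
depleted by the platelets consumed) raises it to roughly 8–9%.

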