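# myocap3d

Three-dimensional morphometry of the skeletal muscle capillary network,
serial-section muscle fibre typing, and the cohort-level statistics that
go with them — validated end to end on synthetic phantoms with exactly
known ground truth.

## Who this is for

Quantifying muscle capillarisation from confocal z-stacks of thick
sections requires a chain of image-analysis steps — segmentation,
topology-preserving skeletonisation, vectorisation, axial (z) shrinkage
calibration — before any biology can be measured, and each step can bias
the result. `myocap3d` implements that chain as composable R functions,
computes the standard stereological network parameters on the resulting
vector graph, and, because suitable public 3D capillary image data do
not exist, ships phantom generators that provide exact vector ground
truth for every parameter so the whole pipeline can be audited.

## What it measures

For a capillary centreline graph in µm:

| parameter | definition | units (reported) |
|---|---|---|
| LVm | centreline length / tissue volume | µm⁻² × 10⁻⁶ |
| LVf, LSf, LL | length / fibre volume, fibre surface, fibre length | µm⁻² × 10⁻⁴, µm⁻¹ × 10⁻⁴, — |
| Br_dens | degree-≥3 nodes / tissue volume | µm⁻³ × 10⁻⁶ |
| MeanCap | (2/3) · L_V / N_V | µm |
| tortuosity | Σ exterior (turning) angles / total length | rad µm⁻¹ × 10⁻³ |
| anisotropy | eigenvalue ratio of the length-weighted orientation tensor | — |

The 2D arm handles serial-section fibre morphometry: MyHC fibre typing
from the BA-D5 / SC-71 / 6H1 antibody panel (pure types positive on one
antibody, hybrids 1/2a and 2a/2x on two), minimal Feret diameters by
rotating calipers, and the intramyocellular lipid (IMCL) area fraction.
The statistics module fits the matching models: linear mixed-effects
group models with a per-subject random intercept for repeated fields of
view, two-way ANOVA (group × fibre type) with Tukey tests, paired
within-subject muscle comparisons, and HbA1c association models.

## Worked example

Generate one full-scale phantom field (387.5 × 387.5 × 100 µm at
0.76 × 0.76 × 1 µm voxels), push it through the complete image pipeline,
and compare against the exact ground truth:

```r
library(myocap3d)

spec <- phantom_spec(seed = 42)       # control-diaphragm-like setpoints
res  <- run_capillary_field(spec)     # generate -> rasterise -> reconstruct

res$measured
#> <morphometry_result> (reporting units)
#>       LVm tortuosity anisotropy  MeanCap  Br_dens LVf LSf LL
#>  591.5243   25.76707   3.737685 281.9717 1.398543  NA  NA NA

validate_against_truth(res$measured, res$truth)
#>       metric     measured        truth  rel_error  tol pass degenerate
#> 1        LVm 5.915243e-04 5.987500e-04 0.01206789 0.10 TRUE      FALSE
#> 2    Br_dens 1.398543e-06 1.398543e-06 0.00000000 0.15 TRUE      FALSE
#> 3 tortuosity 2.576707e-02 2.631687e-02 0.02089153 0.15 TRUE      FALSE
#> 4    MeanCap 2.819717e+02 2.854160e+02 0.01206789 0.15 TRUE      FALSE
```

Length density and tortuosity land within 1-2% of the exact values and
all 21 branch points are recovered in this field. `run_all()` wraps this
over multiple fields with per-stage seed substreams and writes metrics
CSV, graph JSON/SWC and a checksummed manifest.

A mixed-model group comparison on a simulated cohort (24 + 24 subjects,
5 fields each, injected effect −3):

```r
tab <- simulate_cohort(group_effect = -3, seed = 1)
fit_group_model(tab, muscle = "DIA")
#> <model_result> beta = -1.706  95% CI [-3.595, 0.184]  p = 0.07571
```

(One draw at this noise level; calibration of the test — type-I error
and CI coverage over many replicates — is asserted in the test suite.)

A thin command-line wrapper for the simulate / reconstruct / metrics /
run-all steps lives at `inst/cli/myocap3d.R`.

## Package layout

- `R/phantom.R` — capillary network, fibre territory and serial-section
  generators with exact ground truth
- `R/reconstruct.R` — segmentation, thinning, graph extraction,
  smoothing, 5-µm vectorisation, axial calibration
- `R/capmetrics.R` — the network and fibre-geometry parameters
- `R/fibremorph.R` — fibre typing, minimal Feret, IMCL, section matching
- `R/cohortstats.R` — cohort simulator and statistical models
- `R/pipeline.R`, `R/io.R` — orchestration, TIFF/JSON/SWC round trips
- `vignettes/capillary-morphometry.Rmd` — models, assumptions, design
  decisions and limitations
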