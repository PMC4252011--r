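# epidArcQA

Mechanical quality assurance of a linac during arc deliveries, from portal
images alone.

During VMAT-style arc treatments, gravity works on every heavy component
mounted on the rotating gantry: the gantry head itself, the two ~36 kg MLC
carriage boxes, and the EPID (the megavoltage flat-panel imager on its
jointed support arm). The resulting sags and flexes are invisible to the
machine's own encoders, yet they displace the treatment field and degrade
any EPID-based dosimetry. `epidArcQA` implements a one-shot test for all of
them: a simple phantom of five 4.8 mm tungsten-carbide ball bearings — four
(a, b, c, d) rigidly attached to the gantry head around an 18 × 18 cm²
MLC-defined field, one (e) fixed at the isocentre — is imaged once per arc,
and a single pass over the image series yields, per gantry angle θ and
relative to the gantry-zero reference:

* **EPID sag** — cross-plane and in-plane displacement of the panel,
  `EPID Sag_X(θ) = [e_X(θ) − A·cos θ] − e_X(0)` (and `B·sin θ` in-plane),
  where the fitted amplitudes A and B remove the periodic signature of a
  ball bearing (or lasers) slightly off the true isocentre;
* **gantry sag** — the mean displacement ⟨a, b, c, d⟩ of the head markers
  minus the EPID sag;
* **ΔSDD** — the change in source-to-detector distance from the
  magnification of the marker-pair separation,
  `ΔSDD(θ) = SDD⁰ · (⟨a_X,c_X⟩−⟨b_X,d_X⟩)(θ) / (…)(0) − SDD⁰`;
* **skewness** Ψ — in-plane rotation of the pattern from the slope change of
  a marker-pair line;
* **tilt** φ — pitch and roll of the panel from *differential* magnification
  between the gun/target and left/right marker pairs;
* **MLC carriage sag** — the distance between the head-marker centroid and
  each 50%-intensity bank edge (per-leaf crossings averaged per bank), which
  exposes the bulk carriage displacement that per-leaf encoders cannot see.

All outputs are in mm at the isocentre plane (ΔSDD at the detector plane)
and degrees, with TG-142 style tolerance verdicts (2 mm EPID, 1 mm gantry,
5 mm SDD, 1 mm MLC). A forward simulator renders complete synthetic arc
acquisitions — DICOM RT Image files with projected ball-bearing shadows,
MLC aperture, penumbra and noise — under a parametric machine-deformation
model, providing exact ground truth for validation.

## Worked example

Simulate a 91-image cine arc of a machine with typical clinical deformation
amplitudes, write it as DICOM files, and analyse it back:

```r
library(epidArcQA)

model <- defaultMachineModel()          # 1 mm in-plane EPID sag, 0.7 mm gantry
sim   <- simulateArc(model, AcquisitionPlan("cine"), dir = "fixtures/rep1")

series  <- loadArcSeries(sim$files)
metrics <- analyzeArcSeries(series)
metrics
#> ArcMetrics: 91 angles (CW, collimator 0 deg, replicate 1)
#>   ranges (max-min):
#>   epid_sag_x   epid_sag_y gantry_sag_x gantry_sag_y    delta_sdd     skew_deg
#>        0.172        1.001        0.421        0.701        1.697        0.151
#>   tilt_x_deg   tilt_y_deg    mlc_sag_L    mlc_sag_R    mlc_sag_G    mlc_sag_T
#>        0.075        0.148        0.820        0.683        0.344        0.322
#> MisalignmentFit: A = 0.801 mm (lateral), B = -0.500 mm (vertical), residual RMS 0.433 mm
```

The recovered ranges reproduce the injected machine (in-plane EPID sag
1.00 mm, gantry sag 0.70 mm, ΔSDD 1.70 mm, skew 0.15°, carriage sags
0.82/0.68/0.34/0.32 mm), and the misalignment fit returns the 0.8 / −0.5 mm
setup offset of ball bearing e. Tolerance verdicts:

```r
verdicts(summaryReport(metrics))
#>          metric quantity      value threshold    margin pass
#> 2    epid_sag_y  max_abs 1.00071830         2 0.9992817 TRUE
#> 4  gantry_sag_y  max_abs 0.69996324         1 0.3000368 TRUE
#> 5     delta_sdd  max_abs 1.69689918         5 3.3031008 TRUE
#> 6     mlc_sag_L    range 0.82038982         1 0.1796102 TRUE
#> ...
```

A detector drifting 8.65 mm along the beam axis at SDD 150 cm magnifies the
image and, by the inverse-square law, perturbs absolute EPID dosimetry:

```r
round(magnificationImpact(8.65, 1500), 2)
#> magnification_pct   dose_change_pct
#>              0.58              1.15
```

A shell front end (`inst/scripts/epidarcqa`) wraps the same pipeline as
`simulate`, `analyze` and `compare` subcommands with YAML configuration
(examples under `inst/extdata/`).

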