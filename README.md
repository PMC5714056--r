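# ctmar

Metal implants corrupt CT images through two mechanisms: beam hardening
(the polychromatic beam's mean energy rises along its path, mostly relevant
for low-Z metals such as titanium) and photon starvation (detector bins
behind dense, high-Z metal such as Cerrobend receive essentially no
photons, so their log-normalized projections are unusable). The resulting
streaks distort the Hounsfield units (HU) that radiotherapy dose engines
convert to electron density, so plans computed on corrupted images carry
dose errors.

`ctmar` is a desk-scale, fully synthetic re-creation of a classic phantom
experiment quantifying how much a projection-domain metal artifact
reduction (MAR) algorithm improves dose accuracy. It provides, as tested R
code:

- a digital cylindrical tissue-equivalent phantom (33 cm solid water, a
  ring of tissue surrogates) whose two experimental slots hold 1 cm
  titanium, 3 cm Cerrobend, or 3 cm solid water inserts;
- a polychromatic 140 kVp parallel-beam CT simulator with Poisson photon
  noise and ramp-filtered back projection onto the clamped scanner range
  `[-1024, 3071]` HU, producing realistic beam-hardening and
  photon-starvation artifacts;
- a two-stage MAR algorithm: projection physics correction
  (`p_poly(t_water, t_metal)` lookup inversion for every ray crossing the
  segmented metal) plus iterative regularized completion of the starved
  projections under sinogram smoothness and mass-conservation
  (0th-moment consistency) constraints, followed by image-space metal
  reinsertion;
- ground-truth construction by software substitution of the metal HU into
  the metal-free acquisition;
- HU-to-electron-density calibration, a kerma-approximation primary photon
  dose engine (with a Monte Carlo cross-check mode), metal-avoiding beam
  selection and five-beam fluence optimization delivering 10 Gy to
  cylindrical PTVs;
- evaluation: voxelwise difference statistics, cumulative DVHs,
  `D95/D98/D100`, the relative accuracy error
  `Acc_x = |D_x − D_x^GT| / D_x^GT × 100`, Wilcoxon–Mann–Whitney tests,
  and a machine-readable study report.

## Worked example

```r
library(ctmar)

mats <- load_materials()
tab  <- load_attenuation_table()
spec <- load_spectrum()

effective_energy(spec, tab)               # 64.9 keV
linear_attenuation(mats$water, 65, tab)   # 0.1995 / cm
electron_density(mats$titanium)           # 3.759 (relative to water)

# high-Z (Cerrobend) experiment at desk scale
cfg <- run_config(configurations = 2, n = 128, spacing_mm = 3,
                  n_views = 180, seed = 1)
run <- run_study(cfg)
acc <- report_acc_table(run$report)
subset(acc, metric == "Acc100")
```

prints the minimum-dose accuracy errors of the three PTV plans,
uncorrected versus MAR-corrected (percent, relative to the ground-truth
plan):

```
 configuration  ptv     dataset metric acc_percent
         highZ PTV1 uncorrected Acc100        1.50
         highZ PTV1   corrected Acc100        0.09
         highZ PTV2 uncorrected Acc100        1.54
         highZ PTV2   corrected Acc100        0.16
         highZ PTV3 uncorrected Acc100        2.79
         highZ PTV3   corrected Acc100        0.60
```

and the image-domain summary (`run$report$image$highZ`) shows the
uncorrected-vs-ground-truth difference of 67 ± 580 HU collapsing to
−2 ± 47 HU after correction — the correction restores both image quality
and the density information the dose engine consumes. PTV3, whose target
contains the metal itself, is the hardest case: its beams necessarily
cross the insert.

The methods vignette (`vignettes/mar-dosimetry.Rmd`) documents the models,
parameter choices, and what the synthetic phantom does and does not
emulate.

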