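# impulsed

Time-dependent diffusion MRI microstructure mapping for combined PGSE +
OGSE breast protocols.

## The problem

Conventional diffusion-weighted MRI reduces tissue water mobility to one
apparent diffusion coefficient (ADC) at a single, long diffusion time. In
cellular tissue the ADC depends on the diffusion time: oscillating gradient
spin echo (OGSE) sequences probe short times (here 10 ms at 25 Hz and 5 ms
at 50 Hz, as `1/(4f)`), while the pulsed gradient spin echo (PGSE) probes a
long time (78.4 ms, as `Δ − δ/3`). Fitting both jointly with the IMPULSED
two-compartment model,

    S(b; f) = ν_in · S_in(b; f, d, D_in) + (1 − ν_in) · exp(−b · D_ex)

separates cell diameter `d` (5–50 µm), intracellular volume fraction
`ν_in` (0–1) and extracellular diffusivity `D_ex` (0–3 µm²/ms); `D_in` is
fixed (default 1.56 µm²/ms). `S_in` is the Gaussian-phase-approximation
signal for impermeable spheres, built from the sphere eigen-expansion
(`B_n = 2R²/(α_n²(α_n² − 2))`, `λ_n = α_n² D_in/R²`) with closed forms for
rectangular and cosine lobes, validated against numerical quadrature and a
seeded Monte Carlo random-walk engine. Cellularity is `ν_in/d × 100`,
computed voxelwise. The statistics layer reproduces the clinical analysis:
Welch t tests, ROC/AUC with DeLong confidence intervals and Youden
cutoffs, paired DeLong AUC comparisons, combined logistic models, ICC(A,1)
inter-reader agreement, and immunohistochemical subgroup tests.

Because no patient images are distributed, the package ships a synthetic
cohort generator whose defaults are the published group distributions
(malignant: d = 17.26 ± 2.88 µm, ν_in = 0.38 ± 0.10, D_ex = 1.88 ± 0.25,
n = 27; benign: 24.13 ± 4.54, 0.24 ± 0.10, 2.24 ± 0.17, n = 18), rendered
as ellipsoidal lesions with Rician noise (default SNR 25) under the
published three-sequence protocol.

## Worked example

The `analysis/` scripts run the whole study on a simulated cohort:

```sh
Rscript analysis/01_simulate_cohort.R   # draw 45 lesions, render phantom
Rscript analysis/02_fit_maps.R          # voxelwise IMPULSED + ADC maps
Rscript analysis/03_roi_summaries.R     # two-reader ROIs, ICC
Rscript analysis/04_group_stats.R       # t tests, ROC, models, IHC
```

On the default seed this prints (abridged):

```
simulated 45 lesions (27 malignant, 18 benign), 1755 lesion voxels at SNR 25
fit_volume: 1755 voxels, 1755 converged (100.0%)
group comparison (malignant vs benign):
    parameter      malignant         benign     t  p_value
1           d 19.90 +/- 4.46 25.20 +/- 6.21 -3.12 4.14e-03
2        v_in  0.43 +/- 0.12  0.27 +/- 0.10  4.92 1.53e-05
4 cellularity  2.25 +/- 0.73  1.12 +/- 0.45  6.41 9.35e-08
5  adc_ogse25  1.33 +/- 0.23  1.81 +/- 0.20 -7.65 2.44e-09
diagnostic performance:
              parameter   auc ci_low ci_high cutoff sensitivity specificity
4           cellularity 0.893  0.796   0.990  1.590       0.852       0.889
5            adc_ogse25 0.940  0.870   1.000  1.546       0.889       0.889
8 model1_microstructure 0.949  0.876   1.000     NA       0.963       0.889
9   model2_cell_d_adc25 0.942  0.878   1.000     NA       0.815       1.000
```

Reading it: malignant lesions show smaller fitted cell diameters, higher
intracellular fractions and cellularity, and lower diffusivities/ADCs than
benign ones (all p < 0.005); cellularity and the 25 Hz ADC are strong
single discriminators, and combining parameters in a logistic model pushes
the in-sample AUC still higher — the qualitative structure of the clinical
result, recovered from simulation. Tables land in `results/`
(`group_comparison.tsv`, `roc_performance.tsv`, `inter_reader_icc.tsv`,
`delong_pairwise.tsv`, `ihc_subgroups.tsv`); single-seed numbers wobble at
n = 45, which is why the reproduction script below averages over seeds.

Programmatic use mirrors the scripts:

```r
library(impulsed)
prot   <- breast_protocol()
cohort <- draw_cohort(seed = 1)
recs   <- run_cohort_pipeline(cohort, prot, snr = 25, seed = 1)
roc_analysis(recs$cellularity, recs$group, positive = "malignant")
```

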