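# rhythmpencil

Detection and differential analysis of superimposed 12-hour (ultradian) and
24-hour (circadian) rhythms in dense gene-expression time courses and
indirect-calorimetry records.

Liver transcriptomes sampled every 2 h for 48 h contain, per gene, several
superimposed oscillations. This package decomposes each uniformly sampled
series into a constant level plus up to *M* exponentially damped cosines

y(t) = c₀ + Σᵢ Aᵢ·exp(bᵢ·t)·cos(2π·t/Tᵢ + θᵢ) + ε(t)

with the matrix-pencil (eigenvalue/pencil) method: poles of the sum of
complex exponentials are recovered from the SVD-truncated pencil of shifted
Hankel matrices, residues from a Vandermonde least-squares fit, giving each
component's period, amplitude, phase and decay with no period
pre-assignment. Genes are classified by the period of their dominant
component (10–14 h → 12-h class, 20–28 h → 24-h class); a nonparametric
umbrella-ordering rank test for rhythms of prespecified period and
arbitrary waveform (exact permutation moments, exact small-sample
enumeration, BH correction across genes) provides an independent check;
paired control/knockout cohorts are compared gene by gene to call
**abolished** versus **sustained** 12-h rhythms; and group-mean respiratory
exchange ratio (RER = VCO2/VO2) traces are decomposed into their 12-h and
24-h band content. A seeded synthetic-data generator with known oscillatory
ground truth backs every stage's validation.

Intended users: chronobiologists and computational biologists analysing
dense circadian/ultradian designs (2-h sampling, few replicates) who need
unbiased multi-component rhythm decomposition with a tested, reproducible
implementation.

## Worked example

The `analysis/` directory is a numbered workflow over the package. It
simulates a paired cohort (2000 genes, 2-h × 48-h grid, two replicates,
noise CV 0.1, 88.55% of 12-h genes abolished in the knockout) plus 4 + 4
calorimetry animals, then preprocesses, decomposes, classifies, tests and
compares:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_decompose_classify.R
Rscript analysis/04_differential.R
Rscript analysis/05_rer.R
```

Output from a complete run:

```
simulated 2000 genes x 48 samples; 400 twelve_h genes, 354 abolished in knockout
control: 2000 of 2000 genes kept; size factors in [0.991, 1.008]
control classes: arrhythmic=996, other=5, twelve_h=400, twentyfour_h=599
knockout classes: arrhythmic=999, other=9, twelve_h=47, twentyfour_h=945
umbrella p < 0.005: 411 significant; 400 of 400 pencil 12-h calls confirmed (100.00%)
400 control 12-h genes: 354 abolished (88.50%), 46 sustained (11.50%)
truth check: 354 of 354 abolished calls are truly abolished (100.00%)
12-h band amplitude ratio KO/WT = 0.000; 24-h ratio = 1.020
```

Reading these numbers: all 400 simulated 12-h genes are recovered by the
pencil classification and confirmed by the independent umbrella test; the
estimated abolished fraction (88.50%) matches the simulated truth (354/400
= 88.5%); and in the calorimetry comparison the knockout group retains no
12-h RER oscillation (band amplitude ratio 0) while its 24-h oscillation is
unchanged within 2%. Tables for every stage land in `results/`.

Programmatic use mirrors the scripts:

```r
library(rhythmpencil)
grid <- sampling_grid()                      # CT0..CT46, step 2 h
coh  <- generate_cohort(cohort_spec(n_genes = 500, seed = 1))
mat  <- filter_zero_genes(coh$matrix)
norm <- normalize_matrix(mat, size_factors(mat))
avg  <- average_replicates(norm, grid)
d    <- pencil_decompose(avg[1, ], grid)
print(d)
classify_gene(d)$label
umbrella_test(norm[1, ], rep(grid_times(grid), 2), target_period_h = 12)$p_value
```

`run_pipeline(config)` wires the same stages behind one seeded, serialized
configuration (list or YAML/JSON file) and writes versioned outputs plus a
machine-readable summary.

## Method details

The methods vignette (`vignettes/rhythm-decomposition.Rmd`) documents the
signal model, the pencil parameters and their defaults, the oscillation
filter, the umbrella test's statistic and calibration, the
abolished/sustained criterion, the RER pipeline, what the synthetic
generator does and does not emulate, and known limitations.
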