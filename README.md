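# supercell

Phenotype classification from multiparameter single-cell data by
**supercell statistics**: average random groups of N cells, classify the
averages with a linear max-margin boundary, rank measurements by the
boundary's normal components, and diagnose held-out patients by a
leave-one-patient-out jackknife with an abstention band.

## Who this is for

Anyone with per-sample tables of cells × continuous measurements — flow
cytometry panels, automated image morphometry, single-cell expression —
where two groups of samples (healthy/diseased, disease A/disease B) must be
told apart even though *individual* cells from the two groups overlap
heavily. The package answers the practical questions: how many cells must I
measure, and how many markers, to call a new patient reliably?

## The method in brief

A supercell of size $N$ is the mean of $N$ randomly chosen cells from one
sample; $K$ supercells form that sample's point cloud. By the central limit
theorem the supercell marginals narrow by $\sim 1/\sqrt{N}$, so overlapping
single-cell class distributions become separable. For a 1-D mean difference
$\delta$ and cell SD $\sigma$, supercell classification accuracy follows

$$\mathrm{acc}(N) = \Phi\!\left(\frac{\sqrt{N}\,\delta}{2\sigma}\right),$$

rising from $\Phi(\delta/2\sigma)$ near chance to 1. Supercells are
classified with a linear soft-margin SVM (the max-margin perceptron on
separable input); the components of the unit normal in z-scored space — the
*perceptron amplitudes* — rank measurements from most to least informative.
Sweeping $N$ against the number of top-ranked measurements $M$
(`accuracy_grid()`) maps the cells-vs-markers tradeoff. New patients are
predicted by leave-one-patient-out jackknife: a patient is called for a
class only when at least a threshold fraction $\theta$ (default 95%) of
their supercell cloud lands on that class's side; otherwise they are
left unclassified.

## Worked example

```r
library(supercell)

spec <- synthetic_spec(
  n_patients_per_class = c(5, 5), cells_per_patient = 2000,
  n_measurements = 6, class_shift = c(0.8, 0.5, 0.3, 0, 0, 0),
  patient_effect_sd = 0.15, class_names = c("healthy", "diseased"), seed = 42)
co <- generate_cohort(spec)
co
#> <cohort> 10 samples (5 healthy / 5 diseased), 6 measurements, 20000 cells total

cfg <- supercell_config(size_n = 50, count_k = 100, seed = 42)
scs <- lapply(co$samples, build_supercells, config = cfg)
x <- do.call(rbind, lapply(scs, `[[`, "values"))
y <- rep(vapply(scs, `[[`, character(1), "class_label"), each = 100)

fit <- train_linear(x, y, "healthy")
rank_measurements(fit)
#> <feature_ranking>
#>   rank measurement   amplitude abs_amplitude
#> 1    1          m2  0.81043545    0.81043545
#> 2    2          m1  0.56824123    0.56824123
#> 3    3          m3  0.09264636    0.09264636
#> 4    4          m4 -0.07991936    0.07991936
#> 5    5          m6  0.07061689    0.07061689
#> 6    6          m5  0.01841421    0.01841421

jackknife_predict(co, jackknife_config(cfg, m_values = c(1, 2, 3, 6)))
#> <jackknife_summary> 10 patients, theta = 0.95 (per_fold ranking)
#>  m percent_correct percent_unclassified percent_incorrect
#>  1              80                   20                 0
#>  2             100                    0                 0
#>  3             100                    0                 0
#>  6             100                    0                 0
```

Reading the output: the three measurements that carry the simulated class
difference (`m1`–`m3`) get the largest absolute amplitudes, the pure-noise
measurements sit near zero, and a positive sign means the measurement is
higher in the `healthy` class. (With a 10-patient cohort the max-margin
direction is set by the closest patient clouds, so the realized amplitude
order of `m1`/`m2` can differ from the population shift — here the fitted
boundary leans on `m2`.) The jackknife shows one top-ranked measurement
leaves 2 of 10 patients with straddling clouds (abstentions, never forced
calls); two measurements predict all 10 correctly. The CLT narrowing behind
all of this:

```r
width_ratio(co$samples[[1]], "m1", supercell_config(30, 5000, seed = 1))
#> [1] 0.183   # ~ 1/sqrt(30)
```

## Command line

A thin CLI wraps the same functions for scripted runs:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "supercell_cli.R", package = "supercell"))')" \
    jackknife --input cohort.csv --n 500 --k 100 --theta 0.95 --out results/
```

Commands: `simulate`, `gate`, `supercell`, `train`, `rank`, `grid`,
`jackknife`, `sweep`. Each run writes tidy CSV results plus a
`manifest.json` echoing command, options and seed; identical manifests
reproduce identical outputs.

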