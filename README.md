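# tipigtow

Analysis toolkit for **TIPI-gTOW** experiments: estimating the *lower*
expression limit of a protein by combining the genetic tug-of-war (gTOW)
plasmid assay with TEV-protease-induced protein instability (TIPI), and
comparing the resulting genetic-interaction signs with ODE cell-cycle
simulations.

## The problem and who this is for

Deletion screens reveal which yeast genes are essential, but not how
little of an essential protein still supports growth. In gTOW, a 2μ
plasmid with the weakened `leu2d` marker is driven to >100 copies per
cell under −Leu selection. If that plasmid expresses the TEV protease and
the chromosomal target carries a cleavable degron, rising protease dosage
accelerates target degradation — so the plasmid's copy-number ceiling
stalls exactly where the target hits its lower limit, and the ceiling
*inversely* reports that limit. Measuring the ceiling across a panel of
deletion backgrounds reads out genetic interactions of the target in both
directions in a single experiment.

This package is for groups running or re-analysing such panels: it
implements the qPCR copy-number quantification, the panel statistic, a
model-agnostic ODE cell-cycle engine with an in-silico analogue of the
assay, and a synthetic-data generator with known ground truth.

## The statistics at the core

* Plasmid copies per haploid genome from qPCR crossing points, assuming
  perfect doubling per cycle:
  `copies = 2^(Cp_ref − Cp_marker)`.
* Per-strain relative copy-number change of the TEV plasmid against wild
  type, normalised by the empty-vector copy number to cancel strain-level
  plasmid-maintenance differences:
  `Δrel = (C_T/C_V − wtC_T/wtC_V) / (wtC_T/wtC_V)`.
  Negative ⇒ the target's lower limit rose (candidate synthetic-lethal /
  dosage-rescue partner); positive ⇒ it fell (candidate synthetic-rescue /
  dosage-lethality partner).
* The in-silico counterpart: the largest value `UL` of a degradation-rate
  parameter at which a cell-cycle model still simulates as alive, and
  `(ΔUL − wtUL)/wtUL` between mutant and wild-type models, found by
  bisection (or an explicit grid sweep) over alive/dead simulation
  verdicts.

## Worked example

```r
library(tipigtow)

report <- build_panel_report(cdc20_panel())  # packaged deletion-panel data
head(as.data.frame(report), 5)
#>     strain vector_mean tev_mean ratio relative_change        classification
#>  Wild type       149.7     59.8  0.40              NA                  <NA>
#>       bck2        44.3     25.3  0.57            0.43 lower-limit-decreased
#>       bub2        71.4     48.6  0.68            0.70 lower-limit-decreased
#>       cdh1        66.7     19.6  0.29           -0.26 lower-limit-increased
#>       cin8        53.7     37.1  0.69            0.73 lower-limit-decreased
summary(report)
#> strains: 24 (reference 'Wild type' excluded from calls)
#> lower-limit-increased               neutral lower-limit-decreased
#>                    11                     2                    10
```

(Ratios/changes shown rounded to 2 d.p. as `print()` does.) The `bck2`
row: its TEV/vector ratio 25.3/44.3 ≈ 0.57 exceeds the wild-type ratio
0.40 by 43%, so less Bck2 background means *more* TEV protease was
tolerated — deleting *BCK2* lowered the Cdc20 requirement.

The in-silico assay on the packaged analytic fixture
(`dX/dt = s − kd·X`, alive iff steady state ≥ 2, so the true limit is
`s/2`):

```r
thr <- load_model(system.file("extdata", "models", "threshold.json", package = "tipigtow"))
wt  <- scan_parameter_limit(thr, NULL, "kd", lo = 0.1, hi = 20, tol = 1e-4)
#> limit scan of 'kd' on [0.1, 20] (bisect mode): upper limit 4.99985 after 28 evaluation(s)
mut <- scan_parameter_limit(thr, mutant_spec(overrides = c(s = 5)), "kd",
                            lo = 0.1, hi = 20, tol = 1e-4)
relative_degradation_rate_change(mut, wt)
#> [1] -0.5000074
```

Halving synthesis halves the tolerable degradation rate: a relative
change of −0.5, recovered to the scan tolerance.

Experiment-vs-model sign comparison:

```r
sign_concordance(c(mad2 = 0.86, sic1 = -0.29, swi5 = -0.01),
                 c(mad2 = 0.40, sic1 =  0.30, swi5 = -0.20))
#>  gene experimental_change simulated_change     agreement
#>  mad2                0.86              0.4         agree
#>  sic1               -0.29              0.3      disagree
#>  swi5               -0.01             -0.2 indeterminate
#> agree 1 / disagree 1 / indeterminate 1 (dead band 0.05)
```

See `vignettes/tipi-gtow-analysis.Rmd` for the model file schema, the
viability rules, the scanner's censoring semantics and the synthetic-data
generator.

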