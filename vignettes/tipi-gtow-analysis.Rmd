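---
title: "Estimating lower protein limits with tug-of-war copy numbers and in-silico limit scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lower protein limits with tug-of-war copy numbers and in-silico limit scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipigtow)
```

## The measurement problem

Gene-deletion experiments tell us which proteins a cell can live without,
but not how *little* of an essential protein suffices. The genetic
tug-of-war (gTOW) assay addresses the complementary upper question: a
target gene on a 2μ plasmid carrying the weakened `leu2d` marker is pushed
to more than 100 copies per cell under leucine starvation, unless dosage
toxicity of the target pushes back; the achieved copy number therefore
reports an upper dosage limit. Combining gTOW with TEV-protease-induced
protein instability (TIPI) turns the same trick toward the *lower* limit:
the plasmid instead carries the TEV protease, the chromosomal target is
tagged with a cleavable degron, and rising protease dosage accelerates
target degradation. The plasmid copy number then stalls at the point where
the target protein has been pushed down to the minimal level that still
supports growth, so the TEV-plasmid ceiling inversely reflects the
target's lower expression limit.

This package implements the computational layer of such an experiment:

1. **qPCR quantification** — plasmid copy number per haploid genome from
   crossing points, `copies = 2^(Cp_ref − Cp_marker)`, with replicate
   summaries, Student's *t*-tests and Pearson correlations.
2. **Panel statistics** — the TEV/vector ratio per strain and the relative
   copy-number change against wild type,
   `(C_T/C_V − wtC_T/wtC_V) / (wtC_T/wtC_V)`, with sign classification of
   the implied genetic interaction.
3. **An ODE cell-cycle engine** — declarative models with division events
   and a viability rule, supporting in-silico gene deletions.
4. **A degradation-parameter limit scanner** — the in-silico analogue of
   the tug-of-war: raise a degradation rate until the simulated cell dies.
5. **Sign concordance** — per-gene agreement between experimental and
   simulated relative changes.
6. **A synthetic-data generator** — qPCR replicate tables with known
   ground truth, so the whole pipeline is testable end to end.

## Copy numbers from crossing points

One qPCR cycle doubles the template, so the difference between the
crossing point of the genomic single-copy reference and that of the
plasmid marker is the base-2 logarithm of the plasmid copy number:

```{r}
copy_number_from_cp(cp_marker = 5, cp_reference = 12)   # 2^7
```

Some sources print the exponent in the reverse order
(`Cp_marker − Cp_reference`); taken literally that inverts the physics —
an abundant template crosses the threshold *earlier*, so its Cp is
*smaller* — and would put high-copy plasmids at fractions of a copy. The
package computes the physically oriented difference by default and keeps
`exponent_order = "marker-reference"` for literal comparison. PCR
efficiency is fixed at exact doubling; efficiency calibration from
dilution series is out of scope.

Replicate summaries use the sample (n−1) standard deviation, the usual
convention for a handful of independent measurements:

```{r}
summarize_replicates(c(98, 120, 87, 103))
```

## The panel statistic

Vector copy numbers vary considerably between deletion strains (plasmid
replication and partitioning are themselves genotype-dependent, and the
two copy numbers correlate strongly across strains — on the packaged
panel, r ≈ 0.70), so the TEV copy number is never compared directly.
Instead each strain's TEV/vector ratio is compared with the wild-type
ratio:

```{r}
panel <- cdc20_panel()        # packaged deletion-panel summary
report <- build_panel_report(panel)
head(as.data.frame(report), 5)
summary(report)
```

A negative relative change means the TEV ceiling dropped: less protease
was tolerated, so the target's lower limit rose in that background — the
deleted gene is a candidate synthetic-lethal or dosage-rescue partner. A
positive change marks the opposite (synthetic-rescue / dosage-lethality)
direction.

Classification uses a dead band of ±0.05 by default rather than the bare
sign: changes of a percent or two (e.g. −0.01) are well within replicate
noise, and a visual sign call would over-interpret them. The band is a
package choice, configurable per call.

Two numerical caveats are inherent to working from a published summary
table rounded to one decimal: recomputing the 2-d.p. ratio and change
columns from the rounded means reproduces most cells exactly, but a few
(cdh1, clb1, mbp1, sic1 changes; the mih1 ratio) land one unit off in the
last digit because the original table was rounded from unrounded
replicate means. All recomputed cells agree within ±0.015, which is the
tolerance the tests assert; the affected rows are asserted at their
recomputed values.

An optional `delta_method_se` column propagates replicate SDs into a
first-order standard error of the ratio; it is a diagnostic added by this
package, not part of the original statistic.

## The simulation engine

Models are declarative JSON: species with initial values, parameters,
one rate expression per species in a restricted arithmetic grammar
(`+ − * / ^`, `min`, `max`, `exp`, `log`, `sqrt`, `abs`, and
`hill(x, k, n)`), an optional exponentially growing mass variable,
events fired at directional zero crossings of trigger expressions, a
viability rule, and a `gene_map` naming each gene's synthesis parameters
and product species. The restricted grammar means a model file can never
execute arbitrary code; every unresolved symbol is reported with its
location, all offences at once.

In-silico deletion zeroes the gene's synthesis parameters and its
products' initial values, keeping the state dimension fixed across
mutants:

```{r}
osc <- load_model(system.file("extdata", "models", "oscillator.json",
                              package = "tipigtow"))
osc
sim <- simulate_model(osc)
sim
head(diff(sim$division_times))
```

Integration uses `deSolve::lsoda` (stiff-capable, with dense root
localization for the event triggers) at `rtol = 1e-8`, `atol = 1e-10` by
default; halving the tolerances moves division times by far less than
0.1% on the packaged fixtures, and trajectories are bit-reproducible for
fixed settings. Event direction is decided from the sign of the trigger's
time derivative at the root, so a mass-halving division event fires only
on the downward crossing of the cycle regulator.

**Viability.** Published cell-cycle models differ in how they flag a
"dead" simulation, and the rule is part of the model, not of the engine:
the `viability` section either demands at least N division events within
a horizon T with cell mass bounded by M (growth arrest or unbounded mass
⇒ dead), or gives an explicit predicate on the final state. The packaged
oscillator uses N = 3, T = 500 time units, M = 50; the mass bound makes
the alive/dead boundary crisp, because once divisions stop the
exponentially growing mass crosses M quickly.

**Fixtures.** Two fully self-contained models ship with the package. The
*threshold* fixture (one species, `dX/dt = s − kd·X`, alive iff the
steady state `s/kd ≥ 2`) has the closed-form limit `kd_UL = s/2`, which
anchors the scanner tests analytically. The *oscillator* fixture is a
three-species Goodwin-type negative-feedback loop (Hill coefficient 10)
plus a mass variable growing at `μ = 0.07` — chosen so the mass doubling
time (~9.9 time units) matches the division period (~9.6), as in a
steadily cycling cell. Neither transcribes any published cell-cycle
model; a transcribed model can be loaded from its own file and carries
its own viability rule.

## Scanning a degradation limit

```{r}
thr <- load_model(system.file("extdata", "models", "threshold.json",
                              package = "tipigtow"))
wt <- scan_parameter_limit(thr, NULL, "kd", lo = 0.1, hi = 20, tol = 1e-4)
wt
mut <- scan_parameter_limit(thr, mutant_spec(overrides = c(s = 5)), "kd",
                            lo = 0.1, hi = 20, tol = 1e-4)
relative_degradation_rate_change(mut, wt)
```

The experimental procedure corresponds to a gradual sweep; under the
(usual) monotone alive→dead structure a bisection finds the same boundary
in far fewer simulations, so bisection is the default, with
`mode = "grid"` retained for fidelity — the two agree to within one grid
step, a property the test suite checks on randomized parameterizations of
both fixtures. Bisection first probes a coarse logarithmic grid; an
alive–dead–alive pattern there triggers a warning and a fall back to the
full grid sweep, since bisection's bracketing assumption fails. Defaults:
relative tolerance 10⁻³, 200 logarithmically spaced grid points (the
experimental step size has no published analogue; this is a package
choice). A model still alive at the scan ceiling yields a *censored*
result — only a lower bound on the limit — and a censored wild type turns
every relative change into a bound, reported with a warning rather than
silently.

`scan_panel()` runs the whole mutant panel, isolating failures: a mutant
already dead at the bracket floor is recorded as "no viable baseline"
without aborting the others.

## Mapping strains to mutants and scoring concordance

Cell-cycle models often lump redundant paralog pairs into single genes.
The packaged mapping rules cover the conventional lumpings (Clb1/Clb2,
Clb5/Clb6, Cln1/Cln2, Cln3/Bck2) and represent Swi6 through the activity
parameters of the SBF and MBF transcription-factor complexes it belongs
to. Whether deleting one member of a lumped pair should remove the lumped
gene entirely or halve its synthesis is genuinely ambiguous — published
practice does not say — so both conventions are supported
(`dose = "full-knockout"` is the default, `"half-dose"` scales synthesis
by 0.5) and the choice is recorded in the result.

`sign_concordance()` then scores, per gene, whether the experimental
relative copy-number change and the simulated relative degradation-rate
change share a sign outside a common dead band (default ±0.05; the
underlying comparison is conventionally made visually, so the band again
guards against over-reading near-zero values). Genes inside the band, or
with censored/missing values, score *indeterminate*; genes present on
only one side are listed but not scored.

```{r}
sign_concordance(c(mad2 = 0.86, sic1 = -0.29, swi5 = -0.01),
                 c(mad2 = 0.40, sic1 = 0.30, swi5 = -0.20))
```

## Synthetic data and what it does (not) validate

The generator samples the observable layer of a panel: true vector copy
numbers per strain from a log-normal spread (median 70, log-SD 0.4,
matching the ~20–150 copy range real panels show), TEV copy numbers as
`vector × reference_ratio × (1 + effect)`, and then qPCR crossing points
with Gaussian noise of SD 0.2 cycles on both the reference and the
marker Cp. Noise lives on the cycle scale because qPCR error is
multiplicative on abundance; 0.2 cycles reproduces the 10–30%
coefficients of variation seen in replicate measurements. Defaults — four
replicates per strain-plasmid, reference Cp 22 — mirror the experimental
design the package is aimed at.

```{r}
pan <- generate_tugofwar_panel(
  reference_ratio = 0.4,
  strain_effects = c(geneA = 0.5, geneB = -0.4),
  cp_noise_sd = 0.2, seed = 1)
build_panel_report(pan$records)
pan$truth
```

Because `cp_marker = cp_reference − log2(copies) + noise`, the noiseless
generator is the exact inverse of the quantification pipeline — a strong
end-to-end identity the tests exploit. Note that the per-replicate
estimator `2^N(log2 c, σ)` is median-unbiased but mean-biased upward by
the log-normal factor `2^(σ²ln2/2)`; at the default noise this is ~2%,
irrelevant for sign calls but worth knowing when averaging few
replicates.

What passing these tests shows: the pipeline recovers known effects of
|effect| ≥ 0.3 with the right sign at realistic noise and n = 4, and its
error shrinks as replication grows. What it does not show: anything about
the tug-of-war biology itself — selection bias, protease toxicity,
plasmid partitioning and condition effects are deliberately not
modelled; the generator validates the arithmetic, not the assay.

## Numerical choices and limitations

* Test and example problem sizes (oscillator horizons of 250–500 time
  units, grids of 18–80 points, 3 replicate panels per RMSE point) are
  chosen to exercise every property at comfortable numerical margins
  while keeping a full run in tens of seconds.
* The scanner assumes viability is monotone in the scanned parameter
  within the bracket; the oscillator fixture is *globally* non-monotone
  (too little degradation also arrests the cycle), so brackets must start
  inside the viable window — the "dead at lo" error makes this explicit.
* Ratios are computed from replicate means; full uncertainty propagation
  into the relative change (beyond the optional delta-method SE) and any
  hypothesis test on the change itself are out of scope.
* SBML import is not provided; models are written in the JSON schema.
* The engine integrates deterministic ODEs only — no stochastic cell
  cycles, no bifurcation analysis beyond the viability scan.
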