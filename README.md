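# gtbiomark

Design and estimation tools for evaluating dichotomous biomarkers with
**group testing** (physical pooling of archived specimens) in
prospective-retrospective clinical studies.

## The problem

After a clinical trial ends, its archived baseline specimens are a natural
resource for biomarker research: outcomes are already known, only the
marker must be measured. When the assay is expensive, measuring everyone
(the *standard design*) may cost more than the information is worth, and
the usual alternative — outcome-stratified *random sampling* (RS) of a
subset for individual assays — discards most specimens. For a biomarker
that indicates the presence of a molecular alteration (e.g. a gene
mutation), a pooled assay answers "does at least one specimen in this pool
carry it?", so a *group-testing* (GT) design can assay two or three times
as many subjects as RS with the same number of assays.

`gtbiomark` is for biostatisticians planning or analyzing such studies. It
provides:

* **Pooling designs** — outcome- (and treatment-) stratified pooling plans
  with greedy fill at a target pool size (`allocate_pools()`,
  `assay_pools()`).
* **Prevalence estimation** — the MLE of stratum marker prevalence `q`
  from pooled binary results. Each pool of size `k` tests positive with
  probability `π(q,k) = Se{1−(1−q)^k} + (1−Sp)(1−q)^k` (sensitivity and
  specificity known; `Se = Sp = 1` is the perfect assay); single pool size
  gives the closed form `q̂ = 1 − {(Se−p̂)/(Se+Sp−1)}^{1/k}`, mixed sizes a
  bounded scalar likelihood maximization (`estimate_prevalence()`).
* **Pool-size selection** — the per-assay Fisher information
  `I_k(q) = π′(q,k)² / [π(1−π)]` and the cost-efficiency-optimal pool size
  (`per_assay_fisher_info()`, `optimal_pool_size()`, `info_crossovers()`).
  For a perfect assay the optimum among sizes 1–4 is 1 above prevalence
  0.67, 2 on 0.48–0.66, 3 on 0.37–0.47, and 4 below 0.37.
* **Effect measures** — Bayes conversion of stratum prevalences plus the
  observed outcome margins into marker-specific response rates, and from
  those the association `g(p1) − g(p0)` (log odds ratio, log risk ratio,
  risk difference) or the treatment-by-marker interaction
  `β_TX = {g(p11)−g(p10)} − {g(p01)−g(p00)}`, with delta-method or
  bootstrap standard errors (`estimate_from_pools()`,
  `estimate_standard()`).
* **Design comparison** — a Monte-Carlo engine reporting each design's
  relative efficiency `RE = Var_standard/Var_design` and relative
  cost-efficiency `RCE = RE × assays_standard/assays_design`, with
  jackknife Monte-Carlo uncertainty (`run_designs()`, `replicate_table()`).

See the vignette (`vignettes/group-testing-designs.Rmd`) for the model,
the numerical choices, and the simulator's assumptions.

## Worked example

Simulate a completed 330-patient one-arm trial with a marker of prevalence
0.24, then analyze it with a GT-2 design — 83 assays per outcome stratum,
pools of 2 — instead of 330 individual assays:

```r
library(gtbiomark)
td <- simulate_trial(scenario_spec("prognostic", n = 330, prevalence = 0.24,
                                   response_probs = c(p1 = 0.55, p0 = 0.45),
                                   reps = 1, seed = 1), seed = 2026)
td
#> Trial data: 330 subjects, prognostic mode
#> y=1 y=0
#> 166 164

plan  <- allocate_pools(td, budget = 83, pool_size = 2, seed = 3)
batch <- assay_pools(plan, td)          # perfect assay by default
estimate_prevalence(batch[batch$stratum_outcome == 1, ])
#> Pooled-assay prevalence MLE: q_hat = 0.2475 (SE 0.0361)
#> Assays: 83; pool sizes: 83 x size 2

estimate_from_pools(td, batch, link = "logit")
#> log-OR: 0.5538 (SE 0.2959, delta method; 165 assays)

estimate_standard(td, "logit")          # all 330 subjects assayed
#> log-OR: 0.7265 (SE 0.2787, delta method; 330 assays)
```

The pooled design recovers the responder-stratum prevalence (truth ≈ 0.28
under this scenario's parameterization) and estimates the log odds ratio
with a standard error only ~6% larger than the standard design's — using
half the assays. `run_designs()` turns this anecdote into a calibrated
comparison across thousands of replicates, and

```r
optimal_pool_size(0.24, 4)
#> [1] 4
```

says that at prevalence 0.24 even larger pools would be justified on
information-per-assay grounds.

## Command line

A thin CLI over the same functions ships with the package:

```sh
GTB=$(Rscript -e 'cat(system.file("cli/gtbiomark.R", package = "gtbiomark"))')
Rscript $GTB poolsize --prevalence 0.24 --max-pool 4 --out poolsize.tsv
Rscript $GTB fixture  --kind subjects --n 330 --prevalence 0.24 --out subjects.csv --seed 7
Rscript $GTB fixture  --kind pools --subjects subjects.csv --budget 83 --pool-size 2 --out pools.csv --seed 8
Rscript $GTB estimate --outcomes subjects.csv --pools pools.csv --link logit --out est.json
Rscript $GTB simulate --config inst/extdata/synthetic_predictive_scenario.yaml --reps 500 --out comparison.tsv
```

All randomness is governed by `--seed`; data outputs are byte-reproducible.

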