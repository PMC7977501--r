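---
title: "Group testing designs for prognostic and predictive biomarker studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group testing designs for prognostic and predictive biomarker studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtbiomark)
```

## The problem

Prospective-retrospective (P-R) biomarker studies measure a biomarker on
archived baseline specimens from a completed clinical trial. When the assay
is expensive, measuring every subject (the *standard design*) may be
wasteful. Outcome-stratified *random sampling* (RS) assays only a random
subset of responders and non-responders; it saves assays at the cost of
precision. When the biomarker is a binary indicator of a molecular
alteration (a mutation, say), a third option exists: *group testing* (GT),
in which specimens are physically pooled and each pool is assayed once. A
positive pool means at least one member carries the alteration. With the
same number of assays as an RS design, a GT design with pool size $k$
"sees" $k$ times as many subjects, and this package quantifies how much
statistical efficiency that buys.

`gtbiomark` implements the full pipeline: forming stratified pooling plans,
estimating marker prevalence from pooled results by maximum likelihood,
converting those prevalences into clinically interpretable effect measures,
choosing pool sizes by Fisher information, and comparing designs by
simulation.

## Model and estimation

### Strata and sampling

Let $Y \in \{0,1\}$ be the binary trial outcome (1 = response) and
$X \in \{0,1\}$ the marker. For a *prognostic* analysis (one treatment
group) subjects are stratified by outcome; the quantities of interest are
the marker-specific response probabilities $p_x = P(Y=1 \mid X=x)$,
compared through $g(p_1) - g(p_0)$ where $g$ is the logit, log, or
identity link — i.e. the log odds ratio, log risk ratio, or risk
difference. For a *predictive* analysis in a randomized trial with arms
$T \in \{0,1\}$, subjects are stratified by $(T, Y)$ and the target is the
interaction coefficient of the saturated regression
$g\{P(Y=1\mid T,X)\} = \beta_1 + \beta_T T + \beta_X X + \beta_{TX} TX$,
which for any link equals the difference in differences
$\beta_{TX} = \{g(p_{11}) - g(p_{10})\} - \{g(p_{01}) - g(p_{00})\}$ with
$p_{tx} = P(Y=1 \mid T=t, X=x)$.

Pooling is done *within* outcome (and treatment) strata, because the
stratum membership of every subject is known from the completed trial while
the marker is not. What a pooled design estimates directly is therefore the
stratum marker prevalence $q_y = P(X=1 \mid Y=y)$ (or
$q_{ty} = P(X=1 \mid T=t, Y=y)$).

### Prevalence from pooled results

A pool of $k$ specimens from a stratum with prevalence $q$ is truly
positive with probability $1 - (1-q)^k$. With assay sensitivity $Se$ and
specificity $Sp$ (treated as known constants), the probability that the
pooled *test* is positive is

$$\pi(q, k) = Se\,\{1 - (1-q)^k\} + (1 - Sp)\,(1-q)^k .$$

Given pools $j = 1, \dots, m$ of sizes $k_j$ with binary results $z_j$, the
likelihood is $\prod_j \pi(q,k_j)^{z_j}\{1-\pi(q,k_j)\}^{1-z_j}$. When all
pools share one size the MLE has the closed form
$\hat q = 1 - \{(Se - \hat p)/(Se + Sp - 1)\}^{1/k}$ with $\hat p$ the
observed positive fraction, clipped to $[0,1]$; mixed sizes are handled by
bounded scalar maximization of the log-likelihood on
$[10^{-10}, 1-10^{-10}]$ with tolerance $10^{-10}$ (the likelihood is
unimodal in $q$ whenever $Se + Sp > 1$, which the `assay_model` constructor
enforces). With $Se = Sp = 1$ the general formula reduces *exactly* — in
floating point too — to the perfect-assay estimator
$\hat q = 1 - (1-\hat p)^{1/k}$, so there is a single code path.

An estimate of exactly 0 or 1 (e.g. all pools negative) is a *boundary*
estimate: it is returned with a flag and no Wald variance. Downstream
measure estimation refuses boundary strata by default, naming the stratum;
an opt-in `correction` flag instead moves the positive-pool count half a
pool off the boundary. We default to refusal because a silent continuity
correction would bias the Monte-Carlo comparisons below in ways that are
hard to audit.

The variance attached to an interior $\hat q$ is, by default, the inverse
*expected* Fisher information $\{\sum_j I_{k_j}(\hat q)\}^{-1}$ (see next
section); the observed-information alternative (numeric curvature of the
realized log-likelihood) is available via `variance = "observed"`. Expected
information is the default because it is the quantity the analytic
efficiency predictions use, which makes simulation checks of the form
"empirical variance $\approx 1/(m I_k)$" exact statements about the
implementation.

### Choosing the pool size

One pooled test of size $k$ carries expected Fisher information about $q$

$$I_k(q) = \frac{\{\pi'(q,k)\}^2}{\pi(q,k)\{1-\pi(q,k)\}}, \qquad
  \pi'(q,k) = (Se+Sp-1)\,k(1-q)^{k-1},$$

which for $k=1$ (perfect assay) is the binomial information
$1/\{q(1-q)\}$. With a fixed assay budget, the cost-efficiency-optimal pool
size maximizes $I_k(q)$ over $k$. `info_crossovers()` evaluates the curves
on a prevalence grid (default step 0.01 on $[0.01, 0.99]$, argmax ties
broken toward the smaller pool) and locates the continuous crossovers
$I_k = I_{k+1}$ by bracketed root finding. For the perfect assay and
$k \le 4$ the bands are: size 1 optimal from prevalence 0.67 upward, size 2
on 0.48–0.66, size 3 on 0.37–0.47, and size 4 (or more) below 0.37; the
continuous crossovers are $q = 2/3$, $\approx 0.4753$ (root of
$5u^2 + 5u - 4$ in $u = 1-q$), and $\approx 0.3675$ (root of
$7u^3 + 7u^2 + 7u - 9$). Pooling pays off for *rare* markers: with common
markers nearly every pool is positive and carries little information.

```{r poolsize}
info_crossovers(4)
```

### From prevalences to effect measures

The response rate $r = n_1/(n_1+n_0)$ (per arm, in predictive mode) is
known from the full phase-one data, so Bayes' theorem recovers the cell
probabilities from the stratum prevalences:
$w = q_1 r + q_0(1-r)$ is the implied marker prevalence and
$p_1 = q_1 r / w$, $p_0 = (1-q_1) r/(1-w)$. Under the logit link the
measure depends on the prevalences only through the odds-ratio identity
$q_1(1-q_0)/\{q_0(1-q_1)\}$, so the outcome split cancels; the log and
identity links genuinely use $r$.

Standard errors come from first-order propagation through the independent
components — $\hat q$ per stratum (variance from inverse information) and
$\hat r$ per arm (binomial variance $r(1-r)/n_t$) — with gradients by
central differences, or from a nonparametric bootstrap that resamples pools
within stratum (pools are the independent units) and subject outcomes
within arm (`B = 2000` by default, SE = SD of successful replicates).
Whether the response rate should be treated as random is a genuinely open
choice; we include its variance by default, since the phase-one outcomes
are themselves a sample, and provide `r_known = TRUE` for the fixed-margin
sensitivity analysis. On a fully assayed trial with pool size 1 the delta
SE reproduces the textbook standard-design SEs exactly (for the logit link,
$\sqrt{1/a + 1/b + 1/c + 1/d}$), a consequence of the delta method's
invariance to smooth reparameterizations of the saturated multinomial.

## The design simulator

`run_designs()` compares designs on simulated trials. The generator mirrors
the structure of a completed two-arm randomized trial with a dichotomous
endpoint: $X \sim \text{Bernoulli}(q)$ i.i.d., $T \sim \text{Bernoulli}(0.5)$
independent of $X$ (predictive mode), and $Y \mid (T,X)$ Bernoulli with the
scenario's cell probabilities. The default study conditions are shaped like
a 657-patient 1:1 leukemia trial with a marker prevalence of 0.24 and
interior response probabilities; scenario files make every one of these a
visible, editable number. What the generator deliberately does *not*
emulate: covariates, censored or continuous outcomes, within-pool dilution
of the assay signal, and marker misclassification that varies with pool
composition. Conclusions from passing tests are therefore about the
estimation machinery under the stated sampling model, not about assay
chemistry.

Designs are specified as labels: `standard`; `RS-f` (individual assays for
$\approx 1/f$ of subjects); `GT-f-k` (same budget as `RS-f`, pool size $k$,
with `GT-f` shorthand for $k=f$). The total budget is
$\mathrm{round}(n/f)$, split equally over the 2 (prognostic) or 4
(predictive) strata; halves round up. Within a stratum, pools are filled
greedily at the target size from subjects sampled without replacement —
pooling physically consumes distinct specimens — and the final pool shrinks
when the stratum runs short, so the target size is used to the extent
possible; a budget exceeding the stratum size is capped with a recorded
warning rather than an error, because rare-outcome replicates must still
run.

Performance is summarized per measure by the *relative efficiency*
$\mathrm{RE} = \mathrm{Var}_\text{standard}/\mathrm{Var}_\text{design}$ and
the *relative cost-efficiency*
$\mathrm{RCE} = \mathrm{RE} \times (\text{assays}_\text{standard} /
\text{assays}_\text{design})$, information retained per assay. Replicates
in which *any* design fails (a boundary prevalence estimate or an empty
cell) are excluded pairwise and counted, never silently dropped; a failure
rate above 20% triggers a prominent warning. Monte-Carlo uncertainty of RE
and RCE is quantified by a delete-1 jackknife over the paired replicate
estimates, which is what allows principled "design A beats design B beyond
2 SEs" statements in the test suite.

Seeding is layered so comparisons are paired: the master seed generates one
seed per replicate; the trial is drawn from the replicate seed; each
design's allocation and assay noise are seeded from the replicate seed plus
a per-label offset. The standard design's estimate stream is therefore
byte-identical across runs that differ only in the non-standard design
list.

The package's own validation runs use 2,000 replicates at trial sizes 330
(prognostic) and 657 (predictive) with prevalence 0.24 — sizes at which the
qualitative ordering (GT more efficient than assay-matched RS, both usually
cost-efficient against the standard design) is resolved far beyond the
2-jackknife-SE criterion the tests apply, while a full run takes well under
a minute per scenario on one core. Larger replicate counts sharpen the
RE/RCE decimals but not the ordering.

## Numerical and degenerate-input choices

* Likelihood terms use complementary forms of $\pi$ and $1-\pi$
  (`log1p`/`expm1` based) so that prevalences within $10^{-9}$ of 0 or 1 do
  not underflow.
* Grid argmax ties (exact equality of $I_k$ on a grid point) break toward
  the smaller pool size — the cheaper and operationally simpler choice.
* Bayes conversion refuses degenerate implied marker prevalence
  ($w \in \{0,1\}$): the marker is then constant and every measure is
  undefined.
* Empty marker cells in the standard estimator error by default;
  `correction = TRUE` applies the Haldane–Anscombe $+0.5$ to all four
  cells.
* The CSV interfaces accept only 0/1 coding (empty = unknown) to keep
  silent label recoding impossible.

## Known limitations

* Retrospective estimators of log and logit measures carry the usual
  $O(1/m)$ nonlinearity bias, where $m$ is the per-stratum assay count; at
  a few dozen assays per stratum this can become detectable against tight
  Monte-Carlo error bars even though it is negligible on the scale of the
  measure itself.
* Sensitivity and specificity are assumed known and constant; dilution
  effects (sensitivity decreasing with pool size) are out of scope, as are
  Dorfman-style retesting of positive pools, non-binary markers, and
  censored outcomes.
* Wald-type intervals only; no small-sample exact inference.
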