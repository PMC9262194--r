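---
title: "The negative binomial background model behind hicnb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The negative binomial background model behind hicnb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicnb)
```

## The problem

A Hi-C library counts ligation products between pairs of genomic bins. Most
of that signal is background: random collisions whose frequency decays with
genomic distance, modulated by how "visible" each bin is to the assay
(restriction density, GC, mappability, copy number — mostly unobserved).
Calling an interaction significant means asking whether its read count
exceeds what that background would produce. `hicnb` fits the background by
maximum likelihood and scores every stored bin pair against it.

## The model

For a stored pair of bins $(i, j)$ at genomic distance $d_{ij}$ the observed
count is modelled as negative binomial,

$$x_{ij} \sim \mathrm{NB}(\mu_{ij},\, r), \qquad
\mathrm{Var}[x] = \mu + \mu^2/r,$$

with a single dispersion $r$ shared by all pairs of one model. The mean
factorizes into per-bin bias factors and a distance term:

$$\mu_{ij} = \mathrm{softmax}_k\!\left(v_i\, v_j\, f(d_{ij}),\;
\mathrm{base}_e\right).$$

**Bias factors.** $v_i = \max\!\big(s_i^{\,b}\, e^{b_m},\, v_{base}\big)$,
a power law of the bin's effective total read count $s_i$. The hard floor
$v_{base}$ stops sparsely covered bins from producing spuriously small
expectations (and hence spurious calls) without any user-tuned coverage
filter. An exponent $b < 1$ can express saturation from duplicate removal.

**Distance decay.** $f(d) = \mathrm{softmax}_k\!\big(f_v(d),\, f_c\big)$
with $f_v(d) = \exp\!\big(a_3 \ln^3 d + a_2 \ln^2 d + a_1 \ln d + a_0\big)$:
a cubic in log distance, flexible enough to change curvature across scales,
softly floored at a constant $f_c$ that represents distance-independent
background ligation. Trans pairs use $f_c$ directly — far cis and trans
contacts are both dominated by random 3D proximity, so they share the same
constant.

**Soft maximum.** $\mathrm{softmax}_k(\alpha, \beta) =
(\alpha e^{k\alpha} + \beta e^{k\beta})/(e^{k\alpha} + e^{k\beta})$ is used
wherever a floor enters the expectation so the likelihood stays
differentiable; it converges to the hard maximum at rate
$|\alpha-\beta|e^{-k|\alpha-\beta|}$. The bias floor uses a hard maximum
(its subgradient is well defined and the floor is meant to bind exactly).

**P-values.** A pair's significance is the upper tail of its fitted NB,
$P(X \ge x_{ij})$ by default — the inclusive tail is the conservative
convention for discrete tests; `nbTailProb(..., inclusive = FALSE)` gives
the strict tail $P(X > x)$. No multiple-testing correction is applied to
the primary calls (the analysis threshold is a raw P-value, 0.001 by
default); a Benjamini–Hochberg q-value column is emitted for users who want
one.

## Parameters and defaults

| parameter | meaning | units | default |
|---|---|---|---|
| $b, b_m$ | bias power law | — | learned (init $b=1$, median $v=1$) |
| $v_{base}$ | bias floor | — | learned in log space (init 1st percentile) |
| $a_0..a_3$ | decay cubic | on $\ln$ bp | learned (init OLS on stratified means) |
| $f_c$ | background-ligation floor | reads | learned (init mean trans count) |
| $r$ | NB dispersion | — | learned (init method of moments) |
| $k$ | soft-max sharpness | 1/reads | 10, fixed |
| $\mathrm{base}_e$ | expectation floor | reads | 0.5, fixed |

$k$ and $\mathrm{base}_e$ are smoothing hyperparameters, not likelihood
parameters; they are exposed but not optimized. All strictly positive
parameters are optimized as logarithms so positivity can never be violated.
Whether $v_{base}$ should be learned is genuinely open; we learn it by
default because it is a likelihood parameter like any other, and provide
`freezeBiasFloor` for the fixed alternative.

## Fitting

All free parameters are fitted by full-batch ADAM (default step size
$10^{-2}$, moments $0.9/0.999$, $\epsilon = 10^{-8}$) on the analytic
gradient of the NB negative log-likelihood; the dispersion gradient uses
digamma terms. A mini-batch mode (`batchSize`) exists for very large maps
but the default is deterministic given the initialization. A round stops
when every parameter moves less than $10^{-4}$ on its optimization scale,
or at 1000 iterations as an oscillation guard. Because ADAM's
per-coordinate normalization takes comparably sized steps in every
coordinate, the decay cubic is optimized internally on a standardized
log-distance basis $z = (\ln d - m)/s$; on the raw basis the cubic
coefficient multiplies $\ln^3 d \sim 4\times 10^3$ and a single step
destroys the curve. The learning rate decays geometrically
($0.995^t$) so the parameter-change stopping rule is attainable; with a
constant rate ADAM keeps taking $O(\mathrm{lr})$ steps forever.

**Masking rounds.** Real interactions in the training data pull the
background up. Training therefore runs in rounds (default 4, counting the
initial unmasked fit as round 1): fit, score everything, mask the pairs
below the significance threshold (0.001), and for the next round replace
the masked pairs' counts by their expected counts when computing bin totals
— the count they would have shown had they been background — and exclude
them from the objective. The mask is recomputed from scratch each round,
not accumulated, because each refreshed model re-identifies the putative
real interactions. Each new round also recomputes the data-driven
initialization from the refreshed totals rather than warm-starting: in
capture mode the totals can change scale by the class-enrichment factor
between rounds, which is farther than one round of decayed ADAM steps can
travel. The reported model and bin statistics are the ones the final
round's fit actually used, so scoring is self-consistent.

## Capture Hi-C

Capture libraries sequence bait (target) regions more deeply, splitting
pairs into target–target (TT), target–other (TO) and other–other (OO)
classes with different enrichment levels. Each class gets its own full
parameter set, fitted only on its own pairs (a class with fewer than 1000
pairs borrows the nearest class's parameters, with a warning). Bin totals
must not mix scales, so every count is converted to its TT equivalent,
$x^{TT} = x \cdot \mu^{TT}/\mu^{own}$, before totals are accumulated;
masked pairs contribute their converted expectations. The conversion is
linear in $x$ and the identity on TT, and with baits covering every bin
the whole machinery reduces bit-for-bit to the general model. Whether the
dispersion should be shared across classes is not settled; the default is
per-class with a `shareDispersion` switch that pools the per-class
estimates (pair-weighted mean of logs). Enrichment evaluation of capture
calls conventionally considers only bait-interacting (TT and TO) records;
OO calls are still emitted, labelled.

## The simulator, and what it does and does not emulate

`simulateBackground()` is the generative twin of the model: lognormal
per-bin bias multipliers (sd 0.25), the same soft-floored expectation
pipeline, NB draws, and zero-truncation — only pairs with at least one
read are stored, exactly as in the real pipeline, with the dropped
fraction reported. Options add capture structure (a random target set with
a per-end enrichment factor) and `spikeLoops()` redraws chosen pairs at a
fold of their background mean to create ground-truth loops.

Two consequences of this design matter for interpreting tests:

* **The self-consistent bias exponent is 1.** When per-bin multipliers are
  drawn directly, a bin's expected total is proportional to its multiplier
  (for interior bins), so the power law linking bias to totals has exponent
  1 by construction; recovery experiments compare $\hat b$ to 1. An
  exponent below 1 in real data reflects duplicate-removal saturation,
  which only read-level simulation could emulate — out of scope here. A
  recovered $\hat b$ far from 1 would still expose estimator bias, so the
  check is informative.
* **Zero truncation makes shallow libraries only partially identifiable.**
  The fitted model maximizes a plain NB likelihood over pairs with
  $x \ge 1$. Where $\mu$ is well below 1 read, the stored pairs' conditional
  distribution differs from the latent NB, and the fit converges to the
  observable distribution instead: $f_c$ inflates toward the truncated
  mean and the shared dispersion absorbs stratum-dependent truncation. This
  is a property of the method, not of the implementation — on such data the
  fitted parameters achieve a better likelihood than the truth parameters
  do. Parameter-recovery experiments are therefore run at a deep setting
  (`simTruthParameters(depth = 40)`, < 1% of pairs truncated) where the
  latent parameters are identifiable, and decay comparisons are made on
  distance-stratified mean expected counts over the map's actual pairs,
  because only the product $v_i v_j f(d)$ is identified (a constant moves
  freely between bias and decay, and chromosome-end bins have depressed
  totals that the bias-from-totals family cannot represent, which
  contaminates $\hat f$ alone at the far end while pair-level expectations
  stay accurate).

**Calibration on shallow data is approximate.** On the shallow default
fixture (500 bins of 10 kb, ~1e5 simulated pairs, ~35% truncated) the full
4-round pipeline calls about 0.002–0.003 of stored pairs at the 0.001
threshold, versus a truncation-conditioned expectation near 0.001. Two
mechanisms: the shared dispersion is pulled up by the heavily truncated far
strata, leaving near strata with anti-conservative tails; and each masking
round removes the empirical upper tail, nudging the refitted dispersion up
and the threshold count down. The same behaviour — calls a few-fold above
the nominal rate on null data — is intrinsic to iterative-masking callers,
and the package reports it honestly rather than recalibrating.

## Experiment sizes used by the test-suite

Chosen to exercise the statistics well inside a single-core run: the
calibration fixture is the shallow 500-bin/10 kb map; recovery uses ten
700-bin/20 kb deep libraries (~2.4e5 pairs each, so the decay curve can be
evaluated across 20 kb–10 Mb inside one chromosome); the spiked-loop
experiment places 50 loops at 10x background between 40 kb and 2 Mb — the
distance range where chromatin loops live — on a deep map so every spiked
mean is at least 10 reads; capture experiments use 10% target bins at a
10-fold per-end boost, keeping every class above the own-fit threshold.

## Numerical choices

* Tail probabilities go through the survival function
  (`pnbinom(lower.tail = FALSE)`), never $1 - \mathrm{CDF}$, so small
  P-values do not cancel.
* The pmf is evaluated through log-gamma terms; the likelihood kernel
  caches the count-dependent special functions over the unique count
  values (counts repeat massively in sparse maps).
* The cubic's argument is clamped at $e^{500}$ to keep the soft maximum
  total for any finite parameters; overflow in the soft maximum itself is
  prevented by subtracting the larger exponent.
* Distance between cis bins is the midpoint difference,
  $|i - j| \times \mathrm{binsize}$ for equal bins; self pairs are removed
  on input, so $d > 0$ always.
* Midpoint binning assigns a fragment to the bin containing
  $\lfloor(\mathrm{start}+\mathrm{end})/2\rfloor$, half-open, so a midpoint
  on a boundary belongs to the bin starting there.
* Ties in call ordering break on coordinates, making outputs byte-stable.

## Known limitations

* P-values are plug-in tails: they ignore the sampling error of the fitted
  parameters, which makes extreme tails slightly anti-conservative even on
  deep null data.
* The zero-truncation bias described above: on shallow data the model
  describes the observable distribution, and $f_c$, $r$ should be read in
  that light.
* One genome-wide parameter set; no per-chromosome models, no GC or
  mappability covariates (bin totals are assumed to absorb them), no
  matrix balancing — raw counts in, by design.
* The simulator draws independent per-bin biases and has no TAD or
  compartment structure; passing its tests shows the estimator recovers
  its own model family, not that the family captures every feature of
  real chromatin.
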