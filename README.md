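# hicnb — negative binomial background correction for Hi-C and capture Hi-C

Hi-C contact maps are dominated by background: random ligation whose
frequency decays with genomic distance, scaled by how visible each genomic
bin is to the assay. `hicnb` identifies statistically significant chromatin
interactions — candidate enhancer–promoter contacts, structural loops — by
fitting that background with maximum likelihood and scoring every stored
bin pair against it. It is aimed at anyone who has a binned contact map
(HiC-Pro triplet format) and wants calls with read support well above the
local background, plus the enrichment statistics needed to evaluate them
against regulatory annotation.

## The model

The observed count of bins $(i, j)$ at distance $d$ is

$$x_{ij} \sim \mathrm{NB}(\mu_{ij}, r), \qquad
\mu_{ij} = \mathrm{softmax}_k\big(v_i\,v_j\,f(d_{ij}),\ \mathrm{base}_e\big)$$

with per-bin bias factors $v_i = \max(s_i^{\,b} e^{b_m}, v_{base})$ — a
power law of the bin's effective total reads $s_i$ — and a distance term
$f(d) = \mathrm{softmax}_k(e^{a_3\ln^3 d + a_2\ln^2 d + a_1\ln d + a_0},
f_c)$ whose constant floor $f_c$ captures distance-independent background
ligation (trans pairs use $f_c$ directly). Soft maxima keep the likelihood
differentiable; all parameters are fitted by ADAM. Training runs in rounds
(default 4): fit, score, mask pairs with $P < 0.001$, replace their counts
by model expectations in the bin totals, refit — so real interactions do
not inflate the background they are tested against. A pair's P-value is
the NB upper tail $P(X \ge x_{ij})$. Capture Hi-C libraries get three
parameter sets (target–target, target–other, other–other) with counts
converted to the TT scale ($x^{TT} = x\,\mu^{TT}/\mu^{own}$) before bin
totals are formed.

The methods vignette (`vignettes/background-model.Rmd`) derives all of
this, documents defaults and numerical choices, and states what the
bundled simulator does and does not emulate.

## Worked example

Simulate a deep 300-bin library from the model's generative twin, spike
three ground-truth loops at 8x background, and call interactions:

```r
library(hicnb)
sim <- simulateBackground(nBins = 300, binSize = 20000,
                          params = simTruthParameters(depth = 40), seed = 7)
loops <- data.frame(bin1 = c(40, 120, 200), bin2 = c(55, 150, 210),
                    fold = 8)
sp  <- spikeLoops(sim$map, loops, sim$truth, seed = 8)
fit <- fitBackground(sp$map, trainingConfig(rounds = 2), verbose = TRUE)
#> round 1: nll 204700.78 after 120 iters (converged=TRUE), 50 masked
#> round 2: nll 204181.80 after 106 iters (converged=TRUE), 62 masked
modelParameters(fit)
#> BackgroundParameters
#>   bias: v = max(s^0.9955 * e^-10.07, 0.6445)
#>   decay: a0..a3 = 15.47, -0.9862, 0.02147, -0.0006668; trans/far-cis floor f_c = 21.09
#>   dispersion r = 3.898; k = 10; base_e = 0.5
sig <- callSignificant(scoreInteractions(sp$map, fit), 0.001)
head(sig[, c("bin1", "bin2", "distance", "observed", "expected", "pvalue")], 3)
#>   bin1 bin2 distance observed  expected       pvalue
#> 1  120  150   600000      719  76.40124 1.767362e-12
#> 2   40   55   300000     1307 173.90236 9.164966e-10
#> 3  200  210   200000     2652 367.89155 2.337489e-09
```

The three spiked loops come out as the three best calls: observed counts
of 719–2652 reads against fitted background expectations of 76–368, at the
distances where they were planted. The fitted dispersion (3.9) and bias
exponent (1.00) match the simulation truth (4 and 1). `writeCalls()`
exports the records as a tab-delimited file; `regionEnrichment()`,
`pairEnrichment()` and `eqtlPairOverlap()` quantify overlap of the calls
with BED features, feature pairs and SNP–gene pairs.

A thin command-line front end with `run`, `capture`, `simulate` and
`enrich` subcommands is installed at
`system.file("scripts/hicnb", package = "hicnb")`.

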