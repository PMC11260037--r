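---
title: "Mating designs and genomic prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mating designs and genomic prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

matesim is a forward-in-time stochastic simulator for asking one question:
how does the way sires and dams are paired affect the accuracy and bias of
genomic prediction? This vignette documents the model, every tunable that
matters, and the design decisions taken where the problem statement was
genuinely open.

## The simulated world

**Demography.** A base population of 1000 unrelated animals (even sex ratio)
reproduces by random union of gametes for 1000 generations to reach
mutation-drift equilibrium, grows linearly to 10,000 over the next 1000
generations, then declines sharply to 4,000 over 20 generations — the
bottleneck that builds the linkage disequilibrium (LD) the genomic predictor
will exploit. From the bottleneck generation an expansion phase (500 sires,
3,500 dams, 10 generations, five offspring per dam, dam numbers growing
geometrically) produces the material for the recent breeding population:
50 sires and 3,500 dams mated for 10 more generations under one of five
mate-allocation designs. Generations 3–9 of this recent phase form the
reference set (genotyped and phenotyped); generation 10 is the validation
set, whose phenotypes are never shown to the predictor.

**Genome.** One chromosome of 100 cM carries 350/650/950 bi-allelic markers
at exactly equal spacing and 50/150/200 QTL at uniform random positions.
Crossovers follow the Haldane model (Poisson count with mean = map length in
Morgans, no interference); every locus mutates by allele flip at
2.5 × 10⁻⁵ per generation. QTL are deliberately *not* placed on marker
positions: the predictor sees markers only and must rely on marker–QTL LD.

**Trait.** QTL effect magnitudes are gamma(shape 0.4) draws — many small
effects, a few large — with random signs. `scale_trait()` multiplies them by
one constant so that the variance of the true breeding value
(TBV = Σ dosage × effect, purely additive) in the recent-phase founder
cohort equals h²σ²ₚ, with σ²ₚ = 1 and h² ∈ {0.05, 0.30, 0.60}. Phenotypes
add N(0, (1−h²)σ²ₚ) residuals. Anchoring the scaling in the recent founders
puts the nominal heritability exactly where phenotypes are recorded.

## The five mating designs

Each generation, every dam is allocated to exactly one sire and sire usage
is forced near-equal (70 dams per sire at full scale), so the designs differ
*only* in who is paired with whom:

* **random** — dams shuffled and dealt to sires in blocks.
* **assortative (positive/negative)** — sires and dams ranked by EBV;
  positive pairs like ranks with like, negative pairs top sires with bottom
  dams. EBVs are heritability-regressed phenotype deviations
  h²(y − ȳ) (a pedigree-BLUP estimator is available for sensitivity runs);
  ties break by animal id so plans are deterministic.
* **min/max inbreeding** — simulated annealing over balanced allocations
  minimises (or maximises) the mean pedigree kinship of the allocated
  pairs, i.e. the mean expected inbreeding of the next generation.
  Temperature starts at 0.5 and cools by 0.9 per sweep (one proposed
  sire-swap per dam per sweep), Metropolis acceptance exp(−Δ/T).

Pedigree kinship is propagated generation to generation by the tabular
recursion, so each animal's inbreeding coefficient (its parents' kinship) is
recorded and the annealer always sees current kinship. Next-generation
parents are drawn **at random** among offspring: the problem statement fixes
the mating design but not a selection rule, and random replacement ensures
that differences between scenarios are attributable to mate allocation
rather than to selection response (truncation on EBV is available via
`selection = "ebv"`).

## Genomic prediction

Marker effects are estimated by ridge-regression BLUP (SNP-BLUP) on the
pooled reference generations: y = 1μ + Xg + e with X the 0/1/2 dosage
matrix, solving the two-block mixed-model equations

    [ 1'1   1'X        ] [ μ ]   [ 1'y ]
    [ X'1   X'X + Iλ   ] [ g ] = [ X'y ]

by one dense solve (unique for λ > 0; markers fixed in the reference set are
dropped first). Because the simulator knows its true variance components, no
REML step is used: σ²_g = h²σ²ₚ / Σⱼ2pⱼ(1−pⱼ) spreads the genetic variance
over the segregating markers and λ = σ²ₑ/σ²_g. This SNP-BLUP is the exact
dual of GBLUP with a VanRaden-style genomic relationship matrix; the test
suite verifies the equivalence to 10⁻⁸ on random instances. GEBV = Xĝ
(no intercept) for reference and validation animals alike.

**Metrics.** Accuracy is the Pearson correlation r(TBV, GEBV), reported for
the reference pool (A_T) and the validation generation (A_V). Bias is the
OLS slope of TBV on GEBV (unbiased prediction ⇒ slope 1), fitted on
reference and validation animals pooled. LD is r² = D²/(f(A)f(a)f(B)f(b))
counted over phased haplotypes (the simulator knows phase; no phasing
inference), averaged within the standard half-open distance bins
(0–0.05] … (4–5] cM; pairs beyond 5 cM are excluded, and the single-number
LD summary `ld_mean_r2()` is the pair-count-weighted mean over the same
≤ 5 cM pair set pooled across reference generations. Scenario results are
summarised as mean ± SE over replicates (SE = sd/√R, between-replicate, not
bootstrap).

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `length_cM` | 100 | chromosome length (cM) |
| `n_markers` | 350/650/950 | equally spaced markers |
| `n_qtl` | 50/150/200 | uniformly placed QTL |
| gamma shape | 0.4 | QTL effect magnitude distribution (scale 1; irrelevant after rescaling) |
| `h2` | 0.05/0.30/0.60 | narrow-sense heritability |
| `sigma_p2` | 1.0 | phenotypic variance (trait units²) |
| `mutation_rate` | 2.5e-5 | per locus per generation allele flip |
| historical sizes | 1000 → 10000 → 4000 | census anchors over 2020 generations |
| expansion | 500♂ × 3500♀, litter 5 | 10 generations, dam quota × 2.5/generation, capped |
| recent | 50♂ × 3500♀, litter 5 | 10 generations under the design |
| SA | T₀ 0.5, cooling 0.9 | stop at T < 10⁻⁴ or 50 idle sweeps |
| `n_replicates` | 20 | replicates per scenario |
| `scale` | 1 | proportional shrink of censuses and historical phase lengths |

## Scaling and what a green test establishes

The `scale` knob multiplies every census size *and* the historical phase
lengths. This preserves the drift time-scale t/N (hence the
allele-frequency spectrum and the relative LD build-up), the sire:dam
ratio, the litter size, and — because reference size and the effective
number of chromosome segments shrink together — the signal-to-noise ratio
that drives prediction accuracy. Reduced-scale runs are therefore faithful
miniatures for orderings and rough magnitudes, but absolute accuracies
drift upward as scale falls (smaller Nₑ ⇒ deeper LD and closer
relationships), so magnitude-level comparisons are only made at `scale = 1`.
The acceptance script runs the full paper-scale preset; the test suite runs
the scenario grid at a small preset and asserts orderings only there.

The generator emulates a closed nucleus with discrete generations, equal
litter sizes, no selection pressure during history, and a single
chromosome. It does not emulate overlapping generations, mortality or
culling, litter-size variation, dominance or epistasis, multi-chromosome
genomes, or genotyping error — a green suite says nothing about those.

## Numerical and design decisions

* **Founder alleles at frequency 0.5.** The initialisation is not specified
  by the problem statement; maximal initial diversity plus 1000 generations
  of drift/mutation yields the intended equilibrium. Loci fixed by the end
  of history are retained in the genome but excluded from prediction and LD.
* **Linear size interpolation**, rounded to the nearest even count, keeps
  the sexes balanced through growth and decline.
* **Expansion founders ignore historical sex labels.** The bottleneck
  generation (4,000, half female) cannot supply 3,500 dams *and* 500 sires
  by label; since sex is genetically inert under random union of gametes,
  founders are drawn without replacement and roles assigned.
* **Dam-quota cap in the expansion.** Uncapped geometric growth
  (× litter/2 per generation) is computationally explosive; the quota is
  capped at 10,000 (scaled), comfortably above what the recent phase draws.
* **Recent-phase litter of 5** carries the expansion brood structure over,
  as nothing else is specified.
* **λ from true variances**, not REML — the simulation study's point is the
  mating design, not variance estimation; a user λ can be supplied.
* **SA stopping rule** (T < 10⁻⁴ or 50 sweeps without improvement) bounds
  runtime and detects plateaus; the temperature schedule itself is fixed by
  the stated T₀ = 0.5 and factor 0.9.
* **Annealing objective is the mean, so early sweeps at T ≈ 0.5 accept
  almost everything**; the search effectively anneals into a greedy phase
  as T passes the Δ-scale of single swaps. Best-so-far tracking makes the
  returned plan monotone in quality regardless.
* **Bias is fitted on reference + validation pooled**, matching the single
  slope reported per scenario.
* **Histories are shared across scenarios of a replicate** (one simulation
  on the union map: densest marker grid plus the largest QTL-candidate set;
  scenarios take the nearest-to-grid marker subset and a QTL subsample), so
  density and design comparisons see identical genetic backgrounds.
* **QTL collisions** with marker positions (probability zero on a
  continuous map, but guarded) are resampled.

## Worked example

```{r example}
library(matesim)

cfg <- scenario_config(n_markers = 950, n_qtl = 50, h2 = 0.60,
                       design = "assortative_pos", n_replicates = 3,
                       scale = 0.1, master_seed = 1)
res <- run_grid(cfg)
res$summary
autoplot(res)
```

Known limitations: pure-R simulated annealing is the slowest component at
full scale; `kinship_matrix()` is quadratic in pedigree size and meant for
candidate-set and test-scale pedigrees (the generation loop uses the linear
propagation instead); and the single-chromosome genome means absolute LD
levels should not be read as genome-wide cattle values.
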