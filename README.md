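# patrikin

Simulation and inference of patrilineal kinship systems from
identity-by-descent (IBD) data, for archaeogenetics at the scale of whole
cemeteries.

Ancient-DNA studies of fully excavated burial grounds can reconstruct
multi-generation pedigrees and, from them, read off social practice:
patrilineal descent and patrilocal residence (sons stay, daughters leave),
female exogamy (wives are unrelated immigrants), polygyny and levirate
unions (a widow re-partnered to an agnate of her dead husband), and strict
consanguinity avoidance (no long runs of homozygosity anywhere in the
community). `patrikin` implements that entire analysis as a tested,
self-contained pipeline: it *generates* communities obeying configurable
versions of those rules, transmits genomes through them, degrades the
resulting IBD segments to ancient-DNA-like tables, and then *re-infers*
relatedness, pedigrees, social statistics, IBD networks and
pedigree-constrained radiocarbon chronologies — so every inference step is
validated against a known truth.

## The core quantities

* **Kinship from segments**: φ = p₁/4 + p₂/2, where p₁ and p₂ are the
  genome fractions shared IBD1/IBD2; degrees are binned at the log2
  midpoints (first 0.177–0.354, second 0.088–0.177, third 0.044–0.088),
  with parent–child vs sibling separated by IBD2 (p₂ < 0.02 and p₁ > 0.9
  vs p₂ ≥ 0.1).
* **Second-degree subtypes** (avuncular / grandparent / half-sibling) via
  kernel-density likelihoods of (segment count, mean segment length) under
  distributions simulated from 60 reference pedigrees.
* **Consanguinity**: the summed length of >4 cM ROH as a fraction of the
  map, F̂ = Σℓ/L; offspring of second cousins (F = 1/64) are detected at
  ≥80% sensitivity with no false positives on outbred simulations.
* **Network statistics**: per node, degree k, strength w (sum of
  maximum-IBD edge weights), and the within/between-site partition
  k = k_W + k_B, with the k_B/k ratio contrasted between sexes by a
  permutation Kolmogorov–Smirnov test and Welch's t-test. Edges require a
  shared segment >12 cM (two of them if the longest is <16 cM), segments
  >8 cM with >220 SNPs/cM, and individuals with >450,000 covered SNPs.
* **Chronology**: calendar-year posteriors
  P(θ) ∝ N(age; μ_curve(θ), √(σ² + σ_curve²)) refined by a generational
  random walk T_{g+1} = T_g + gap, gap ~ N(29 y, 8 y), sampled by
  Metropolis-within-Gibbs; the payoff is the reduction in 95% HPD widths.

## Worked example

```r
library(patrikin)

spec <- scenario_spec("rk_like", seed = 11,
                      overrides = list(n_generations = 5))
bundle <- generate_scenario(spec)
calls <- classify_pairs(bundle$pairs)
table(calls$degree)
#> first_ambiguous    parent_child          second         sibling
#>               2             127             299              47
#>           third       unrelated
#>             380            1345

sm <- patriliny_metrics(bundle$pedigree)
sm[c("n_sons", "n_daughters", "n_exogamous_mothers", "n_lineage_mothers")]
#> sons 47, daughters 45, exogamous mothers 28, lineage mothers 1
sm$patriline_purity
#> [1] 1

table(detect_shared_partner_unions(bundle$pedigree)$relation)
#>          full_brothers paternal_half_brothers
#>                      7                      4
```

Reading: from 105 observed burials the observed IBD tables yield 127
parent–child and 47 sibling calls; every father descends from a founder
male (purity 1.00); all but one mother married in from outside; and the
eleven shared-partner unions are all between agnates — the levirate
signature. The `analysis/` directory contains numbered drivers
(`01_simulate_communities.R` … `05_chronology.R`) that run the same
workflow at full scale and write tables under `results/`.

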