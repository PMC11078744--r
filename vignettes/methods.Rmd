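---
title: "Methods: simulating and re-inferring patrilineal kinship from IBD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and re-inferring patrilineal kinship from IBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrikin)
```

## What the package models

`patrikin` is a desk-scale pipeline for studying how steppe-style kinship
rules — patrilineal descent, patrilocal residence, female exogamy,
polygyny, levirate re-partnering and strict consanguinity avoidance —
express themselves in the genetic record of a cemetery, and for testing
whether those rules can be re-inferred from the kind of data ancient-DNA
studies actually produce: pairwise IBD segment tables, degree
classifications, uniparental haplogroups, age-at-death classes and
radiocarbon dates.

The pipeline is generative end to end. A community simulator produces a
multi-generation pedigree; a transmission model drops founder-labelled
genomes through it; an observation model degrades the resulting IBD
segments to ancient-DNA-like tables; inference modules then classify
relatedness, assemble pedigrees, compute social-practice statistics,
build IBD-sharing networks, and calibrate radiocarbon dates under
genealogical priors. Because the truth is known at every stage, each
inference step is tested against the generative record.

## The community model and its parameters

`sim_config()` holds the generative parameters. The defaults are the
study conditions and are chosen once:

* **Generation gap**: mean 29 years (the standard conversion between
  generations and calendar time in archaeogenetics), sd 4 years.
* **Exogamy rate 0.98**: essentially all wives are unrelated immigrant
  women; the rare exception is an in-community union, which must respect
  the consanguinity rule.
* **Consanguinity minimum degree 6**: unions between relatives closer
  than the sixth genetic degree never occur, so even second cousins
  (degree 5, kinship 1/64) do not marry. This mirrors steppe marriage
  rules that forbid intermarriage within the paternal line for several
  generations.
* **Polygyny 0.15–0.2 per extra partner** (capped at four partners) and
  **levirate 0.15–0.2**: a union's male may die and his widow is
  re-partnered to a male agnate, chosen in the priority order full
  brother, paternal half-brother, father's brother's son, son of the
  deceased by another partner.
* **Offspring counts** are Poisson per union (simplest count model
  consistent with a mean parametrization); per-union means near 1.1–1.3
  keep nine-generation communities in the low hundreds of individuals. A
  per-generation cap on reproducing males (`max_reproducing_males`) acts
  as a carrying capacity so that community size stays bounded over long
  simulations.
* **Burial sampling**: adult lineage daughters are absent with
  probability 0.7–0.75 (they married away); a fraction of last-generation
  males' partners appear as childless, unrelated adult women. These two
  filters reproduce the observational signature of patrilocality: sons
  outnumber daughters in pedigrees, and unrelated adults skew female.

Two facts about the model's edges are worth stating because tests rely on
them. First, founding-generation wives are exogamous *by construction* —
no community predates its founders — so recovery of the configured
exogamy rate is evaluated on partners of non-founder fathers
(`exogamy_rate_postfounding`). Second, when the consanguinity rule
exhausts the in-community bride pool the simulator falls back to an
exogamous wife; the realized endogamy fraction therefore tracks the
configured one only when the pool does not bind, which the test
configurations ensure (four generations, five founders, mean two
daughters per union).

## Genome transmission and what "IBD" means here

Genomes are founder-labelled haplotype tilings over a 22-autosome
sex-averaged map totalling about 3,540 cM. Meiosis draws a
Poisson(length/100) crossover count per chromosome with uniform
positions, no interference, and a random starting haplotype. IBD between
two individuals is read off exactly from label equality: IBD2 where the
two label multisets match, IBD1 where exactly one pair matches. ROH are
the intervals where an individual's own two labels coincide.

This sidesteps sequence-level simulation entirely: founders are IBD-free
by construction, so no background-relatedness or mutation parameters are
needed, and every sharing statistic has a closed-form expectation
(parent–child IBD1 covers the map exactly; sibling IBD0/1/2 fractions
average 1/4, 1/2, 1/4; the ROH fraction of an inbred individual averages
its inbreeding coefficient F). Crossover interference is deliberately
omitted — it changes higher moments slightly but none of the first-moment
targets the analyses use; the map and crossover model are isolated behind
`drop_genomes()` as an extension point.

The observation model converts true segments to observed ones:
boundaries jitter by ±0.5 cM, segments vanish with probability
0.5·exp(−length/10) (a monotone decreasing detection loss emulating
haplotype-IBD calling on coverage-matched ancient genomes), segments
below 8 cM are discarded, and SNP counts are assigned at a fixed density
(220 per cM by default; the scenario generator uses 250 so that
generated tables pass the downstream density filter the way real
post-imputation data would).

## Relatedness classification

Degrees are classified from segment summaries, not genotype likelihoods:
the genotype-HMM callers this module stands in for ultimately emit the
same summaries. The kinship coefficient is estimated as
φ = p₁/4 + p₂/2 with p₁, p₂ the genome fractions in IBD1/IBD2, and
binned at the standard log2 midpoints (0.354, 0.177, 0.088, 0.044).
Within the first degree, parent–child requires p₂ < 0.02 and p₁ > 0.9;
siblings require p₂ ≥ 0.1. A first-degree pair failing both (which
happens when a distantly consanguineous union adds a sliver of IBD2 to a
parent–child pair) is reported ambiguous; pedigree assembly may still
treat it as parent–child when p₁ > 0.9, since no sibling configuration
approaches full IBD1 coverage.

Second-degree subtypes use reference distributions simulated from 60
eight-member pedigrees containing an avuncular, a grandparent–grandchild
and a paternal half-sibling pair. Classification maximizes a
product-Gaussian kernel likelihood over (segment count, mean segment
length), with a likelihood-ratio-below-2 rule mapping to "ambiguous".
Two robust orderings emerge: avuncular pairs carry **more** segments than
grandparent–grandchild pairs, and grandparent segments are **longer**.
One caution: under label-based truth, half-sibling segment counts sit
near the avuncular cluster (theoretical expectations ≈46 vs ≈43
segments, against ≈29 for grandparents), so the three classes overlap
asymmetrically here — completely on total IBD, strongly between
half-siblings and avuncular pairs, and only weakly between half-siblings
and grandparents. Genotype-level noise in real callers blurs these
distributions further and symmetrizes the overlap; reproducing that
requires the genotype model this package intentionally excludes. The
tests therefore assert the orderings plus the overlap pattern the
generative model actually supports, and half-sibling recall should not be
expected to be the weakest of the three in this setting.

Consanguinity is flagged when the summed length of >4 cM ROH exceeds
0.4% of the map (≈14 cM). That threshold was calibrated once on
simulations: offspring of second cousins (F = 1/64) are detected at
roughly 87% sensitivity, offspring of first cousins essentially always,
while outbred individuals — who in this model have no ROH at all — never
trip it.

## Pedigree assembly

Connected components over first- and second-degree calls become
candidate pedigrees. Parent–child pairs are oriented by birth year,
chronological phase, or adult/subadult contrast; equal or unknown ages
leave the pair unresolved rather than guessed — the archaeological
context that resolves such ties in real studies is not available to an
algorithm. Fathers and mothers are assigned by sex; Y labels must match
along father–son edges and mtDNA labels along mother–child edges when
enforcement is on, and violations become per-component conflict reports.
Sibling sets with no observed parent receive a single inferred
(unobserved) parent when at least two observed members demand one; a
parent known for part of a sibling set is never propagated to the rest,
because levirate unions produce 3/4-sibling sets that share a mother
while their fathers are brothers. On rk_like communities with perfect
observation, the assembled parent–child edge set equals the truth
restricted to observed individuals exactly.

## Networks

Edges follow the published filter chain: per-segment >8 cM and >220
SNPs/cM; a pair qualifies with at least one retained segment >12 cM, and
needs two such segments when its longest is under 16 cM; individuals
with ≤450,000 covered SNPs are excluded. The edge weight is the longest
single shared segment (maximum IBD), not total sharing — first-degree
weights above 280 cM are only attainable by a single
near-chromosome-1-length segment. Node statistics are degree k, strength
w, and the within/between-site partition k_W + k_B = k with the burial
site as the module. Σk = 2|E| and Σw = 2Σweights are asserted on every
generated network. Group contrasts use a two-sample KS statistic with a
pooled-relabelling permutation null (the standard exchangeable null;
p = (1 + #{D* ≥ D})/(1 + n_perm)) and Welch's t-test for the k_B/k
ratio. On multi-site simulations with female exchange, the female mean
k_B/k exceeds the male mean — in-marrying women are the between-site
connectors. One bookkeeping note: published adult-network link counts
and mean degrees cannot always be reconciled exactly (a stated link
count of 1,211 with 195 adults implies a mean degree near 12.4, not the
18.07 that is printed alongside), which is why `node_stats()` reports
raw counts and means side by side instead of deriving one from the
other.

## Chronology

Single dates are calibrated on a 1-year calendar grid:
posterior(θ) ∝ N(measured age; μ_curve(θ), √(σ_meas² + σ_curve²(θ))),
with the 95% HPD as the smallest set of grid cells holding 95% of the
mass. The joint model replaces the phase/sequence machinery of
full-featured calibration software with the same prior information
content in a transparent form: latent per-generation reference years
T_{g+1} = T_g + gap_g, gap_g ~ N(29, 8) truncated positive, individual
years θ_i ~ N(T_{g(i)}, 10), sampled by Metropolis-within-Gibbs
(random-walk updates on θ_i, T₁ and each gap; marginal densities
histogrammed on the grid with a light 5-cell moving average; split-chain
mean discrepancies reported as a convergence diagnostic). Within-
generation sd (10 y) and gap sd (8 y) are configurable; the truncation
at zero encodes that generations do not run backwards. On a
nine-generation chain with σ_meas = 25 y on a wiggly synthetic curve,
constrained 95% HPD widths shrink for every individual, with median
reductions near 50% and maxima above 60% where the curve is
uninformative — the regime in which genealogical priors pay off most.
The synthetic curve (slope one plus sinusoidal wiggles) is exactly that:
synthetic, standing in for a measured atmospheric record so that the
pipeline stays self-contained.

## Scenario presets and problem sizes

`scenario_spec()` exposes three structural presets: `rk_like` (one site,
nine generations, four founder males plus a three-male replacement
cohort entering at generation 5 with fresh Y lineages and taking over
reproduction — the generative analogue of a community replacement
detectable as a switch in the dominant Y haplogroup), `multi_site`
(three sites, 40% of exogamous wives drawn from other sites'
patrilines), and `null` (unrelated individuals, no structure). Presets
are structural, not calibrated to any real site's counts.

Test and acceptance problem sizes — 1,000 sibling pairs, 600–1,000 ROH
replicates, 60 reference pedigrees, 200 seeds for exogamy recovery,
1,000–2,000 replicates for test calibration, 8,000 MCMC iterations —
were chosen as the smallest sizes at which the Monte-Carlo standard
errors are comfortably below the effect sizes being asserted.

## Known limitations

* No genotype or sequence level: phasing error, contamination and
  coverage enter only through the segment-level observation model.
* Founders are unrelated by construction, so background IBD between
  "unrelated" individuals is absent; real between-site sharing includes
  a population-level component this model does not generate.
* Third-degree subtypes are not resolved, matching the resolution limit
  of the upstream callers.
* The assembly stage limits ghost inference to single unobserved parents
  connecting at least two observed relatives; deeper missing-individual
  reconstruction is out of scope.
* Pass/fail on synthetic data shows the inference machinery is coherent
  with its own generative assumptions; it does not by itself validate
  those assumptions against real cemeteries.
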