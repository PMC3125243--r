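---
title: "Gene-network metacommunities: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-network metacommunities: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(netcomm)
```

netcomm is an individual-based simulator for a question at the interface of
evolutionary genetics and metacommunity ecology: when two species compete for
a resource whose quality drifts through time, and the limiting quantitative
trait of each species is produced by a gene regulatory network, which wins —
the species with the "better" genetic architecture, or the species with the
better dispersal ability?

## The genotype-phenotype model

Each individual carries a single chromosome encoding a Boolean gene network
of `n` genes. Every gene except the basal-most ("root") gene has exactly one
upstream regulator (its *head*) and a function bit: 1 for an activator, 0
for a repressor. Gene states are binary and fully determined in one pass
from the root: a gene is *on* exactly when its head's state equals its
function bit (an on-activator or an off-repressor turns its target on). The
root gene's state is a heritable bit, drawn at random for each founder and
transmitted thereafter with the chromosome.

Restricting each gene to a single input keeps state evaluation linear in
`n` and makes the state assignment unique: the head relation is a tree
rooted at the basal gene, so no attractor iteration is ever needed.
Construction adds genes one at a time and attaches each new gene to a
previously added regulator, which guarantees acyclicity by index order
(`heads[i] < i`); recombination mixes positions between two such
chromosomes and therefore preserves the bound, and head mutations resample
only earlier-indexed genes. Topologies are built either *randomly* (uniform
attachment) or *scale-free* (lottery attachment with probability
proportional to out-degree + 1; the +1 lets a gene with no downstream
targets acquire its first edge, without which attachment would freeze on
the first edge drawn).

The phenotype is the number of terminal genes (out-degree 0) in the on
state, rescaled to the environmental range: `(env_max / T) * S`. With
`env_max = 140`, a network with 8 terminal genes of which 4 are on yields a
trait value of 70:

```{r}
g <- genome(heads     = c(NA, 1, 1, 2, 3, 4, 4, 5, 5, 2, 2, 3, 3),
            functions = c(NA, 1, 0, 1, 1, 1, 0, 1, 0, 1, 0, 1, 0),
            root_state = 1L)
length(terminal_genes(g))
phenotype(g, env_max = 140)
```

A fixed topology can express at most `T + 1` distinct trait values, so
small networks trade resolution for adaptive speed: a 16-gene network moves
in steps of roughly 17.5 trait units, a 256-gene network in steps of about
one unit. The trait range is taken as `[0, env_max]`: the worked example
above only pins the maximum, and a zero minimum is the natural reading of
"all terminals off".

## Reproduction, selection, demography

Individuals are hermaphrodites mating at random within their species and
patch. Each resident seeds one mating with a uniformly drawn distinct
partner (partners may be reused); the offspring number per mating is
Poisson with mean `lambda = 1.5`. We chose this *per-capita seeding* over
disjoint pairing deliberately: disjoint pairs give a per-capita growth
factor of `lambda / 2 = 0.75 < 1` and no population could persist, whereas
per-capita seeding gives `lambda = 1.5`, which sustains populations at
carrying capacity.

The offspring chromosome is a positional chimera of its parents: position 1
(which carries the heritable root state) comes from a uniformly chosen
starting parent, and each later position switches source with probability
`rec` (so a 256-position chromosome at `rec = 0.05` sees on average
`0.05 * 255 = 12.75` switches). Mutation then hits each of the `2(n - 1)`
mutable elements — the head and function entries of every non-root gene —
independently with probability `mu`. A hit function bit flips; a hit head
entry is resampled uniformly among earlier-indexed genes excluding self and
the current head, so realized mutations are always non-synonymous and never
create cycles. One corner case follows from the encoding: gene 2's only
legal head is gene 1, so that single element has no non-synonymous
alternative and is left unchanged (at `mu = 1e-3`, `n = 256` the expected
number of realized mutations per genome is therefore
`(255 + 254) * 1e-3 = 0.509`).

Death occurs in three stages after reproduction. All parents die
(non-overlapping generations). Offspring then face Gaussian stabilizing
selection against their patch's resource quality `q`: survival probability
`RF = exp(-delta^2 / (2 * omega^2))` with `delta = |q - phenotype|` and
`omega = 2` trait units. We use the standard Gaussian stabilizing-selection
kernel with `2 * omega^2` in the denominator; the alternative `omega^2`
normalization differs only by a rescaling of `omega`. Finally a carrying
capacity of `K = 200` is enforced per patch on both species pooled, by
uniform random removal down to exactly `K` — the cap is species- and
fitness-blind, so exceeding cohorts are thinned hypergeometrically.
Competition is thus purely demographic: the better-matched species loses
fewer offspring to viability selection and gradually claims more of the
shared cap.

## The landscape and dispersal

Three circular patches (radius 10 units by default) sit at the vertices of
an equilateral triangle, 50 units apart edge to edge. Patch radius is a
free geometric parameter; 10 units puts centers 70 units apart, within the
100-unit maximum dispersal distance, so inter-patch dispersal is possible
but usually lethal — colonization is rare and costly. All patches start at
resource quality 70; each patch's quality then changes by its own rate
(defaults `1e-3`, `2.5e-4`, `1e-4` units per generation), deterministically
increasing and reflecting at the range boundaries (decreasing and
random-walk dynamics are available as options). Landscape *heterogeneity*
is the number of unique rates (1, 2 or 3).

Dispersal is passive and fixed per species: each survivor leaves with
probability `d` (grid: 0.1, 0.05, 0.01), departing from a uniform random
point of its source disc at a uniform angle and a uniform 0-100 unit
distance. Individuals landing outside every patch die immediately; patch
membership uses the closed disc. Within a run, the first 20 generations are
a *canalization* period without dispersal, letting additive variance
stabilize in the founding patches.

The per-generation schedule is: resource update, reproduction, parental
death, viability selection, dispersal, capacity enforcement, recording. We
place dispersal after viability selection and before the cap, so colonists
face the shared carrying capacity in their destination patch immediately —
the natural reading of competition for space; quantitative-genetics
summaries are measured on the post-viability, pre-dispersal cohort, where
mid-parent records are complete.

## Experiments and metrics

A run starts with 100 individuals of each species in patches 1 and 2
(patch 3 empty) and lasts 750 generations or until the first regional
extinction, whichever is first; runs are bit-reproducible given a seed.
`run_experiment()` drives factorial designs with per-run seeds derived by a
stable hash of (master seed, cell, replicate). The default metacommunity
design crosses competitor network size (16, 64, 256), topology (scale-free,
random), mutation rate (1e-3, 1e-4, 1e-5), recombination (0.05, 0.5) and
dispersal (0.1, 0.05, 0.01) with three landscape-heterogeneity
representatives — 324 cells, with the focal species fixed at the 16-gene
scale-free, `mu = 1e-4`, `rec = 0.05`, `d = 0.05` architecture. The
single-species metapopulation arm runs, by default, three replicates at
each of seven landscape rate assignments (three homogeneous, three
two-rate, one all-rates; ten unordered assignments exist, and the list is
user-configurable).

Per run we report: *coexistence* (both species regionally present at the
final scheduled generation), *persistence time* (first regional extinction,
capped at the run length), the census-weighted *trait-environment mismatch*
(|patch mean phenotype − patch quality|, weighted by patch census, averaged
over species, patches and post-canalization generations), and the *0.9 K*
ecosystem-function proxies: the critical population size is 0.9 times the
maximum regional census observed across all runs being compared, and we
extract the first generation above it and the fraction of generations above
it. Both 0.9 K metrics are computed over the realized run length — a run
that ends at extinction contributes no post-extinction zeros.
Heritability is the ordinary least-squares slope of offspring phenotype on
mid-parent phenotype, per species and generation; additive variance is
`h2 *` phenotypic variance. Slopes outside `[0, 1]` are reported raw — with
selection pinning phenotypes to a coarse grid the mid-parent variance is
often tiny and the slope correspondingly noisy or undefined (`NA`).

`fit_summary_models()` is a thin convenience layer over `glm()` (binomial,
logit link; coexistence on competitor dispersal, network size,
heterogeneity and their interaction, reported as sequential deviance) and
`lm()` (persistence on competitor dispersal, network size and mutation
rate, reported as percent variance explained).

## What the simulations emulate, and what they do not

All data are self-generated: the simulator *is* the data generator, and its
defaults are the study conditions (two species, three patches, `K = 200`,
`omega = 2`, `lambda = 1.5`, 750 generations, founding census 100). Runs
emulate drifting environmental optima, genetic transmission with
recombination and mutation, and demographic stochasticity. They do not
emulate multi-input regulation, continuous expression, pleiotropy between
networks, evolvable dispersal, explicit resource depletion, or more than
two species — all deliberate simplifications of the underlying model
class.

Two consequences of the chosen constants are worth knowing before
interpreting results. First, founding populations carry independently
random networks, so the founding cohort's segregation variance is large;
with `omega = 2` the mean viability of a large-network species'
(`n >= 64`) early offspring falls well below the `1 / lambda = 0.67`
replacement threshold, and such species reliably fail to establish within
about ten generations. Small networks (n = 16) establish because their
coarse trait grid concentrates survivors on the optimum and
homogenizes the gene pool within a few generations. In the desk-scale
factorial this makes competitor network size, not dispersal, the dominant
source of persistence-time variance. Second, the default environmental
rates move the optimum by at most 0.75 trait units over a full run —
small against `omega = 2` — so dispersal-mediated competitive exclusion
between architecturally equal species is weak at these run lengths, and
equal-architecture pairs essentially always coexist. Both behaviours are
asserted by the test suite, which is the authoritative record of what the
package actually reproduces.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: a singleton patch population
produces no offspring; an empty world is a fixed point of the scheduler;
mid-parent regression returns `NA` below 3 pairs or at (near-)zero
mid-parent variance (tolerance `1e-12`); empty patches contribute zero
weight to the mismatch. Ties and boundaries: patch membership is a closed
disc; resource quality reflects at `[0, env_max]`; the capacity cull brings
an exceeding census to exactly `K`.

The test suite exercises the full engine at reduced problem sizes chosen to
give stable statistics: distributional checks use 10,000 draws with
3-standard-error tolerances; topology contrasts use 200 genomes per kind at
`n = 256`; the coexistence corner design uses 10 replicates of the four
{equal, maximally unequal} network-size x dispersal corners at full run
length; the mismatch trend uses 5 replicates at each competitor dispersal
rate; the persistence decomposition uses a 2^3 factorial with 3 replicates.
Larger designs (the 324-cell factorial at many replicates) are intended for
script use via `run_experiment()` or the command-line front end in
`inst/cli/netcomm.R`.
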