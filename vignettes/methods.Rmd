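---
title: "Methods: coalescent models, filters and estimators in tunapopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalescent models, filters and estimators in tunapopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tunapopgen)
```

# Scope

`tunapopgen` implements the computational core of a whole-genome
population-genomic analysis of two weakly differentiated ocean populations
(an "Atlantic"-role population A and an "Indo-Pacific"-role population P):
variant-filter cascade, fixation indices with locus bootstrap, folded joint
minor-allele site-frequency spectra (SFS), isolation-with-migration (IM)
demographic inference by simulated-SFS composite likelihood, mutation-rate
calibration, PSMC input encoding and output scaling, and
transversion-collapsed haplotype genealogy graphs. Because all analyses are
exercised on synthetic data, the package also contains a first-class
two-population IM coalescent simulator and a fixture generator that
emulates a two-caller variant-calling setup.

# The IM model and the coalescent engine

## Model and conventions

An ancestral population of diploid effective size $N_{anc}$ splits
instantaneously $T$ generations before present into populations A and P of
constant sizes $N_A$ and $N_P$, connected by constant gene flow. Migration
rates are stated in the forward direction: $m_{PA}$ is the proportion of
population A replaced each generation by migrants from P. Backwards in
time this reverses: a lineage currently in A traces its ancestor into P at
rate $m_{PA}$ per generation. Pairs of lineages in a population of diploid
size $N$ coalesce at rate $1/(2N)$ per generation; time is continuous with
exponential waiting times. $T = \infty$ gives the equilibrium two-deme
(island) model. These conventions make $E[T_2] = 2N$ for a panmictic pair,
which the tests verify by simulation.

## Exact simulation and the strong-migration collapse

The engine (C++) runs an exact Gillespie simulation of every coalescence
and migration event. At migration rates typical of weakly structured
marine fish (for example $m \sim 0.05$ per generation against coalescence
rates of order $10^{-5}$) a single genealogy contains thousands of
migration events, which makes simulation-intensive inference prohibitively
slow. The engine therefore switches to a *strong-migration collapse* when
the location process is demonstrably much faster than coalescence:

* condition: $m_{PA} + m_{AP} > F / (2 \min(N_A, N_P))$ with
  `strongFactor` $F = 30$ by default;
* an exact burn-in of `relaxTime` = 5 location-relaxation times
  ($5/(m_{PA}+m_{AP})$) is always simulated first, so that the sampling
  configuration is forgotten before the collapse;
* afterwards lineage locations are treated as i.i.d. stationary
  ($\pi_A = m_{AP}/(m_{AP}+m_{PA})$) and every pair coalesces at the
  location-averaged rate $\pi_A^2/(2N_A) + \pi_P^2/(2N_P)$.

A guard (`maxExactEvents`, default 2000 events per genealogy) forces the
collapse in extreme corners of parameter space where the condition narrowly
fails but exact simulation would be unbounded. `simControl(strongFactor =
Inf, maxExactEvents = 1e12)` forces the fully exact path.

The collapse preserves marginal rates but discards the *clumping* of
coalescences during correlated residence episodes (for example, several
A-sampled lineages coalescing rapidly inside a small A before escaping).
The tests quantify the consequences: the collapsed and forced-exact
spectra agree closely at the default settings (total-variation distance a
few percent), and the engine reproduces the analytic panmictic folded SFS,
$E[T_2] = 2N$, the island-model fixation-index closed forms, and an
independent simulator (msprime) on an asymmetric IM model. The residual
approximation does, however, flatten the likelihood in directions dominated
by within-small-population clumping (see "Known limitations").

## The SFS law of segregating sites

For SFS-based inference the quantity of interest is the probability that a
segregating site shows derived counts $(i, j)$ in samples of $k_A$ and
$k_P$ alleles. Under infinite sites this is
$E[L_{ij}]/E[L_{tot}]$, the ratio of expected branch lengths subtending
the configuration. The engine accumulates branch lengths per configuration
over independent genealogies and uses the ratio of sums, which is unbiased
for the ratio of expectations; sampling a single mutation per genealogy
would instead estimate $E[L_{ij}/L_{tot}]$, which is measurably biased at
these sample sizes (about 0.017 on the singleton class at $k = 14$, larger
than the Monte-Carlo error of the calibration tests). An observed spectrum
of $S$ SNPs is drawn multinomially from the estimated law.

# Joint folded SFS construction

Genotype data are projected to fixed allele counts ($k_A$, $k_P$, default
14 each; the Indo-Pacific axis may be set to 16) by drawing alleles at
random without replacement (a hypergeometric draw on the alternate-allele
count). A site is skipped when a group has more than 50% missing genotypes
or fewer than $k$ non-missing alleles. Orientation is decided on the
*pooled* post-projection counts: cells with pooled derived frequency above
0.5 are reflected onto their complement; at exactly 0.5 the site
contributes weight 0.5 to each orientation, so folding is idempotent and
total weight always equals the number of contributing sites. Sites
monomorphic after projection fall into the (0,0) cell, which is recorded
but masked from likelihood computations (SNP-conditioned inference carries
no information in the invariant class).

# The filter cascade

The cascade mirrors a two-caller short-read workflow. Defaults (all
configurable through `filterConfig()`):

| stage | rule |
|---|---|
| callset intersection | identical (scaffold, position, ref, alt) in both callers |
| hard filters | FS > 60, MQRankSum < -12.5, ReadPosRankSum < -8, QD < 2, MQ < 40 (strict inequalities); non-biallelic sites and indels removed |
| indel proximity | SNPs within 10 bp of an indel's affected reference span removed |
| genotype masking | genotype set missing when GQ < 20 **or** DP < 3 **or** DP > 100 |
| minor-allele count | pooled MAC >= 2 |
| Hardy-Weinberg | removed only when the exact HWE p < 1e-4 **and** the one-sided heterozygote-excess p < 1e-4 |
| MAF / missingness | MAF > 1% (1-3% typical); per-site missingness <= 20% (10/20/50% typical) |
| LD pruning | greedy positional scan per scaffold; a site is dropped when r^2 > 0.8 with any retained upstream site within 10 Mb |

Design notes. Missing INFO annotations never trigger removal (the
rank-sum annotations are undefined at sites without heterozygotes). The
masking rule treats the three bounds marginally (any failing bound masks),
the conventional reading of combined GQ/DP criteria. The HWE test pools
all samples, matching the default behaviour of the genotype-QC tools this
cascade emulates; the heterozygote-excess condition means a site deviating
through heterozygote *deficit* is retained. The exact test enumerates
Levene's conditional distribution of the heterozygote count given allele
counts; the two-sided p sums point probabilities not exceeding the
observed one. LD pruning is a deterministic greedy scan in position order
(ties keep the smaller position), since the exact windowed heuristic of
the emulated tool is unspecified.

# Differentiation statistics

`fstWeirCockerham()` computes the Weir & Cockerham (1984) variance
components $a$, $b$, $c$ per locus in the diploid observed-heterozygosity
form with per-locus non-missing sample sizes, and combines loci as the
ratio of sums $\sum a / \sum (a+b+c)$ (the "weighted" convention).
`neiBasicStats()` computes the sample-size-corrected gene diversities
$H_O$, $H_S$, $H_T$ with the harmonic-mean correction, and
$F_{ST} = (\bar H_T - \bar H_S)/\bar H_T$, $F_{IS} = 1 - \bar H_O/\bar H_S$
on locus means. Both are pinned by independent brute-force oracles at
$10^{-12}$ in the tests, and both are invariant to sample relabeling and
allele-label swaps.

Worth noting for interpretation: in a two-deme island model at migration
rate $m$ per lineage, the total-population (Nei/$G_{ST}$-type) index has
expectation $1/(1+16Nm)$, while the pairwise Weir-Cockerham estimator
converges to $1/(1+8Nm)$ — the two statistics answer slightly different
questions with few demes, and the simulator reproduces both closed forms.

`bootstrapFst()` resamples loci with replacement; the 95% interval is the
2.5/97.5 percentile pair and the p-value is floored at $1/(B+1)$ so finite
resampling never reports zero. `holmAdjust()` applies sequential
Bonferroni via `stats::p.adjust`.

# Demographic inference

## Likelihood

The composite log-likelihood of an observed folded spectrum is
$\sum_{ij} w_{ij} \log p_{ij}$ over unmasked cells, with expected cell
probabilities estimated by simulation. Zero-probability cells carrying
observed weight receive the floor $\varepsilon = 1/(10 \times
\text{simulations})$, after which probabilities are renormalized — this
guarantees the Gibbs inequality (composite $\le$ saturated) on every
evaluation, which is asserted at run time and in the tests. The saturated
likelihood is $\sum w \log (w/W)$.

## Identifiability and the fixed-$\mu$ anchor

The SNP-conditioned folded spectrum is *exactly* invariant under
$(N, T) \to (cN, cT)$, $m \to m/c$: the composite likelihood alone cannot
identify absolute sizes or times. Analyses that report absolute estimates
anchor the scale through the fixed mutation rate and the amount of
sequence surveyed. `fitIMModel()` makes this anchoring explicit: when the
total sequence length $L$ is supplied, a Poisson term on the SNP total
with expectation $L \mu E[L_{tot}]$ is added, and — because the anchor is
analytic in the scale while the shape term is scale-free — the optimal
scale is profiled out exactly at every evaluation (a conditional-
maximization step). Without $L$ the fit runs in shape-only mode and only
ratios and the migration asymmetry are meaningful; the result object
flags which mode produced it.

## Search protocol

The replicate protocol follows the simulation-budget structure of
SFS-based demographic fitting: `nSets` independent sets (default 80;
desk-scale checks use 20), each spending `nLoops` x `simsPerLoop`
simulations (defaults 40 x 1e5; desk scale 15 x 2e4). Within a set the
budget is spent multi-fidelity: a screen of 20 cheap prior draws
(log-uniform priors, defaults $N, T \in [10^2, 10^6]$,
$m \in [10^{-5}, 0.5]$, spanning the plausible estimates by two orders of
magnitude), then a Nelder-Mead simplex on log-parameters at half-budget
per evaluation, with all evaluations of a set sharing one random
substream (common random numbers make comparisons nearly deterministic in
the parameters), and finally one full-budget evaluation under a substream
common to all sets so that ranking is fair. The `nBest` (default 10)
sets with the smallest gap to the saturated likelihood are averaged into
the reported mean +/- sd.

## Known limitations

At desk-scale budgets the composite-likelihood surface of the
six-parameter IM model is *sloppy*: wide regions of parameter space —
with, for example, the small recipient population's size varied by an
order of magnitude and compensating shifts in the other parameters —
fit an observed spectrum of $2 \times 10^5$ SNPs within a few tens of
log-likelihood units, which is the same order as the Monte-Carlo noise of
an expected-spectrum estimate built from $2 \times 10^4$ genealogies.
Two structural reasons: (i) when $m_{PA} \gg 1/(2N_A)$ the recipient
population's allele frequencies are migration- rather than
drift-dominated, so $N_A$ enters the spectrum only weakly (and the
strong-migration collapse used for speed removes part of that weak
signal); (ii) the folded 15 x 15 spectrum compresses the data to ~113
numbers. Consequently the desk-scale parameter-recovery checks in the
test suite (factor-2 recovery of the sizes and time, and the direction of
migration asymmetry, across ten seeded replicates) do not reach their
target pass rates: the fitted sets land on the degenerate manifold rather
than the truth, and averaging the best sets mixes both asymmetry
orderings. Resolving the manifold requires either far larger simulation
budgets per evaluation (so that likelihood differences of tens of units
become resolvable), the exact engine in the strong-migration regime
(an order of magnitude slower), or additional data features (unfolded
spectra, linkage information) that are outside this design. The machinery
itself — likelihood, anchor, search, selection — is exercised and verified
by faster tests (Gibbs bound, determinism, gap improvement, selection
rules).

# PSMC support

`encodePsmcfa()` reduces each scaffold to consecutive windows of `s`
bases (default 20): 'K' if the window contains a heterozygous site, 'T'
otherwise, 'N' when more than half of the window's bases are uncallable
(outside the consensus-depth bounds, typically 6x-40x); scaffolds shorter
than 10 kb are dropped. `tuneWindowSize()` selects the window size whose
fraction of callable windows with two or more heterozygous sites is
closest to 1% (ties to the smaller size). `parsePsmcPattern()` interprets
interval patterns like `"4*4 + 13*2 + 4*4 + 6"` (22 free parameters over
64 atomic intervals). `scalePsmcOutput()` converts scaled output to
natural units via $N_0 = \theta_0/(4\mu s)$, $N_e(k) = N_0 \lambda_k$,
$t(k) = 2 N_0 t_k g$ years, and is exactly linear in $\lambda$ and $t$.

`calibrateMutationRate()` computes $\mu = (S/L)/(\ell T/g)$ from the
substitution count $S$ between two genomes, the aligned length $L$, the
species divergence time $T$ (years) and the generation time $g$, with the
lineage-count convention $\ell$ exposed ($\ell = 2$ counts generations
along both lineages, the default). Published per-generation rates for the
same inputs can differ when a different $L$ or lineage convention was
used upstream; both knobs are therefore parameters rather than
assumptions.

# Haplotype genealogy graphs

Identical sequences are collapsed into haplotypes, and a minimum-length
(Fitch parsimony) unrooted tree of the haplotypes is sought: exhaustively
over all topologies for up to 8 haplotypes (guaranteed optimum, verified
against an independent oracle), otherwise by nearest-neighbour-interchange
hill climbing from a neighbour-joining start. For substitution placement
the unrooted tree is rooted on an edge (making it strictly binary, which
keeps the classical Fitch backtrace optimal); state ties break in the
fixed order A < C < G < T, and gaps/N are missing states that never
generate substitutions. Edges are weighted by substitution counts —
transversions only (A/G vs C/T crossings) under the reduced metric — and
zero-weight edges are contracted, merging their endpoints, so that
sequences identical or separated only by transitions share one node.
Contraction survivors without sampled members are the graph's inferred
intermediate (unsampled) haplotypes. Edge weights keep the full
multi-substitution count; long edges are not subdivided.

# The synthetic-data generator and what the tests show

`simulateGenotypes()` produces diploid genotypes by random pairing of
simulated haplotypes within populations (Hardy-Weinberg pairing), with
free recombination between and none within loci (default locus length
500 bp). `makeCallerFixture()` layers a two-caller setup on top:
controlled caller-unique sites, injected indels with proximal SNPs, one
site violating each hard-filter annotation, a multiallelic site,
heterozygote-excess and -deficit sites, a MAC singleton, a low-MAF site
and a high-missingness site driven through the DP/GQ masking bounds — each
with a truth table of the expected filter outcome. Base sites are retained
only when they pass every filter with a safety margin, so the truth is
unambiguous and the cascade can be checked for *zero* discrepancies.

The generator emulates the logical structure of real callsets, not their
physical error processes: no read-level errors, mapping artifacts,
allele-specific biases, batch effects, linked selection or intra-locus
recombination. Passing the cascade tests therefore demonstrates that the
filters implement their rules exactly as specified — not that those rules
are optimal for any particular sequencing technology.

# Problem sizes used by the test suite

Calibration checks use $10^5$ replicates ($E[T_2]$, folded SFS), the
island-model check uses a 1 Mb two-deme dataset, estimator oracles use
20-locus instances, the cascade truth check runs 20 seeded fixtures of
roughly 60 sites each, and the demographic-recovery experiment runs ten
seeded fits of 20 sets x 15 loops x 2e4 simulations against observed
spectra of 2e5 SNPs — about 1% of the SFS mass a full-genome analysis
would supply, chosen so that the entire suite completes on a single CPU
in well under half an hour.
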