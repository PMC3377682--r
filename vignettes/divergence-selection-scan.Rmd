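---
title: "Scanning candidate genes for selection under a fitted divergence model"
author: "divergeScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning candidate genes for selection under a fitted divergence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(divergeScan)
```

## The problem

Demography confounds selection scans. An excess of intermediate-frequency
polymorphism at a candidate gene looks like balancing selection but can
equally be produced by population subdivision; a diversity deficit looks
like a sweep but can be produced by a bottleneck. `divergeScan`
implements the strategy of fitting an explicit demographic null to
*control* loci and then asking whether each *candidate* gene is extreme
relative to data simulated under that fitted null.

The concrete setting is a resequencing survey of a structured crop
sample: haploid gene sequences (one per individual) for a set of
candidate genes along a metabolic pathway, anonymous sequence loci and
microsatellites as demographic controls, individuals partitioned into
two geographic populations and into phenotype (root color) groups, and a
distant congener as outgroup.

## The divergence model

Two populations of constant effective sizes $N_W$ and $N_E$ (diploid
individuals) diverged $T_d$ generations ago from an ancestral population
of size $N_A$. There is no migration after the split and no growth;
these are deliberate model restrictions, not oversights. Sequences
mutate under Jukes–Cantor at rate $\mu_{seq}$ per site per generation;
microsatellites follow a generalized stepwise model with per-locus rate
$\mu_{SSR}$ and geometric step sizes ($P(k) = (1-P_{SSR})P_{SSR}^{k-1}$,
direction equiprobable, alleles reflected into the observed allele
range).

**Scaling convention.** One sequence is sampled per diploid individual,
so a population of $N$ individuals carries $2N$ exchangeable gene copies
for sequence loci, and likewise $2N$ copies (two per individual) for
microsatellites. The continuous-time coalescent uses pair rate
$1/(2N)$ per generation throughout; all times are in generations. This
single convention is used by the simulator, the ABC machinery and the
null distributions.

## ABC fit

The model is fitted to the control loci by rejection ABC with local
linear regression:

* **Summary statistics** (fixed order): mean number of SSR alleles per
  population, Weir–Cockerham SSR $F_{ST}$, shared-allele distance, mean
  number of distinct haplotypes per population and pooled, mean number
  of segregating sites, and the multi-locus Hudson $F_{ST}$ for
  sequences.
* **Priors**: log-uniform $N \in [10^2, 10^5]$ for all three sizes,
  log-uniform $\mu_{seq} \in [10^{-9}, 10^{-7}]$ and
  $\mu_{SSR} \in [10^{-5}, 10^{-3}]$, uniform $P_{SSR} \in [0, 0.9]$,
  and $T_d \sim N(500, 100)$ truncated to $[350, 750]$ generations (a
  crop whose two gene pools separated within the last millennium of
  cultivation history, with roughly biennial generations). All are
  configurable.
* **Distances** are Euclidean on MAD-standardized statistics (MAD rather
  than SD for robustness to the heavy right tails that log-uniform
  priors produce). The accepted proportion defaults to $10^{-2}$.
* **Regression adjustment** uses Epanechnikov weights
  $w_i = 1 - (d_i/d_{max})^2$ — the boundary particle receives weight
  0 — and a weighted linear regression of each parameter on the centered
  statistics. Positive parameters are regressed on the log scale and
  back-transformed; adjusted particles are clamped to the prior support.
  A rank-deficient design falls back to plain rejection with a warning.
* **Reference-table hygiene**: draws from prior corners in which every
  locus is monomorphic cannot produce a defined summary vector (the FST
  denominators are empty). After 10 failed attempts such a draw is
  replaced by a fresh prior sample; the replacement count is reported.
  This conditions the fitted prior on data-like (variable) datasets.

Model fit is checked two ways (`posteriorPredictiveCheck`): a PCA of the
prior-simulated statistics onto which the observed vector and the
posterior predictive cloud are projected, and a two-tailed rank p-value
of each observed statistic within its posterior predictive distribution.

## Neutrality tests against the fitted null

For each candidate gene, `neutralityTests` simulates (default) 2000
infinite-sites datasets of the gene's own length under parameter vectors
resampled from the ABC posterior (weights-proportional), and compares:

* **Tajima's D** (two-tailed) on the pooled sample, each geographic
  group, and each color group;
* **normalized Fay–Wu H** (one-tailed, low) on the same sample sets,
  using the Zeng et al. (2006) normalization with $\hat\theta_w$ and
  $S(S-1)/(a_n^2+b_n)$ plug-ins;
* **Hudson's $F_{ST}$** ($1 - H_w/H_b$, two-tailed — low differentiation
  is itself a balancing-selection signal) between West and East and
  across the five color groups (pooled within/between pairs for more
  than two groups).

Because $F_{ST}$ is strongly mutation-rate dependent, its observed value
is ranked only against simulated datasets whose per-locus Watterson
$\theta_w$ lies within $\pm 1.5$ of the gene's observed value (per-locus
units, matching the magnitude of the values a practitioner tabulates per
gene). The matched simulation count is reported alongside the p-value.

Color groups mix the two gene pools, so color-group nulls subsample each
simulated dataset to the observed color composition (how many members of
each color group are Western vs Eastern) before recomputing the
statistic.

**Misorientation.** H requires calling ancestral states from the
outgroup, and the outgroup lineage itself mutates. With Jukes–Cantor
divergence $d$ between ingroup and outgroup, the probability that the
orienting lineage changed state at a site is
$P = \tfrac{3}{4}(1 - e^{-4d/3})$, and a changed outgroup matches the
wrong allele of a biallelic site one time in three, so the per-site
misorientation rate is estimated as $m = P/3$ (ceiling $1/4$; $m(0)=0$;
monotone in $d$). The same $m$ is injected into the simulated nulls by
flipping each simulated site's derived state with probability $m$, so
observed and null H are biased identically. The estimator is a stated
package decision — simulation tests confirm it tracks the realized
misorientation rate — and is deliberately simple; it can be replaced by
orienting with a second outgroup when one is available.

**Rank p-values** use the pseudo-count convention
$r = (\#\{sim \le obs\} + 1)/(n+1)$, $q = (\#\{sim \ge obs\} + 1)/(n+1)$,
one-tailed $p = r$, two-tailed $p = \min(1, 2\min(r, q))$. The
symmetric $q$ (rather than $1-r$) keeps p strictly positive in both
tails. Simulations in which a statistic is undefined (no segregating
site in the relevant subset) are dropped for that statistic and the
used count is reported.

## HKA and ML-HKA

`hkaCounts` reduces each gap-excluded candidate alignment with outgroup
to (S, D, L): segregating sites, fixed differences and comparable sites.
The classic pairwise test estimates per-locus $\theta_i L_i$ and the
divergence time $T$ (coalescent units) from the standard moment
equations — with a single outgroup sequence the species-size ratio is
fixed at $f = 1$, giving $E[D_i] = \theta_i L_i (T + 1)$ — and refers
$\chi^2 = \sum (obs-exp)^2/\mathrm{Var}$ with
$\mathrm{Var}(S) = E[S] + (\theta L)^2 b_n$ and
$\mathrm{Var}(D) = E[D] + (\theta L)^2$ to $\chi^2_1$.

The maximum-likelihood extension multiplies locus $i$'s
population-scaled mutation rate by a selection parameter $k_i$:
$S_i \sim \mathrm{Pois}(k_i \theta_i L_i a_{n_i})$ and
$D_i \sim \mathrm{Pois}(\theta_i L_i (T + (1+k_i)/2))$, with $k_i$
entering the ingroup half of the ancestral-polymorphism term. $k<1$
flags a diversity deficit (sweep-like), $k>1$ an excess
(balancing-like). The $\theta_i$ are profiled out analytically; $T$ and
the selected $k$'s are maximized numerically on the log scale
(L-BFGS-B, convergence tolerance $10^{-8}$ relative on the
log-likelihood, multiple starts). The neutral optimum is always one
start, so the likelihood-ratio statistic is non-negative by
construction; its degrees of freedom equal the number of selected loci.

## Pairwise dN/dS

The ortholog analysis is tree-free: Nei–Gojobori (1986) counting over
all taxon pairs. Synonymous site fractions per codon are the fraction of
one-step changes preserving the amino acid (changes to stop codons are
not synonymous); multi-difference codons average the difference counts
with equal weight over the orderings of single-step paths, excluding
paths through stop codons (if every path is blocked, all paths are used
and stop-crossing steps count as nonsynonymous — a rare fallback);
proportions are corrected as $d = -\tfrac34 \ln(1 - \tfrac43 p)$.
Saturation ($p \ge 3/4$) yields a flagged undefined rate; $\omega$ is
undefined (never 0 or $\infty$) when $d_S$ is undefined or 0.

## Pathway position analysis

Pathway positions are ordinal indexes counted in enzymes from the most
upstream gene; a gene acting at several steps is indexed at its most
upstream one, which ties the two lycopene cyclases. The defaults are
(1, 2, 3, 4, 4, 5, 6) for IPI, PDS, CRTISO, LCYB1, LCYE, CHXE, ZEP;
Kendall's $\tau$ only uses the order and the ties, so any
order-preserving override gives identical correlations. Per gene, all
neutrality-test p-values (three statistics over pooled, geographic and
color sample sets) are pooled and correlated with position via
tie-corrected $\tau_b$ (exact p-value for $n \le 30$ without ties,
normal approximation with tie correction otherwise — pooled p-value
vectors are tied by construction, hence the midrank-based default);
a Kruskal–Wallis test asks whether the p-value location differs among
genes at all, and a Wilcoxon rank-sum test compares genes upstream of
the central metabolic node (IPI, PDS, CRTISO) with those downstream
(LCYB1, LCYE, CHXE, ZEP).

## The synthetic-data generator

`syntheticScenario`/`generateStudyBundle` produce complete study-shaped
datasets with known truth. The default conditions: 46 individuals (24
West, 22 East; colors white 6, yellow 10, orange 18, red 6, purple 6),
7 candidate genes of 600–1000 bp (PDS at 911 sites), 3 anonymous
sequence controls and 17 dinucleotide microsatellites;
$N_W = N_E = N_A = 2\times10^4$, $T_d = 500$ generations,
$\mu_{seq} = 5\times10^{-8}$, $\mu_{SSR} = 5\times10^{-4}$,
$P_{SSR} = 0.22$; outgroup divergence $2.4\times10^6$ generations
(about 0.24 substitutions per site, a deep congener). These were chosen
once as a realistic crop-diversity setting (per-site $\theta \sim$ a few
per thousand, SSR diversity of 10–15 alleles per locus) and are not
tuned per analysis.

Selection regimes on candidate genes:

* **sweep** — all three population sizes are scaled by $1/c$
  (default $c = 6$), contracting the within-species coalescent
  six-fold while outgroup divergence is untouched: low $\pi$, high
  divergence/polymorphism ratio, $k \approx 1/c$ in ML-HKA.
* **balancing** — the sample is split into two allelic classes whose
  genealogies join only at $12 \times 2N_A$ generations. The forced deep
  split is a structural emulation (not forward simulation): it cheaply
  produces the intermediate-frequency excess, elevated diversity and low
  differentiation that the tests target, with Tajima's D typically in
  the +2 to +3 range. The split age was fixed once at the value giving
  that effect size. Class membership can be correlated with a focal
  color (default association 0.8 at LCYB1), so the color-FST test has a
  planted signal.
* **neutral** — a plain divergence-model draw.

What the generator does *not* emulate: recombination within loci,
migration after divergence, size changes, sequencing error, missing
data, and linkage between loci. Passing tests therefore demonstrate
internal statistical correctness of the pipeline under its own model
class, not robustness to those real-data complications.

## Numerical and design choices

* Gap-containing columns are excluded everywhere (alignment columns with
  `-` in any row, including the outgroup); columns containing `N` or
  more than two ingroup alleles are excluded from SFS-based statistics
  entirely — the simplest defensible rule for the rare triallelic site.
* Coordinates are 0-based half-open internally; reports are 1-based.
* Undefined statistics are explicit `NA`s and are propagated (and
  counted) rather than silently replaced.
* Haplotype counting is exact string equality after gap exclusion.
* Statistics use all gap-free polymorphic sites; silent-site diversity
  can be computed separately when an exon/intron annotation is attached
  to the alignment.
* Orientation happens once on the full alignment; group subsets inherit
  it (computing H within a subset re-uses the full-sample orientation).
* Seeded determinism end to end: `runFullStudy` reruns byte-identically
  under a fixed config.

## Problem sizes

The package's default and documented analysis sizes are desk-scale:
reference tables of $10^4$–$2\times10^4$ simulations (tolerance
$10^{-2}$), 2000 null simulations per gene, 200 posterior predictive
draws, 2000-replicate calibration experiments, and 50-replicate coverage
experiments. All are plain arguments; raising them (e.g. to $10^6$
reference simulations and $10^4$ nulls per gene) changes only runtime.

## Worked example

```{r example, eval = FALSE}
scenario <- syntheticScenario(seed = 1)
bundle <- generateStudyBundle(scenario)
res <- runFullStudy(bundle, config = list(abcSims = 10000L,
                                          nullSims = 2000L, seed = 1L))
res$neutrality$fst
res$pathway$correlation
```

## Known limitations

* The misorientation estimator uses total ingroup–outgroup divergence;
  within-species polymorphism inflates $d$ slightly at shallow
  divergences.
* The HKA divergence count uses fixed differences with $f = 1$; with a
  very large outgroup population or very recent divergence the moment
  expectations would need the two-population $f$ term.
* ML-HKA assumes free recombination between loci and none within.
* The balancing regime plants a single ancient biallelic split;
  multi-allelic balancing or frequency-dependent selection will look
  quantitatively different.
* Color-group tests assume the color composition is fixed and known;
  uncertainty in phenotype assignment is not modelled.
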