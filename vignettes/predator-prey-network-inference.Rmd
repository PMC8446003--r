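---
title: "Inferring obligate predator-prey interactions from OTU time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring obligate predator-prey interactions from OTU time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balonet)
```

## The inference problem

Bdellovibrio and like organisms (BALOs) prey obligately on gram-negative
bacteria. In a community sampled repeatedly over a year, sustained
predation leaves a temporal signature: when a predator population is
high its preferred prey is suppressed, and when the predator wanes the
prey recovers. Over a series of samples this produces a strong
*negative* monotone association between the two relative-abundance
series — the Kill-the-Winner (KtW) signature. `balonet` screens every
(predator OTU, prey OTU) pair for that signature and assembles the
survivors into a bipartite interaction network.

The screen is deliberately simple: Kendall's rank correlation with a
hard gate, no time-lag modelling, no compositionality-aware estimator.
Its power and its blind spots are characterised below.

## The screening statistic

For aligned series $x, y$ of length $n$ we use tie-corrected Kendall
$\tau_b$:

$$\tau_b = \frac{C - D}{\sqrt{(n_0 - n_1)(n_0 - n_2)}},$$

where $C$ and $D$ count concordant and discordant sample pairs, $n_0 =
n(n-1)/2$, and $n_1, n_2$ count tied pairs within each series. Count
series contain many tied zeros, so the tie correction matters: it
removes uninformative tied pairs from the denominator rather than
diluting $\tau$ with them.

Significance is two-sided. For $n \ge 9$ the null variance of $C - D$
uses the standard tie-corrected normal approximation; for $n < 9$ the
null distribution is enumerated exactly over all $n!$ pairings of the
two observed value multisets (valid under ties). Series with zero
variance have undefined $\tau$ and can never become edges.

An edge is retained iff $\tau < \tau_{\max}$ **and** $p < \alpha$, with
defaults $\tau_{\max} = -0.7$ and $\alpha = 0.01$. The $\tau$ gate is
the principal sieve: at $n = 18$ the null standard deviation of
$\tau_b$ is about 0.17, so $-0.7$ sits more than $4\sigma$ into the
tail and, as the acceptance suite verifies on $10^4$ independent noise
pairs, the joint gate removes well over 99.5% of possible pairs. No
multiple-testing correction is applied by default — the hard $|\tau|$
gate already dominates the familywise behaviour — but Benjamini–Hochberg
adjustment is available (`p_adjust = "BH"`).

The full screen is vectorized: each series is reduced to its
$n(n-1)/2$-vector of pairwise signs, after which $C - D$ for every pair
of series is a single matrix product and $\tau_b$ is the cosine
similarity of sign patterns. The matrix path is tested cell-by-cell
against the scalar statistic and against `stats::cor.test`.

## Pre-network filtering

Three filters precede the screen, in this order:

1. **Read filter.** Within one site-fraction series, an OTU must have
   *strictly more than* `min_reads = 10` reads summed over the series.
   The threshold is interpreted per series (not per sample); a
   per-sample variant is available.
2. **Gram-positive removal.** Prey candidates whose phylum is
   Actinobacteria or Firmicutes are removed — obligate predators of this
   guild cannot attack gram-positive cells, so any correlation with them
   is necessarily indirect. OTUs with unresolved phylum are
   conservatively retained; predator OTUs are never removed.
3. **Relativization.** Counts are divided by each sample's *total*
   sequencing effort of the complete table, so dropping OTUs does not
   change the denominators. Correlations run on these relative
   abundances; zeros are genuine observations, not missing data.

## Network description

The inferred network is strictly bipartite (predators vs prey) with at
most one edge per pair. Topology statistics follow common practice:

- degree means are reported with the **standard error** of the mean
  (configurable to the standard deviation);
- communities come from Louvain modularity maximization at resolution 1.
  The sweep is randomized, so it is restarted from ten derived seeds and
  the best partition kept, making the result deterministic given the
  seed; graphs with at most 12 nodes are instead solved to the exact
  modularity optimum. Modularity is Newman–Girvan $Q$ on the bipartite
  graph directly (no projection);
- average path length and diameter are computed over reachable pairs
  only, since screened networks are usually disconnected;
- the global clustering coefficient is structurally zero for a bipartite
  graph — reporting it is a built-in sanity check.

Prey-range overlaps are reported as Venn region counts with percentages
of the union. Printed shared-OTU percentages mix two denominators in the
field's reporting style (shared over pairwise union vs over one
collection's total), so `overlap_pair()` emits both, labelled.
Percentages are rounded half-up to one decimal.

## Community statistics

- Shannon $H = -\sum p \ln p$; Simpson is reported as the Gini–Simpson
  index $1 - \sum p^2$; evenness is Pielou's $H / \ln S$.
- Bray–Curtis dissimilarity $1 - 2\sum \min(x_i, y_i) / (\sum x_i + \sum
  y_i)$; it is a semi-metric, so no triangle inequality is asserted.
- PCoA is classical scaling of $-D^2/2$ after double centring. Negative
  eigenvalues (expected for Bray–Curtis) are reported but excluded from
  the proportion explained; no Cailliez/Lingoes correction is applied.
- MRPP uses group-size weights $n_g/N$, observed
  $\delta = \sum_g (n_g/N)\,\bar d_g$, chance-corrected agreement
  $A = 1 - \delta_{obs} / \overline{\delta_{perm}}$ and
  $p = (1 + \#\{\delta_{perm} \le \delta_{obs}\}) / (1 + B)$ with
  $B = 999$ permutations by default. `exact = TRUE` enumerates all
  distinct label assignments instead — feasible for small groups and
  used to validate the permutation mode.
- Environmental correlations are per-OTU Pearson $r$ against an aligned
  covariate (temperature by default); the aggregate over a stated OTU
  subset is the mean and *sample* (n − 1) standard deviation of $|r|$.
  Which OTUs enter the aggregate is an explicit argument, since
  different subsets (all OTUs, the five most abundant, one clade) give
  different summaries.

## The synthetic community generator

`simulate_dynamics()` provides ground truth for validating the screen.
It is a discrete-time (Ricker-type) stochastic generalized
Lotka–Volterra community on a daily grid:

$$x_i(t+1) = x_i(t)\exp\!\big(r_i(t)\,(1 - x_i/K_i) - \textstyle\sum_j a_{ij} y_j + \varepsilon_x\big),$$
$$y_j(t+1) = y_j(t)\exp\!\big(-d_j + c\,\textstyle\sum_i a_{ij} x_i + F_j(t) + \varepsilon_y\big),$$

observed at the study calendar (12 monthly samples plus two runs of
extra weekly samples; 18 points), with abundances floored at $10^{-9}$
of community biomass to mimic detection limits and keep the log-domain
stable.

Deliberate structural choices, each of which proved necessary:

- **Per-prey niches.** Each prey has its own carrying capacity $K_i$,
  drawn log-normally (sd 1.5) to give the long-tailed species-abundance
  distribution of real 16S surveys. A single shared capacity does not
  work: unpredated competitors pin the community total at $K$ and
  predator equilibria collapse to zero.
- **Suppression sweet spot.** The predator equilibrium sets its primary
  prey at $x^* = d/(c\,a)$. For the KtW signature to be *detectable at
  zero lag*, $x^*/K_i$ must sit roughly in 0.3–0.5: much deeper and the
  prey's logistic self-regulation vanishes, turning log-prey into an
  integrator of predator history (a 90° phase shift that destroys the
  rank correlation); much shallower and the prey barely moves. Defaults
  (`attack_rate` 8,000–14,000 per unit predator abundance per day,
  `conversion` 0.00128, `decay_rate` 0.04–0.08/day) put typical
  readable prey in that band.
- **Predator biomass scale.** The map $a \to \kappa a$, $c \to c/\kappa$
  leaves prey dynamics exactly invariant while dividing predator biomass
  by $\kappa$; this sets the predator read fraction to the observed
  0.1–1% of the community (the default lands near 0.5%) without touching
  detectability.
- **Individual predator rhythms.** Each predator carries an annual
  forcing component whose phase is jittered (sd 60 d) around the
  temperature peak — so predators are temperature-linked on average but
  do not move as one block — plus two sub-annual components with its own
  periods (40–200 d). The two-tone rhythm is what the observed
  weeks-to-season oscillations look like, and it is also what keeps
  predators statistically distinguishable: with a single shared seasonal
  mode, every predator of similar phase would correlate with every other
  predator's prey and indirect false edges dominate.
- **KtW targeting and niche partitioning.** A prey's chance of being
  attacked scales with its niche size (`ktw_exponent = 0.6`) —
  frequency-dependent predation concentrates on winners — while each
  claimed prey's weight for further predators decays
  (`partition_strength = 2`), reproducing the strong prey-range
  partitioning seen in such communities (about half of prey OTUs unique
  to a single predator). Each predator's first-claimed prey takes an
  attack coefficient from the full range; later claims are weak, giving
  a prey-preference hierarchy.
- **Two microhabitats.** Floc and liquor are separate compartments
  sharing all predators but only 15% of prey, matching the observed
  segregation of prey but not predators between fractions.

Read sampling is multinomial per sample (`sample_reads()`), and
`sample_study_reads()` draws the study's three sequencing pools — a
general 16S pool (default 5,000 reads/sample at desk scale) plus
dedicated high-depth pools for each predator clade — so predator series
have full within-clade resolution, as in the real design.
`latent_tables()` exposes the noise-free compositions, i.e. the
unbounded-depth observation limit.

What the generator does **not** emulate: bdelloplast life-cycle delays,
phage and protist guilds, spatial floc microstructure, primer and copy
number biases, and OTU-clustering artefacts. Passing recovery tests on
this generator therefore says the screen works *when its assumptions
hold*, not that every real edge is recoverable.

## What recovery experiments show

Edge recovery is scored on (predator, prey) identity against the true
adjacency, restricted to the pair universe the screen actually examined;
precision and recall are reported as absent (not 0/0 = 0) when
undefined.

Two findings from the validation suite shape how results should be
read:

1. **On latent compositions** the gate is conservative and sound: across
   20 simulated communities at the 18-point design, mean precision is
   above 0.9 (false edges are rare, and those that occur are indirect —
   prey of a predator whose rhythm happens to align), and recall
   increases when the year is sampled at 50 weekly points instead of 18,
   as statistical power should.
2. **Under read sampling at survey depth**, counting noise attenuates
   the sampled $\tau$ of true pairs toward zero. With a hard absolute
   gate this has a counter-intuitive consequence: pairs whose expected
   sampled $\tau$ sits just above $-0.7$ are detected at $n = 18$ mainly
   through estimator variance, so *lengthening* the series can *reduce*
   recall while precision rises — a selection-at-threshold effect, not a
   bug. Detected edges concentrate on abundant prey; rare-prey links are
   systematically missed. Precision, however, remains high in both
   regimes, which is the property the screen is designed around: its
   product is a set of high-confidence candidate links, not a complete
   food web.

The acceptance script (`scripts/acceptance.R`) recomputes both
experiments, the null-sieve selectivity, and a complete read-sampled
desk analysis from scratch on every run.

## Numerical and reproducibility choices

- Dates are ISO-8601; sample order is by date, ties broken by sample id.
- All randomness flows through explicit integer seeds
  (simulation, read sampling, Louvain restarts, MRPP permutations);
  repeated calls with the same seed are bit-identical.
- The screen's gates are strict inequalities; boundary values
  ($\tau = \tau_{\max}$, exactly 10 reads) are excluded, matching the
  "more than" / "less than" wording of the conventions it follows.
- Degenerate inputs error early with the offending identifier (zero-read
  samples at relativization, duplicated ids, singleton MRPP groups,
  edgeless networks for modularity).

## Problem sizes

The validation experiments use the desk-scale design throughout: 200
prey and 10 + 10 predators per site, 18 (or 50) time points, 5,000
general reads per sample, 20 replicate seeds. One simulate–sample–screen
cycle takes well under a second, the full test suite about two minutes,
and the acceptance script a few seconds, so the whole analysis is
comfortably interactive; the `"full"` design (3 sites, ~3,600 prey,
~170 predators, 35,000 reads) runs the same code unchanged for users
who want study-sized synthetic data.

## Limitations

- Zero-lag rank correlation misses genuinely lagged interactions and
  oscillations faster than the sampling interval.
- Compositional closure can induce spurious negative correlation in
  low-diversity tables; with hundreds of OTUs the effect is small, but
  the estimator is not compositionality-aware by design.
- The τ gate's recall depends strongly on read depth and prey abundance;
  absence of an edge is weak evidence of absence.
- MRPP and the KS tests assume exchangeable samples; yearly time series
  are autocorrelated, so their p-values are descriptive rather than
  strictly valid for temporal groupings.
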