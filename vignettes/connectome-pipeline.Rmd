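---
title: "Density-thresholded connectome analysis with conngraph: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-thresholded connectome analysis with conngraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conngraph)
```

## The analysis this package implements

`conngraph` takes region-by-time signal matrices — the kind produced by
averaging a BOLD time series over each region of a whole-brain
parcellation — and carries them through the standard graph-theoretic
connectome pipeline:

1. **Construction.** Pearson correlation between every pair of regional
   time courses, Fisher r-to-z transformed, then *proportional
   thresholding*: at a target density $\delta$ exactly
   $k = \mathrm{round}(\delta\, n(n-1)/2)$ of the strongest links are
   kept and binarised. Holding the edge count fixed — rather than the
   correlation cut-off — is what makes graph measures comparable across
   subjects and sessions, because almost every binary graph measure is
   confounded by density.
2. **Graph measures.** The eight global measures (mean clustering
   coefficient, transitivity, Louvain modularity $Q$, characteristic
   path length $L$, global and local efficiency, the small-world index
   $\sigma$, degree assortativity $r$) and nine nodal centralities
   (degree, betweenness, closeness, eigenvector, PageRank, K-coreness,
   subgraph centrality, participation and diversity coefficients
   against the six-module functional partition).
3. **Null models.** $\sigma = (C/\langle C_{null}\rangle) /
   (L/\langle L_{null}\rangle)$ requires degree-preserving random
   references; these are Maslov–Sneppen double-edge-swap ensembles
   (default 20 members, 10 attempted swaps per edge).
4. **Group statistics.** The study design is 13 subjects measured under
   two conditions — rested wakefulness (RW) and chronic sleep
   restriction (SR) — at four times of day (10:00, 14:00, 18:00,
   22:00). Each measure, at each density of the canonical sweep
   $\delta \in \{0.06, 0.07, \ldots, 0.30\}$ (25 densities), is
   analysed with a 2 × 4 within-subject ANOVA; p-values are adjusted by
   Benjamini–Hochberg FDR across the 25 densities; per-time paired
   contrasts compare SR against RW; and a region-flagging rule reports
   the nodes significant in more than half of the thresholded graphs
   (≥ 13 of 25).

The experimental data this design mirrors are not publicly deposited,
so the package ships a first-class synthetic-cohort generator with
*planted* effects. Every downstream stage can therefore be validated
against known ground truth: the statistics must rediscover exactly what
the generator hid, starting from raw time series.

## The generative model

Each recording draws stationary AR(1) latent series with unit marginal
variance and lag-1 autocorrelation $\varphi = 0.3$, a plain surrogate
for BOLD autocorrelation at TR = 3 s (the measured lag-1 autocorrelation
of task fMRI at 3 s sampling is typically 0.2–0.4). There is a global
series $g$, a specific series $u_k$ per module, a hub series $h$, and a
latent per wired connector pair (below). The module signal is

$$m_k = \gamma\, g + \sqrt{1-\gamma^2}\, u_k, \qquad \gamma = 0.9,$$

so $\gamma$ ("betweenCoupling") is the coherence of the modules with
the global signal. An ordinary region in module $k$ is

$$x_i = w\, m_k + \sqrt{1-w^2}\,\varepsilon_i, \qquad w = 0.6 .$$

Every regional variance is normalised to 1, so couplings translate
directly into correlations: within-module $r = w^2 = 0.36$,
between-module $r = w^2\gamma^2 \approx 0.29$. The deliberately small
gap between the two matters: under proportional thresholding a planted
effect is visible *only if it changes which links rank above the
cut-off*. With the gap of roughly one to two correlation-noise
standard deviations ($\mathrm{sd}(r) \approx 0.04$ at 840 timepoints),
the marginal retained edges at mid-range densities are a mixture of
weak within-module and strong between-module links, and coupling-level
effects propagate into the binary graphs.

Three structural ingredients sit on top:

* **Hubs** — deterministically the *first region of each module*, so no
  circularity with measured centrality. A hub carries a constant extra
  loading (`hubBoost` = 0.25) on its module-specific signal, making it
  the top-degree node of its module, plus a loading
  (`hubCoupling` = 0.5) on the shared hub series that inter-correlates
  the six hubs into a mutually connected club.
* **Connector blocks** — the 12 regions after the hub in each module.
  Each connector is wired to exactly three partner connectors in one
  other module through dedicated shared latents whose variance is set
  at generation time so every wired pair reaches the same correlation
  (`bridgeCoupling` = 0.42) regardless of its module pair's baseline.
  A connector's expected between-module degree is therefore identical
  in every session and condition. Blocks in the two largest modules get
  a positive loading contrast (+0.22) on their module signal and blocks
  in the two smallest a negative one, so connectors in large modules
  are high-degree and connectors in small modules low-degree.
* **Subject jitter** — each subject's couplings are perturbed by a 5 %
  coefficient of variation, constant across that subject's eight
  recordings (a genuine within-subject design).

### The planted condition effect

In SR, $\gamma$ is scaled by $1 - 0.15$. Between-module correlations
drop while within-module correlations are mathematically untouched
($w^2$ does not involve $\gamma$). At fixed density the SR networks
therefore retain fewer diffuse inter-module shortcuts and more marginal
within-module links: they are more segregated, and the characteristic
path length rises. This is the mechanism by which reduced global
integration — the standard interpretation of a longer path length under
sleep restriction — is planted at the *coupling* level, seven
processing steps away from the statistic that must detect it. A naive
alternative (reducing within-module coupling in SR) does the opposite:
it makes the thresholded network *more* random and so shortens the path
length; proportional thresholding is also scale-invariant, so uniform
rescalings of a whole correlation stratum that do not cross the ranking
boundary produce no binary effect at all.

### The planted time-of-day effect

Two components, chosen so that the two signatures live at different
levels of the analysis:

* **Hub decay** (nodal signature). Both hub couplings are scaled by
  $1 - \tfrac{1}{3}(s-1)$ across sessions $s = 1..4$: by 22:00 the hub
  club has dissolved and each hub has decoupled from its module. The
  six hubs — and only they — carry a strong nodal time effect on
  degree, which the Table-2-style flagging rule must recover. The
  freed edge slots redistribute diffusely across the remaining 110
  regions, well below the flagging threshold.
* **Mixing rotation** (global signature). The wired partner assignment
  of the connector blocks rotates: in session 1 all wirings join
  degree-similar module pairs (largest with second largest, and so on);
  by session 4 a third of the slots at a time have been rewired to the
  degree-dissimilar pairing (largest with smallest). Edge *counts*
  never change — only who is wired to whom — so nodal degrees carry no
  time signature, but high-degree/high-degree edges are progressively
  replaced by high/low edges and the network's degree assortativity
  declines monotonically across the day in both conditions.

The separation is deliberate: degree assortativity is a property of
which *pairs* connect, not of the degree sequence, so it can be moved
without moving any nodal degree. Conversely an effect confined to six
of 116 regions cannot move a global mixing coefficient by much more
than its own sampling noise — the assortativity of a single
thresholded network fluctuates on the order of $1/\sqrt{E}$ and more
in structured regimes — which is why the global decline cannot
honestly be driven by the hubs alone.

## Parameters that matter, and defaults

| parameter | default | unit / meaning |
|---|---|---|
| `nSubjects`, design | 13 × 2 × 4 | subjects × conditions × sessions |
| `nRegions`, `nTimepoints`, `trSeconds` | 116, 840, 3.0 | 42-min task at TR 3 s |
| `withinCoupling` $w$ | 0.6 | within-module $r = 0.36$ |
| `betweenCoupling` $\gamma$ | 0.9 | between-module $r \approx 0.29$ |
| `conditionEffect` | 0.15 | $\gamma$ reduction in SR |
| `timeEffect` | 1/3 | per-session hub-coupling decrement |
| `hubCoupling`, `hubBoost` | 0.5, 0.25 | hub club / top-degree loadings |
| `bridgeCoupling` | 0.42 | planted wired-connector correlation |
| `bridgeBlockSize`, `blockContrast` | 12, 0.22 | connectors per module, degree contrast |
| `arCoefficient` $\varphi$ | 0.3 | lag-1 autocorrelation of all series |
| `subjectSd` | 0.05 | between-subject CV of couplings |

The couplings were calibrated once, before the validation suite was
frozen, so that the three planted outcomes hold with comfortable
statistical margins under the full design; the suite then verifies
exactly that: the SR path-length excess at $\delta = 0.18$ and the
strictly monotone assortativity decline (per-network assortativity
averaged over $\delta = 0.12$–$0.22$, session means over subjects)
each in at least 95 % of 200 replicate cohorts, all six hubs flagged
by the degree panel with a non-hub false-flag rate of at most 5 %.
The couplings are the study conditions of the synthetic design, not
tuning knobs, and the validation thresholds were not revisited after
calibration.

## Numerical and procedural choices

* **Fisher z clipping.** $|r|$ is clipped to $1 - 10^{-7}$ before
  $\operatorname{atanh}$, so duplicated series yield a large finite
  $z \approx 8.4$ instead of infinity.
* **Edge-count rounding** is round-half-away-from-zero, documented
  because base R rounds half to even.
* **Tie-breaking.** Ties at the threshold cut are resolved by ascending
  (row, column) index order. This makes thresholding deterministic and
  gives the density sweep exact monotone nesting: the edge set at
  $\delta_1 < \delta_2$ is a subset of the edge set at $\delta_2$.
* **Signed ranking.** Links are ranked by signed z (strongest positive
  correlations survive); `absolute = TRUE` switches to $|z|$ ranking.
* **Fragmentation.** $L$ averages over reachable pairs only and sets a
  `fragmented` flag; global efficiency (where $1/\infty = 0$) is the
  fragmentation-safe companion. Closeness is component-scaled
  (Wasserman–Faust). Rewired null members are not guaranteed connected
  and are handled by the same conventions.
* **Eigenvector and PageRank.** The eigenvector is the principal
  eigenvector of the symmetric adjacency (unit Euclidean norm,
  non-negative orientation); on a graph with several components it is
  well-defined only up to the dominant component. PageRank uses power
  iteration to an L1 tolerance of $10^{-12}$ with uniform teleport and
  uniform redistribution of dangling mass.
* **Modularity.** Louvain at resolution 1 over 10 seeded restarts; best
  Q wins, exact ties go to the lexicographically smallest membership.
* **Small-world index.** The classical $\sigma$ with degree-preserving
  nulls is computed knowingly: it is density-dependent and can misread
  lattices, which is documented rather than "fixed" — alternative
  indices are out of scope.
* **ANOVA.** The within-subject decomposition is computed directly from
  sums of squares, each effect tested against its subject-by-effect
  interaction (`F_condition` on (1, n−1) df; `F_time` and the
  interaction on (3, 3(n−1)) df); `stats::aov` with `Error` strata is
  used as an independent cross-check in the test suite. Sphericity is
  uncorrected by default; a Greenhouse–Geisser option estimates
  $\varepsilon$ from orthonormal contrasts of the within-subject
  covariance. Cells with zero error variance raise an error from
  `rmAnova()` and become `NA` (with a warning) inside `anovaPanel()` so
  sweeps do not abort.
* **FDR family.** The default correction family is the 25 density-level
  p-values per measure × node × factor, matching "25 tests per
  measure"; `family = "measures"` widens it. Post hoc contrasts are
  uncorrected by default with a Bonferroni switch.
* **Participation/diversity partition.** The a priori six-module
  partition is the default; pass the `modularityPartition()` result to
  use a data-driven one instead. The packaged region-to-module map
  follows conventional functional groupings (the cerebellar module is
  exactly regions 91–116); it is the package's own assignment, intended
  for module-resolved summaries rather than as a reference atlas.

## What the synthetic data do and do not emulate

The generator reproduces the *statistical structure the analysis
assumes*: modular correlated signals with realistic autocorrelation,
within-subject factorial design, between-subject variability, hubs,
connectors, and effects planted at the coupling level so that they must
survive correlation, thresholding, graph measurement and group
statistics to be seen. It does **not** emulate hemodynamic convolution,
scanner drift and motion artifacts, physiological noise, spatial
autocorrelation between neighbouring parcels, task-locked transients,
or heavy-tailed noise. Passing tests therefore demonstrate that the
pipeline's inferential machinery is correct and calibrated — not that
any particular empirical brain result would replicate.

Two reporting subtleties discovered during validation are worth
knowing. First, a condition effect that shifts the retained-edge
composition necessarily redistributes degree between regions, so nodal
*condition* effects appear broadly across regions in the synthetic
cohort; the false-flag guarantee concerns the *time* factor, whose
planted nodal signature is confined to the hubs. Second, the rotation
moves eigenvector and PageRank centralities diffusely (they respond to
global structure), so region flagging for the time factor is assessed
on nodal degree, the canonical centrality whose planted signal is
hub-confined.

## Problem sizes used by the validation suite

The acceptance tests run 200 replicate cohorts of the full design
(104 recordings of 840 × 116 each) for the directional checks, 200
random graphs with $n \le 12$ against brute-force oracles, 1000 null
panels for type-I calibration, and two full cohorts through the
25-density degree panel for region flagging. `scripts/acceptance.R`
reports the same quantities with 40 replicate cohorts for the
directional percentages. These sizes give the binomial margins quoted
above while keeping a complete run in the tens of minutes on one CPU.

## Known limitations

* Binary undirected graphs only; no weighted variants of the measures.
* The classical $\sigma$ small-world index only.
* The generator's planted effects are large by design (they are meant
  to be recovered reliably at n = 13); real effect magnitudes under
  sleep restriction are unknown and likely far smaller.
* `rmAnova()` requires a complete balanced design; missing cells are an
  error, not an imputation problem this package attempts to solve.
* Region flagging inherits the arbitrariness of the "more than half of
  the densities" rule; it is reproduced as specified, not endorsed.

## A minimal run

```{r example, eval = FALSE}
cfg <- synthConfig(seed = 1)
out <- runPipeline(cfg, "run1",
                   globalMeasures = c("path_length", "assortativity"),
                   localMeasures = "degree")
head(out$contrasts)                     # SR vs RW per time of day
subset(out$roi, flagged_time)           # regions with a diurnal signature
```
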