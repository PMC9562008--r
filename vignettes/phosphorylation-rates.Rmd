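---
title: "Quantifying phosphorylation rates from 2-DE spot volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phosphorylation rates from 2-DE spot volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoRate)
```

## The measurement model

A 2-DE phosphoproteome experiment produces three gel profiles per
biological replicate:

* **reference** — total-protein stain (Sypro Ruby type), volume $T$;
* **phospho** — phosphoprotein-specific stain (Pro-Q Diamond type),
  volume $P$;
* **dephospho** — total-protein stain after chemical removal of phosphate
  groups with hydrogen fluoride–pyridine (HF-P), volume $D$.

Per matched spot and replicate the two phosphorylation-rate statistics are

$$\mathrm{PR}_{\text{Pro-Q}} = 100\,\frac{P}{T}, \qquad
  \mathrm{PR}_{\text{HF-P}} = 100\,\frac{T - D}{T},$$

both estimating the same quantity — the fraction of the spot's protein
carrying phosphate — through different physics. Both are forced into
$[0, 100]$ by conventions the data make necessary:

* $P > T$ reads as $\mathrm{PR} = 100$. This is not an edge case: volumes
  are normalized per gel to a fixed total density, and phosphostain gels
  carry far fewer spots than reference gels, so normalized $P$ is
  systematically inflated. The clamp absorbs that inflation (at the cost
  of compressing genuinely high rates against 100).
* A spot absent from the phosphostain profile (or failing the replicate
  detection rule there) has $\mathrm{PR}_{\text{Pro-Q}} = 0$.
* A spot that disappears after dephosphorylation has
  $\mathrm{PR}_{\text{HF-P}} = 100$.
* A replicate with $D > T$ has no applicable dephosphorylation rate, and
  the package marks the **whole spot** N/A as soon as any usable
  replicate is N/A. The alternative — dropping the offending replicates
  and averaging the rest — censors exactly the negative half of the
  measurement noise and biases unphosphorylated spots toward positive
  rates; with the spot-level rule an unphosphorylated spot ends up N/A or
  near zero, which is also how such spots present in published
  per-spot tables (N/A across mean, CI and p columns).

One further rule connects the estimate to gel geometry: the HF-P
statistic measures volume loss *at the spot's original position*. If the
dephospho consensus position of a pre-matched spot lies farther than
`position_tol` (default 0.01 gel fractions, the coordinate-matching
tolerance) from its reference position, the original position is treated
as vacated — $D$ absent, $\mathrm{PR} = 100$. Coordinate-mode matching
can never pair spots beyond the tolerance box, so this keeps pre-matched
and coordinate inputs consistent; without it, a fully phosphorylated spot
whose dephosphorylated form migrates to a nearby basic position would
read $\mathrm{PR} \approx 0$.

## Uncertainty: BC percentile bootstrap at N = 3

Per spot and method, the mean rate over the $N$ replicates is
bootstrapped: $B$ resamples of size $N$ with replacement (defaults
$B = 2000$, $N = 3$), resample means $\theta^*$, and the bias-corrected
percentile interval with

$$z_0 = \Phi^{-1}\!\left(\frac{\#\{\theta^* < \hat\theta\}}{B}\right),
\qquad
\text{levels } \Phi\!\left(2 z_0 + z_{\alpha/2}\right),\;
\Phi\!\left(2 z_0 + z_{1 - \alpha/2}\right).$$

No acceleration constant is used (BC, not BCa). Numerical choices forced
by the tiny sample:

* With $N = 3$ the resample-mean distribution has only $3^3 = 27$
  equiprobable atoms, so ties $\theta^* = \hat\theta$ are common. They
  count half toward the bias fraction, which is then clamped to
  $[1/2B,\, 1 - 1/2B]$ to keep $z_0$ finite. Tie detection uses a
  relative tolerance of $10^{-9}$ because floating-point column means can
  split exact ties.
* Quantiles use the inverse-empirical-CDF (type 1) definition — fully
  deterministic at small $B$, endpoints always members of the resample
  support. A constant replicate vector therefore yields a zero-width
  interval, matching the $100 \pm 0.0\ (100, 100)$ rows of per-spot
  results tables.
* The test suite checks the Monte-Carlo endpoints against an independent
  oracle that enumerates the 27 atoms exactly and applies the BC level
  shift analytically.

Seeding: one root seed; each spot × method stream is derived as
`root XOR hash(spot_id)` (31-ary string hash modulo $2^{31}-1$), so adding
or removing a spot never perturbs another spot's interval, and identical
configurations reproduce byte-identical outputs.

### Multiplicity and the significance call

Per-spot intervals are built at confidence $1 - \alpha/m$ (Bonferroni,
default $\alpha = 0.05$, $m$ = number of matched spots — the natural
family here; `bonferroni_m` overrides it). Two methods differ
significantly for a spot when the two adjusted intervals are disjoint.
This interval-overlap rule is the reading consistent with result tables
that print per-method CIs next to a single p-value column; it is
conservative (interval overlap can hide differences a direct test would
find). A paired-difference bootstrap
(`significance_rule = "diff_bootstrap"`, methods resampled independently
because HF-P gels are physically separate) is provided as the sharper
alternative. Spots with an N/A mean on either side are `not_comparable`.

Method-level detection counts are compared with a two-tailed Fisher exact
test, implemented from first principles (log-binomial accumulation over
all tables with the observed margins, summing probabilities no larger
than the observed table's at relative tolerance $10^{-7}$). A zero margin
returns $p = 1$ with a warning.

## Preprocessing rules

* **Normalization**: each gel (one replicate × profile) is scaled so its
  volumes sum to `normalization_scale` (default $10^6$, ppm-style) —
  "total density of valid spots". Background subtraction is assumed done
  upstream by the image software.
* **Detection rule**: a spot counts as present on a profile only if seen
  in ≥ `min_replicates_detected` replicates (default 2 of 3). One rule is
  reused everywhere: matching, rate computation (a phosphostain signal
  failing it is treated as undetected), and pattern classification.
* **Matching**: pre-matched tables (master ids from the image software)
  are grouped by id. Id-less tables are matched by position: greedy
  mutual-nearest-neighbour pairing within a tolerance box (default
  0.01 × 0.01 gel fractions, ≈ 0.03 pH units on a 4–7 strip), each spot
  used once, ties broken by Euclidean distance; records are put in a
  canonical order first so the result is invariant to input row order.
  Dephospho spots with no reference partner become *novel candidates*
  (kept, with no rate); phosphostain spots with no partner are dropped
  (no denominator).

## Dephosphorylation patterns

Decision order per spot: **novel** (no reference presence) →
**disappeared** (no dephospho presence) → **shifted_basic** (consensus
dephospho pI at least `pi_shift_min` — default 0.05 pH — toward basic;
acidic shifts never fire) → **reduced** (mean $D$ below
$(1 - \texttt{vol\_drop\_min})$ × mean $T$, default drop 10%) →
**unchanged**. Mr displacement is recorded (`delta_logmr`, when a marker
ladder is supplied) but never drives the class, since mass shifts after
dephosphorylation are explanatory rather than categorical. The defaults
are deliberately conservative against typical inter-gel variation; both
thresholds are arguments.

## Gel calibration

pI is the affine image of the strip's linear pH gradient (default 4–7).
Mr interpolates $\log_{10}$(kDa) piecewise-linearly against migration —
the standard SDS-PAGE mobility model — exactly through the marker knots,
and refuses to extrapolate beyond the ladder rather than fabricate
masses.

## The synthetic study generator

`generate_study()` emulates the statistical structure the analysis
assumes, at the scale of the motivating study design: 174 master spots,
3 biological replicates, 450 µg load, pH 4–7 strip.

* Abundances are log-normal (median 50 ng, $\sigma = 0.6$ in
  $\log_{10}$), truncated to [1, 5000] ng; 1 ng renders 1000 volume
  units (arbitrary — only ratios survive normalization).
* True phospho-fraction $f$: point mass at 0 (13% of spots — echoing the
  roughly one-in-eight spots never phosphorylated in studies of this
  design), point mass at 1 (5%, chosen once as a realistic share of
  fully phosphorylated proteoforms), remainder uniform.
  `phospho_frac_min` raises the lower bound when a test needs effect
  sizes separated from classifier thresholds.
* Detection limits: phosphostain spots are emitted only when
  $f \times$ abundance ≥ 4 ng; total-stain spots require 1 ng. An
  optional hard `saturation_cap` emulates ultra-saturated phosphostain
  spots.
* Each emitted volume carries independent log-normal noise
  (`noise_sigma`, default 0.15 on the natural-log scale).
* Dephospho profile: the unphosphorylated residue $(1-f)a$ stays at the
  reference position; phospho-derived mass reappears shifted toward
  basic by `n_phosphates` × `pi_shift_per_phosphate` (default
  0.05 pH per phosphate, 1–3 phosphates with probabilities
  0.5/0.3/0.2). A detectable residue makes the shifted mass a separate
  dephospho-only master (novel partner); an undetectable residue leaves
  a singly-phosphorylated spot tracked at its shifted position
  (shifted_basic) and a multiply-phosphorylated one disappeared, its
  mass becoming the novel partner — mirroring what an image analyst
  would and would not match across a small versus large displacement.

**What the generator does not model**, hence what passing tests cannot
show about real gels: proteoform charge trains (each master spot is one
independent protein, so dephosphorylated material rarely lands on an
existing spot, and the *novel* class is over-represented relative to real
gels, where it would merge into the unmodified form's spot); background
and its subtraction; spatial warping or coordinate jitter (consensus
positions are noise-free); staining non-linearity beyond the optional
hard cap; correlations between replicates.

## Known limitations

* **Normalization offset.** With heavy-tailed abundances a single spot
  can hold ~20% of a gel's total density, so per-gel total-density
  normalization leaves a study-level offset of a few percent between the
  reference and dephospho profiles; the HF-P rate inherits it as a bias
  of a few points on every spot of that study. This is a property of
  total-density normalization itself, visible in the synthetic recovery
  metric the acceptance script reports (at noise $\sigma = 0.05$,
  roughly nine of ten detectable spots land within ±5 points of the
  generating phospho-fraction, the remainder driven by this offset and
  by replicate noise on low-$f$ spots).
* **Undercoverage at N = 3.** BC percentile intervals from three
  replicates undercover; the suite reports the empirical coverage of the
  truth rather than asserting the nominal 95%.
* **Shifted spots.** The position guard assigns shifted spots
  $\mathrm{PR} = 100$; partially phosphorylated proteins whose residue
  is undetectable are therefore rounded up to fully phosphorylated —
  a detection-limit effect, not a numerical one.
* **Phosphostain inflation.** Under per-gel normalization the clamp at
  100 absorbs the phosphostain's smaller gel total; relative comparisons
  between methods remain meaningful, absolute Pro-Q rates less so.

## Problem sizes used in the checks

The acceptance script runs the full published scale — 174 spots ×
3 replicates × both methods at $B = 2000$ (a few seconds on one core) —
plus two further 174-spot studies for recovery and classification. Unit
tests use smaller studies (30–60 spots) and reduced $B$ where only means
or determinism are exercised, and $B = 10^5$ once when pinning the
Monte-Carlo interval against the exact 27-atom oracle.
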