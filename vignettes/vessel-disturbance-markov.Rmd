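---
title: "Markov-chain behavioural budgets under vessel disturbance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov-chain behavioural budgets under vessel disturbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duskybudget)
```

## The problem and the model

Dusky dolphin groups at Kaikoura are scan-sampled from shore every 150 s
during focal follows: at each sample the predominant group activity is one
of five mutually exclusive behavioural states (Resting, Traveling, Milling,
Socialising, Feeding), and the number of vessels — including qualifying
aircraft — within the 300 m interaction threshold is recorded. Successive
samples of the same group are strongly dependent, so the package analyses
the *transitions* between consecutive samples as a first-order
time-discrete Markov chain: the distribution of the next state depends only
on the current state.

Three factors are allowed to modify the transition structure: season
(month-based: Dec–Feb Summer, Mar–May Autumn, Jun–Aug Winter, Sep–Nov
Spring), time-of-day block, and vessel condition. Time of day is
standardised against day length by the daylight index
$(t - \mathrm{sunrise})/(\mathrm{sunset} - \mathrm{sunrise})$, so sunrise
is 0, midday 0.5, sunset 1; blocks are Morning (index $< 0.33$), Midday
($0.33$–$0.66$) and Afternoon ($> 0.66$).

Transitions are assigned to two chains. **Treatment** transitions have at
least one vessel present at both endpoint samples. **Control** transitions
are vessel-free at both endpoints *and* preceded by a fully observed,
vessel-free buffer of 15 min within an unbroken run of samples — this
guards against carry-over of a recent interaction into the "undisturbed"
chain. Everything else is Excluded.

The classified transitions form a five-way contingency table, preceding
$\times$ succeeding $\times$ season $\times$ time block $\times$ condition.
Feeding is removed first: dolphins here feed at night offshore, daytime
feeding is a fraction of a percent of samples, and rows that sparse cannot
be modelled. Transitions touching Feeding are discarded, not bridged —
bridging two 150 s steps would fabricate a 300 s "transition" that the
chain model does not define.

## Log-linear model selection

Hierarchical log-linear models are stated by their generating class. Every
candidate model contains

* `preceding:succeeding` — the Markov association itself, and
* `condition:time_block:season` — the design margin, fixed by the sampling
  scheme rather than by dolphin behaviour.

A factor "affects transitions" through the three-way generator
`preceding:succeeding:factor`; the time-by-season interaction is the
four-way generator `preceding:succeeding:time_block:season`. The lattice
runs from the null model through all combinations of the three factor
effects plus the interaction (ten models).

Each model is fitted by iterative proportional fitting. Misfit is
$G^2 = 2\sum O \ln(O/E)$ with $0\ln(0/E) \equiv 0$; nested models are
compared by $\Delta G^2$ on $\Delta\mathrm{df}$ with an upper-tail
chi-square p-value, and models are ranked by $\mathrm{AIC} = G^2 -
2\,\mathrm{df}$. This deviance form of AIC ranks models of the same table
identically to $-2\ell + 2k$ and is the convention used throughout.
Degrees of freedom are
$(\text{cells} - 1) - \text{free parameters}$, counting one corner
parameter set $\prod_i (d_i - 1)$ for every distinct non-empty subset of a
generator.

## Behavioural budgets and comparisons

The budget under a condition is the stationary distribution $\pi$ of the
row-normalised transition matrix, obtained as the left eigenvector of the
dominant eigenvalue and verified against $\pi P = \pi$ to $10^{-8}$.
Budgets are compared state-by-state between Control and Treatment with the
pooled two-proportion Z test
$z = (p_1 - p_2)/\sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)}$ and 95 % Wald
intervals. Seasonal budgets pool time blocks; diurnal budgets pool seasons,
mirroring how such results are usually displayed.

The effective $n$ for tests and intervals is the number of observed
transitions in the stratum's chain — transitions are the sampling unit of
the Markov analysis. Because transitions within a follow are autocorrelated
this $n$ is optimistic; a percentile bootstrap that resamples whole follows
(`budget_ci(method = "bootstrap")`) is the robust alternative, and per-state
p-values are reported unadjusted by default with an optional Holm flag.

## Tunable parameters

| parameter | default | units | rationale |
| --- | --- | --- | --- |
| `nominal_interval` | 150 | s | the study's scan interval |
| `gap_tolerance` | 30 | s | real scan schedules jitter; larger gaps break the chain rather than fabricate long transitions |
| `control_buffer` | 900 | s | 15 min vessel-free history for Control |
| `states_to_drop` | Feeding | — | < 0.5 % of samples; unmodellable |
| `alpha` | 0.05 | — | conventional two-sided level |
| `ci_method` | wald | — | bootstrap-over-follows available |
| IPF `tol` | 1e-10 | counts | max change per sweep |
| IPF `max_iter` | 1000 | sweeps | far beyond practical need |

## Decisions where the design was genuinely open

* **Block boundaries.** Indices exactly 0.33 or 0.66 go to Midday: the
  boundary description "0.33 to 0.66" is read inclusively against the
  strict "< 0.33" / "> 0.66" of the outer blocks.
* **Out-of-daylight samples.** Pre-sunrise starts do occur (summer tours
  launch before dawn). Indices outside $[0,1]$ are retained, clamped into
  Morning/Afternoon, and flagged with a warning.
* **Stratum of a transition** is taken from its first sample: the
  preceding state anchors the Markov step.
* **Mixed transitions** (vessel at exactly one endpoint) are Excluded;
  assigning them to either chain would contaminate it with an
  arrival/departure boundary.
* **Buffer windows truncated by a follow start or a chain break** are
  treated as insufficient history (Excluded): "no vessels for 15 min" can
  only be asserted about observed samples.
* **Sampling zeros** are retained as zeros. No continuity constant is
  added (any constant shifts every $G^2$ systematically), and df are not
  adjusted for zero margins; zero-margin cells are visible in the fitted
  objects.
* **Reducible chains are an error**, not silently regularised: a budget of
  a reducible chain depends on the start state and is not a budget. An
  absorbing state makes the chain reducible and is likewise refused. If a
  second eigenvalue lies within $10^{-6}$ of the dominant modulus (e.g. a
  periodic chain) the function refuses with a non-uniqueness diagnostic.

## What the synthetic generator emulates

`simulation_config()` encodes the study conditions: 150 s samples inside
follows whose lengths are geometric with mean 100 samples (follows end for
visibility and weather, not on schedule); seasonal effort in the ratio of
the reported 231/246/158/93 tracking hours; a two-state per-step
vessel-presence chain with stay-probability 0.9 calibrated so the long-run
presence fraction is 55/52/49/44 % by season; vessel counts when present of
$1 + \mathrm{Poisson}$ with seasonal means matching the reported
1.99/1.87/1.90/1.21; a fifth Feeding state entered with probability 0.002
per step (marginal frequency $\approx 0.3\,\%$, exercising the drop-state
path); and fixed per-season sunrise/sunset (e.g. winter 07:30–17:30,
summer 06:00–21:00) with no ephemeris. Behavioural states persist strongly
across 150 s (self-transition $\approx 0.85$), reflecting bouts of several
minutes; seasonal and diurnal tilts (more rest in summer, more travel in
autumn and afternoons, more socialising in spring/summer) and the vessel
response (rest and socialising shifted toward milling) are planted by
moving probability mass between columns.

The generator does **not** emulate: spatial geometry (presence/absence is
simulated directly, not 300 m distances), within-day vessel traffic
patterns beyond the two-state chain, behavioural response lags beyond the
instantaneous matrix switch, observer error in state assignment, or
between-group heterogeneity. Passing recovery tests therefore show the
*pipeline* is consistent — they cannot show that real Kaikoura data meet
the first-order Markov assumption.

## Validation design and what it shows

Validation runs at the sizes stated here (the full versions live in the
acceptance suite and `scripts/acceptance.R`):

* **Oracle equivalence.** IPF under the two-way independence model against
  the closed form $\text{row}\times\text{col}/\text{total}$ (200 random
  tables, agreement to $10^{-10}$); eigenvector budgets against power
  iteration (500 random irreducible $4\times4$ matrices, $10^{-6}$); the Z
  statistic against the signed root of the uncorrected two-sample
  chi-square (1000 random points, $10^{-10}$). In unit tests, IPF is also
  cross-checked against Poisson IRLS (`glm`) and `stats::loglin` — two
  independent maximisers of the same likelihood.
* **Parameter recovery.** 200 replicates, 10,000 transitions per
  condition simulated from known random irreducible matrices; success is a
  maximum state deviation under 0.02, required in at least 95 % of
  replicates. Random matrices are the right family here because they mix
  fast: for the generator's own persistent matrices (second eigenvalue
  $\approx 0.8$) the stationary distribution is ill-conditioned in the
  matrix entries — sensitivity scales like $1/(1-\lambda_2)$ — and the
  deviation at 10,000 transitions measures the information limit of
  persistent chains, not estimator error. That variant is still computed
  and reported separately.
* **Model-selection error rates.** With a planted vessel effect of 0.15
  probability mass per row, the AIC-best model must contain the vessel
  term in at least 80 % of 100 replicates; with no planted effect, in at
  most 20 %. Transitions for these experiments are drawn
  product-multinomially (preceding states from the stationary law,
  successors from the matrix row), the sampling scheme under which the
  $G^2$/AIC asymptotics actually hold. When each condition is instead one
  long unbroken chain, occupancy fluctuations between conditions are
  over-dispersed and AIC buys the vessel term on autocorrelation noise in
  roughly half of null replicates — a genuine caveat of transition-level
  log-linear analysis on persistent chains, reported as a supplementary
  rate and one more reason the bootstrap-over-follows interval exists.
* **Rule fidelity.** Logs with a vessel sighting planted 10–14 min before
  a vessel-free stretch: every affected transition must stay out of the
  Control chain (the tests assert all of them do), and the saturated model
  must reproduce every tabulated dataset with $G^2 = 0$ exactly.

## Known limitations

* The first-order assumption is untested on real data here; higher-order
  dependence or duration effects would bias transition probabilities.
* Wald intervals and Z tests treat transitions as independent; with
  persistent states they overstate precision. Use the bootstrap for
  reporting.
* The AIC lattice encodes factor effects through
  `preceding:succeeding:factor` generators; coarser or finer encodings of
  "an effect of vessels" are possible and would change df.
* Budgets of sparsely observed strata (zero rows, reducible chains) are
  refused rather than smoothed; a Jeffreys-style pseudo-count
  (`estimate_matrix(counts, pseudo_count = 0.5)`) exists but must be asked
  for explicitly, never applied silently.
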