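# duskybudget

Markov-chain analysis of how tour-vessel traffic changes the behavioural
budget of dusky dolphin (*Lagenorhynchus obscurus*) groups, built for the
shore-based focal-follow design used at Kaikoura, New Zealand: a group's
predominant behavioural state (Resting, Traveling, Milling, Socialising,
Feeding) is scan-sampled every 150 s, together with the number of vessels
(including qualifying aircraft) within the 300 m interaction threshold.

The package is aimed at marine-mammal researchers and wildlife managers who
want to move from raw focal-follow logs to defensible statements like
"milling increases in the presence of vessels in winter", with the model
selection and uncertainty quantification done explicitly.

## The analysis

Consecutive observations of the same group are not independent, so the
state sequence is treated as a first-order time-discrete Markov chain of
transitions (preceding state at time 0, succeeding state at time 1).
Each transition is classified by season (Dec–Feb = Summer, …), time-of-day
block (thirds of the sunrise–sunset interval via the daylight index
*(t − sunrise)/(sunset − sunrise)*), and vessel condition:

* **Treatment** — vessels within 300 m at both endpoint samples;
* **Control** — no vessels at either endpoint *and* a fully observed,
  vessel-free 15 min buffer before the transition (reducing carry-over from
  recent interactions);
* everything else (mixed endpoints, unverifiable history) is excluded.

The resulting five-way count table (preceding × succeeding × season ×
time block × condition, with the rare Feeding state dropped) is modelled
with hierarchical log-linear models fitted by iterative proportional
fitting. Model misfit is measured by the likelihood-ratio statistic
G² = 2 Σ O ln(O/E); nested models are compared by ΔG² on Δdf degrees of
freedom, and the lattice of candidate models — the null model plus every
combination of vessel, time-of-day and season effects on the transition
structure, including the time × season interaction — is ranked by
AIC = G² − 2 df.

The behavioural budget under each condition is the stationary distribution
π of the estimated transition matrix P (the left eigenvector of the
dominant eigenvalue, πP = π), and Control vs Treatment budgets are compared
state-by-state with pooled two-proportion Z tests and 95 % confidence
intervals (Wald by default, with a bootstrap-over-follows alternative).

Because the raw transition-level field data are not deposited, the package
ships a seeded synthetic focal-follow generator
(`simulation_config()` / `simulate_study()`) that reproduces the study's
statistical structure — seasonal effort, vessel-presence fractions of
55/52/49/44 % by season, mean vessel counts when present, rare feeding —
so every stage of the pipeline is testable against known truth.

## Worked example

```r
library(duskybudget)

cfg   <- simulation_config(seed = 7)     # study-scale synthetic truth
study <- simulate_study(cfg)
an    <- analyse_observations(study$records)
an
#> Disturbance analysis: 15231 raw transitions, 10180 classified
#>   (Control + Treatment) after dropping Feeding
#> AIC-best model: condition+time_block+season+time_blockxseason

head(an$lattice$table[, c("label", "g2", "df", "aic", "rank")], 3)
#>                                           label        g2  df      aic rank
#> 1 condition+time_block+season+time_blockxseason  448.9165 165 118.9165    1
#> 2                   condition+time_block+season  644.8843 255 134.8843    2
#> 3                          condition+time_block 1037.1446 300 437.1446    3

an$comparisons[an$comparisons$stratum == "Summer",
               c("state", "control", "treatment", "z", "p_value")]
#>                   state control treatment      z  p_value
#> Resting         Resting   0.268    0.0282  20.84 1.74e-96
#> Traveling     Traveling   0.290    0.3763  -4.71 2.50e-06
#> Milling         Milling   0.139    0.4940 -18.97 3.03e-80
#> Socialising Socialising   0.303    0.1015  14.25 4.25e-46
```

Reading the output: of 15,231 raw transitions, 10,180 could be assigned to
a chain; model selection retains vessel condition, time of day, season and
the time × season interaction (the AIC-best model), so transition structure
genuinely depends on all three factors. The summer comparison recovers the
planted vessel response of the generator: resting collapses (0.268 → 0.028)
and milling rises (0.139 → 0.494) when vessels are present, both with
vanishing p-values at these chain lengths.

The same pipeline applies to real logs: a CSV with columns `follow_id`,
`timestamp`, `state`, `n_vessels`, `date`, `sunrise`, `sunset` read by
`read_observation_log()`.

## The analysis workflow

`analysis/` contains the narrative drivers, to be run from the repository
root in order:

| script | does | writes |
| --- | --- | --- |
| `01_simulate_study.R` | simulate the default synthetic study | `results/synthetic/` |
| `02_build_chains.R` | transitions, conditions, count table | `results/chains/` |
| `03_model_selection.R` | IPF model lattice, G²/df/AIC ranking | `results/models/` |
| `04_budgets.R` | stationary budgets, Z tests, figure | `results/budgets/` |
| `05_validation.R` | oracle checks and recovery rates | `results/validation/` |

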