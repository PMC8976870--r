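# htmagent

Building blocks and an experiment harness for a biologically inspired
reinforcement-learning agent that operates entirely on sparse distributed
representations (SDRs):

- **`sdr`** — the shared data type: sorted 0-based active indices in a binary
  space, compared by overlap.
- **`spatial_pooler`** — k-winners-take-all Hebbian encoder from binary
  observations to fixed-sparsity state codes.
- **`temporal_memory`** — minicolumn/cell sequence memory with per-step
  anomaly and confidence signals and optional apical (top-down) feedback.
- **`pattern_memory`** — online clustering that maintains the vocabulary of
  codes an encoder has emitted.
- **`bgt`** — basal ganglia / thalamus action selection: dual-pathway striatum
  with TD-dopamine learning, pallidal inhibition sampling, thalamic softmax,
  and motivation priorities that mix extrinsic and intrinsic pathways.
- **`empowerment`** — an intrinsic signal: the entropy of where the agent
  could be *n* steps later, estimated by propagating state superpositions
  through the learned transition memory (plus exact enumeration oracles).
- **`dreaming`** — anomaly-gated model-based learning in imagination
  (Dyna-style rollouts that never touch the environment).
- **`hierarchy`** — the two-level sensorimotor agent: gated visual
  abstraction, motor options formed from learned action sequences, and a
  second-level selector whose feedback boosts the option's next predicted
  action.
- **`gridworld`** — deterministic mazes with multi-channel binary windowed
  observations and the goal-relocation / exhaustible-resource protocols.
- **`harness`** — `trial_config()` / `run_trial()` experiment runner,
  deterministic per `(config, seed)`.

## Worked example

Exact one-step empowerment on an open 5×5 grid (4 actions):

```r
library(htmagent)
open5 <- parse_maze(rep("11111", 5))
ideal_empowerment(open5, c(2, 2), 1)   # interior cell
#> [1] 2
ideal_empowerment(open5, c(0, 0), 1)   # corner: counts (2,1,1)/4
#> [1] 1.5
```

A temporal memory masters a cyclic sequence of four disjoint patterns in a
few cycles — anomaly falls to 0 and the next element is predicted with full
confidence:

```r
vocab <- lapply(0:3, function(i) sdr((i * 10):(i * 10 + 9), 110))
tm <- temporal_memory(110, expected_sparsity = 10, seed = 1)
for (cycle in 1:5) for (p in vocab) tm_compute(tm, p)
out <- tm_compute(tm, vocab[[1]], learn = FALSE)
c(out$anomaly, out$confidence)
#> [1] 0 1
```

A baseline (one-level) agent on the four-corridors protocol, 5 episodes per
goal phase:

```r
cfg <- trial_config(protocol = "four_corridors", agent = "baseline",
                    episodes_per_phase = 5, time_limit = 40)
set.seed(1)
run_trial(cfg, seed = 1)$episodes
#>    episode task level steps reward reached_goal
#> 1        1    1     1    27   0.46         TRUE
#> 2        2    1     1    40  -0.80        FALSE
#> 3        3    1     1     4   0.92         TRUE
#> 4        4    1     1    40  -0.80        FALSE
#> 5        5    1     1    40  -0.80        FALSE
#> 6        6    2     1    14   0.72         TRUE
#> 7        7    2     1    27   0.46         TRUE
#> 8        8    2     1    40  -0.80        FALSE
#> 9        9    2     1    22   0.56         TRUE
#> 10      10    2     1     6   0.88         TRUE
```

The ideal four-step empowerment field over the bundled 9×9 four-rooms maze
spans 3.198 bits (deep corners) to 4.05 bits (next to doorways):

```r
fld <- empowerment_field(four_rooms_maze(), n = 4, variant = "ideal")
range(fld$value)
#> [1] 3.198438 4.049800
```

Agent variants for comparisons: `"baseline"` (one level, no intrinsic drive,
no dreaming), `"two_level"`, `"full"` (two levels + empowerment + dreaming),
and the minimal `"td"` / `"td_dreaming"` pair used to isolate the dreaming
block.

## Reproduction

- Unit, property and acceptance tests:
  `testthat::test_dir("tests/testthat", package = "htmagent",
  load_package = "installed")`. The acceptance tests in
  `tests/testthat/test-acceptance.R` check the analytic empowerment values,
  the equivalence of the estimator with enumeration oracles, temporal-memory
  and clustering contracts, TD/selection calibration, dreaming contracts, and
  three directional behavioral comparisons over 10 seeds each.
- Headline quantities as JSON:
  `Rscript scripts/acceptance.R --seed 1 --out acceptance.json`
  (runs against the installed package).
- A methods walk-through lives in `vignettes/htmagent.Rmd`.
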