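---
title: "Building a hierarchical, intrinsically motivated agent from SDR blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building a hierarchical, intrinsically motivated agent from SDR blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(htmagent)
```

`htmagent` implements a brain-inspired reinforcement-learning agent as a set
of small, independently testable blocks that all speak the same data type: the
sparse distributed representation (SDR). This vignette walks bottom-up through
the blocks and ends with the two-level agent and the experiment harness.

## Sparse distributed representations

An `sdr` is a sorted set of 0-based active bit indices inside a space of `n`
bits. Overlap (the size of the intersection) is the only similarity notion the
whole package uses.

```{r}
a <- sdr(c(0, 3, 7), n = 32)
b <- sdr(c(3, 7, 20), n = 32)
sdr_overlap(a, b)
sdr_union(a, b)
```

## Spatial pooler: observations to state codes

The spatial pooler turns arbitrary binary vectors into fixed-sparsity SDRs by
k-winners-take-all over random synaptic pools, with Hebbian refinement. Two
similar observations keep overlapping codes; distinct observations get
near-disjoint codes.

```{r}
m <- four_rooms_maze()
obs <- obs_vector(m, c(1, 1))         # 5x5 multi-channel binary window
sp <- spatial_pooler(length(obs), num_columns = 150, k_active = 10, seed = 1)
sp_compute(sp, obs)
```

## Temporal memory: sequences, anomaly, confidence

The temporal memory learns transitions between SDRs with minicolumns of
context cells. Each step reports an anomaly (how surprising the input was) and
a confidence (how strongly the next step is predicted). Both signals drive the
rest of the architecture: anomaly feeds the dreaming gate and one family of
intrinsic rewards, and the anomaly/confidence pair decides when a pattern is
passed up a hierarchy level.

```{r}
vocab <- lapply(0:3, function(i) sdr((i * 10):(i * 10 + 9), 110))
tm <- temporal_memory(110, expected_sparsity = 10, seed = 1)
for (cycle in 1:5) for (p in vocab) out <- tm_compute(tm, p)
out <- tm_compute(tm, vocab[[1]], learn = FALSE)
c(anomaly = out$anomaly, confidence = out$confidence)
```

## Pattern memory: an online vocabulary

The pattern memory clusters the stream of codes an encoder emits, keeping a
per-bit density per cluster. It supplies the state vocabulary used to mask
empowerment statistics and to snap imagined states back onto known ones.

```{r}
pm <- pattern_memory(110, pattern_size = 10)
for (p in vocab) pm_update(pm, p)
pm$n_clusters
```

## Basal ganglia and thalamus: soft action selection with TD dopamine

A striatum holds two antagonistic weight matrices whose difference encodes the
value of a stimulus-response pair; TD errors move the pair's value by exactly
`alpha * delta`. The pallidal stage (`gpi_select`) samples an inhibition mask
from the normalized pathway difference, and the thalamus softmax-selects among
response candidates by how much of each survives the mask. Dual pathways
(extrinsic and intrinsic) are combined by slowly adapting motivation
priorities.

```{r}
st <- striatum(60, 20, alpha = 0.1, gamma = 0.9)
s <- sdr(0:4, 60); r <- sdr(0:4, 20)
striatum_observe(st, s, r)
td_learn(st, reward = 1, new_value_estimate = 0)
striatum_value(st, s, r)
```

## Empowerment: an intrinsic signal from the transition memory

Empowerment of a state is the entropy of where the agent could be `n` steps
later. The estimator propagates a superposition of predicted states through
the learned transition memory, collects per-bit visit statistics, masks them
against the pattern-memory vocabulary with a statistic `lambda` (the mode by
default), and takes the entropy. On a deterministic maze it can be checked
against exhaustive enumeration:

```{r}
open5 <- parse_maze(rep("11111", 5))
c(interior = ideal_empowerment(open5, c(2, 2), 1),
  corner   = ideal_empowerment(open5, c(0, 0), 1))
```

`empowerment_field()` computes a whole per-cell map; on the four-rooms maze
the four-step field peaks next to doorways and bottoms out in deep corners.

## Dreaming: learning in imagination

The dreaming block keeps a forward model (a temporal memory over joint
state-action patterns), a reward readout, and a per-transition anomaly map.
When the current transition is familiar enough, the agent may detach with
probability `p_max * (1 - anomaly)^2` and run rollouts in which its own policy
acts on imagined states, training its value function without touching the
environment.

```{r}
dreaming_config()$p_max
```

## The two-level agent

`hierarchical_agent()` wires everything together: a visual pathway (pooler,
temporal memory, anomaly/confidence-gated second level) and a motor pathway
(temporal memory over action SDRs plus a basal-ganglia selector). Sequences
the motor memory has learned become options: a second-level selector picks a
stored start pattern; it is fed back apically, and elementary actions that
carry both sequence-context and feedback support get a boosted thalamic
weight until the feedback no longer matches.

```{r}
env <- grid_env(four_corridors_maze(), goal = c(4, 4), time_limit = 30)
obs <- env_reset(env)
ag <- hierarchical_agent(length(obs), n_actions = 4, level2 = TRUE, seed = 1)
a <- agent_act(ag, obs, reward = 0, pos = env$pos)
for (t in 1:29) {
  stp <- env_step(env, a)
  a <- agent_act(ag, stp$obs, stp$reward, done = stp$done, pos = stp$pos)
  if (stp$done) break
}
print(ag)
```

## The harness

`trial_config()` + `run_trial()` play full protocol schedules (goal
relocation, restricted/free four-rooms, the exhaustible-resource curriculum)
with any agent variant, deterministically per `(config, seed)`.

```{r}
cfg <- trial_config(protocol = "four_corridors", agent = "baseline",
                    episodes_per_phase = 3, time_limit = 40)
run_trial(cfg, seed = 1)$episodes
```

`aggregate_trials()` aligns episode tables across seeds, `option_stats()`
normalizes the option traces, and `scripts/acceptance.R` recomputes the
package's headline quantities into a JSON report.
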