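# fcreliab

Test–retest reliability of fMRI functional connectivity, across rest and
task states.

Functional connectivity (FC) — the Pearson correlation between BOLD time
courses of brain regions — is increasingly used as an individual-difference
measure, but its usefulness hinges on reliability: whether the same
person's connectome, measured twice, gives the same answer. Reliability
varies across the cortex and is shaped by scan length, head motion,
regional signal properties, and by what the participant is doing in the
scanner. `fcreliab` is for researchers working with densely sampled
multi-session fMRI (many sessions per subject, rest plus task states) who
want to quantify these effects and attribute them to their sources.

## What it computes

For unit *u* with split-half connectomes *A*, *B* (sessions 1–5 vs 6–10,
each the Pearson connectome of concatenated, per-run mean-centered,
motion-censored frames):

- **FC-TRC**: the split-half test–retest correlation,
  `FC-TRC(u) = cor(A[u, -u], B[u, -u])` — a per-unit reliability map.
- **Edge-wise ICC(2,1)**: the two-way random-effects intraclass
  correlation per connectome edge across subjects × halves,
  `ICC(2,1) = σ²_λ / (σ²_λ + σ²_π + σ²_ε)` (between-subject variance over
  total), from the ANOVA mean squares, with the variance components
  reported and the conventional poor/fair/good/excellent bands.
- **Signal properties**: per-unit tMean, tSD and tSNR (per-run mean/SD
  ratio), averaged run → session → subject, and their task-minus-rest
  deltas on volume-matched data.
- **FIR task GLMs**: finite-impulse-response designs (motor 7 × 2.2 s;
  event conditions 8 × 1.5 s; sustained blocks and cues), per-unit OLS
  fits, uniform averaged-bin contrasts (PEs), and task-residualized
  connectomes.
- **Consensus networks**: community detection (Infomap or Louvain) on
  2–5 % density-thresholded group connectomes, consensus across
  thresholds via the co-assignment probability matrix, and reassignment
  of excess communities to neighboring networks.
- **Attribution**: parcel-wise and network-wise regressions between maps
  (with low-reliability-network exclusion), and the per-parcel mixed
  model `reliability ~ tMean + tSD + PE + (1 | participant)`.

A synthetic multi-subject, multi-session BOLD generator with planted
network structure, subject-stable edge perturbations, task-evoked
responses confined to engaged parcels, and motion spikes provides ground
truth for validating every stage; `run_pipeline()` chains the whole
analysis end to end on a simulated (or equivalently formatted) dataset.

## Worked example

Simulate a small study (4 subjects × 2 sessions, rest + motor, 102
parcels in 17 planted networks) and run the full pipeline:

```r
library(fcreliab)

spec <- synth_spec(n_subjects = 4, n_sessions = 2,
                   n_parcels = 102, n_networks = 17,
                   frames_per_run = c(rest = 200, motor = 180),
                   runs_per_state = c(rest = 1L, motor = 1L), seed = 42)
dataset <- file.path(tempdir(), "demo-study")
simulate_dataset(spec, dataset, overwrite = TRUE)

result <- run_pipeline(dataset, pipeline_config(infomap_reps = 10),
                       mixed_model = FALSE)
result
#> <fc_pipeline_result>
#>   FC-TRC rest      group mean 0.286
#>   FC-TRC motor     group mean 0.292
#>   rest edge ICC(2,1) mean 0.046
#>   consensus networks: 17

table(classify_icc(result$icc$edge_icc))
#> excellent      fair      good      poor
#>       370       688       483      3610

eng <- spec$engaged_parcels$motor
sprintf("mean delta-tSD engaged %+.2f vs non-engaged %+.2f",
        mean(result$delta_signal$tsd$motor[eng]),
        mean(result$delta_signal$tsd$motor[-eng]))
#> "mean delta-tSD engaged +2.15 vs non-engaged +0.09"

adjusted_rand(result$networks$assignment,
              build_ground_truth(spec)$partition)
#> 0.98
```

Reading the output: group-mean FC-TRC is modest (~0.29) because each
split half holds only ~90 retained frames — reliability grows with scan
length, which the test suite checks explicitly. Most edges fall in the
"poor" ICC band for the same reason (and because the default
between-subject edge variance is small relative to sampling noise at this
length). The motor task raises temporal SD specifically in the parcels it
engages (+2.15 vs +0.09 a.u.), and the consensus assignment recovers the
planted 17-network partition almost exactly (adjusted Rand 0.98).

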