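# dnbr — dynamic network biomarker analysis for time-course expression data

`dnbr` locates the *triggering phase* of a critical state transition —
the short low-resilience interval just before a biological system tips into
a disease state — from replicated time-course expression data, using the
dynamic network biomarker (DNB) framework. It is aimed at systems-biology
analysts working with small-replicate time courses (the motivating design:
five consecutive developmental timepoints, three replicates each) who want a
self-contained, fully testable DNB pipeline.

## The statistic

Near a tipping point there exists a dominant group of genes whose
within-group standard deviation (SD<sub>in</sub>) and within-group absolute
Pearson correlation (PCC<sub>in</sub>) rise sharply while their correlation
to all other genes (PCC<sub>out</sub>) falls. The scalar signal is the
criticality index, computed per timepoint across that timepoint's
replicates:

```
CI = sqrt(size) * (PCC_in / PCC_out) * SD_in
```

The CI profile across timepoints peaks at the critical timepoint. `dnbr`
provides:

* per-timepoint group statistics and CI (`group_stats()`,
  `criticality_index()`, `criticality_profile()`);
* dominant-group search by average-linkage clustering of `1 - |PCC|` with
  clade-level CI scoring and an escalation-based selection rule
  (`find_dominant_group()`), plus `detect_transition()`;
* an optional one-vs-rest Welch + Benjamini–Hochberg candidate screen
  (`one_vs_rest_screen()`) and the qPCR `ddct_fold_change()` utility;
* integrated member ranking by intra-group network degree and pathway hits
  (`integrated_rank()`, GMT and edge-list readers included);
* a one-factor Gaussian simulator with a planted DNB group and transition
  (`simulate_series()`) and its closed-form CI oracle (`expected_ci()`),
  so the whole pipeline is validated end to end without downloads;
* a pipeline driver (`run_pipeline()`) and CLI (`inst/exec/dnbr.R`) with
  YAML configs, deterministic outputs and a run manifest.

## Worked example

Simulate the default strong-effect world — 200 genes, a 20-gene planted DNB
group, five timepoints D3–D7 with the transition planted at D6, ten
replicates — and search for the dominant group:

```r
library(dnbr)
sim <- simulate_series(simulation_config(n_rep = 10, seed = 42))
res <- find_dominant_group(sim$series)
print(res)
#> dnb_result: 26-gene dominant group, critical timepoint D6
#>  timepoint size     SD_in    PCC_in   PCC_out        CI floored
#>         D3   26 1.0380455 0.3277800 0.3578088  4.848803   FALSE
#>         D4   26 0.9929045 0.2787433 0.2908643  4.851859   FALSE
#>         D5   26 0.9542103 0.2875354 0.3014117  4.641539   FALSE
#>         D6   26 2.2172926 0.7164583 0.2936098 27.588624   FALSE
#>         D7   26 0.9318493 0.2778298 0.2881965  4.580601   FALSE
```

Reading the profile: at D6 the selected group's per-gene standard deviation
more than doubles (SD_in 0.95 → 2.22), its internal coherence jumps
(PCC_in 0.29 → 0.72) while its correlation to the rest of the transcriptome
stays flat (PCC_out ≈ 0.29), so the criticality index spikes from ~4.8 to
27.6 — the signature of a triggering phase at D6, which is exactly where the
transition was planted (`sim$truth$t_star`). The group overlaps the planted
20-gene DNB in 19 of its 26 members here.

A full pipeline run (simulate → screen → DNB search → ranking → TSV/JSON
artifacts) from one config:

```r
run_pipeline(list(seed = 1, simulate = list(enabled = TRUE, n_rep = 10)),
             out_dir = "dnbr_out")
```

or from the command line:

```sh
Rscript inst/exec/dnbr.R full --config config.yaml --out-dir dnbr_out
```

Outputs: `criticality_profile.tsv`, `dnb_members.tsv`, `de_results.tsv`,
`candidates.txt`, `ground_truth.yaml` (when simulating), `run_config.yaml`
and `manifest.json`; reruns with the same config and seed are
byte-identical.

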