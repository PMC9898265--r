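---
title: "Dynamic network biomarker analysis with dnbr: model, search and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic network biomarker analysis with dnbr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Complex biological systems often do not deteriorate gradually: they sit in a
resilient state, pass through a short low-resilience *triggering phase*, and
then tip into a qualitatively different stable state. Classical biomarkers
compare the two stable states and are blind to the triggering phase, which is
precisely where intervention is still possible. The dynamic network
biomarker (DNB) framework detects the approach to a tipping point from
fluctuation and correlation structure rather than from mean expression: near
criticality there exists a group of molecules whose

1. standard deviations (SD~in~) become dramatically high,
2. mutual correlations (PCC~in~, in absolute value) become markedly higher,
3. correlations to all other molecules (PCC~out~) drop.

`dnbr` implements this framework for replicated time-course expression data
(the motivating design: five consecutive developmental timepoints, three
replicates each), together with everything needed to validate it end to end
without external data.

## The criticality index

For a candidate gene group of a given *size* at one timepoint,

$$\mathrm{CI} = \sqrt{\textit{size}}\;
  \frac{\mathrm{PCC}_{in}}{\mathrm{PCC}_{out}}\;\mathrm{SD}_{in},$$

where SD~in~ is the mean across group genes of the sample standard deviation
over that timepoint's replicates (n − 1 denominator), PCC~in~ the mean
absolute Pearson correlation over all within-group pairs, and PCC~out~ the
mean absolute correlation over all group × background pairs. All three are
computed strictly within one timepoint; the CI profile across timepoints is
the transition signal and its peak marks the critical timepoint.

Numerical choices:

* **`pcc_out_floor`** (default `1e-6`) bounds the denominator; engagement is
  flagged, never silent.
* **Zero-variance genes** within a timepoint get correlation 0 and are
  flagged rather than dropped — dropping would silently change *size* and
  hence $\sqrt{\textit{size}}$.
* **Background** defaults to every measured gene outside the group; it can
  be restricted to the candidate set (`background = "candidates"`). The
  defining texts say only "the group versus others"; both readings are
  supported.
* Correlations across 3 replicates are extremely noisy; the search warns
  below 5 replicates per timepoint. Recovery guarantees quoted below are
  established at 10 replicates.

## Dominant-group search

The DNB criteria define what the dominant group looks like, not how to find
it. `find_dominant_group()` uses, per timepoint: absolute Pearson
correlation among candidate genes; average-linkage hierarchical clustering
on the distance $1 - |\mathrm{PCC}|$; and then scores **every dendrogram
clade** whose merge height is at most `cut_height` (default 0.5) and whose
size is at least `min_group_size` (default 5). Scoring all coherent clades —
rather than only the clusters of one fixed-height cut — lets the criticality
index itself choose the group granularity; with a single cut the winning
cluster systematically absorbs weakly attached genes (in our validation this
raised planted-membership recovery from a median Jaccard of about 0.58 to
about 0.77).

Each clade's CI is then evaluated at *every* timepoint, and the dominant
group is chosen by the `selection` rule:

* **`"excess"` (default):** maximize the clade's CI at its formation
  timepoint minus the median of its CI across all timepoints. A dynamic
  biomarker is defined by its score *escalating* at the triggering phase; a
  large constitutively co-expressed module has a high CI at every timepoint
  purely through the $\sqrt{\textit{size}}$ term and is correctly ignored by
  this rule. In simulations whose background is one big weakly correlated
  module, plain CI maximization picks such a module in roughly 5% of runs;
  excess selection recovers the planted transition in 99–100 of 100 runs on
  disjoint seed ranges.
* **`"max"`:** the classical rule — the (clade, timepoint) pair with the
  globally maximal CI.

The reported `critical_timepoint` is the selected group's formation
timepoint; `detect_transition()` separately returns the argmax of any CI
profile (ties broken to the earliest timepoint and flagged; an identically
zero profile yields a structured "no transition" result). When no clade
meets `min_group_size`, the result has `found = FALSE` — that is an answer,
not an error.

## The synthetic world

`simulate_series()` generates the stated validation world: a one-factor
Gaussian model with a planted DNB group and a planted transition timepoint
`t_star`. One latent factor $z_{tr}$ is shared per (timepoint, replicate):

* DNB gene $i$: $\mu_i + s_i(t)\,(\sqrt{\rho_{in}(t)}\,z_{tr} +
  \sqrt{1-\rho_{in}(t)}\,\varepsilon)$, with $s_i(t) = \sigma_0\beta$ at
  $t^\*$ and $\sigma_0$ otherwise;
* background gene $j$: $\mu_j + \sigma_0(\sqrt{\rho_{out}(t)}\,z_{tr} +
  \sqrt{1-\rho_{out}(t)}\,\varepsilon)$.

The one-factor construction gives closed-form large-replicate limits:
within-group correlation $\rho_{in}(t)$, group–background correlation
$\sqrt{\rho_{in}(t)\rho_{out}(t)}$, background–background correlation
$\rho_{out}(t)$. `expected_ci()` substitutes these into the CI and serves as
an independent oracle; at 500 replicates the per-timepoint mean empirical CI
over 50 seeds agrees with it to well under 2%.

Defaults state the world once: 5 timepoints labelled D3–D7, transition at
the fourth (D6), 3 replicates (the motivating design; tests that need tight
tolerances raise `n_rep` explicitly), 200 genes with a 20-gene planted
group, $\sigma_0 = 1$, $\beta = 3$, $\rho_{in}: 0.1 \to 0.8$ and
$\rho_{out}: 0.3 \to 0.05$ at the transition. Further choices, made once and
documented here:

* **`coupled_fraction = 1`**: every background gene carries the
  $\rho_{out}$ loading, keeping the closed-form PCC~out~ limit exact. A side
  effect is that the whole background forms one large weakly correlated
  module — a hard, adversarial case for the search (see the excess rule
  above), which we kept deliberately.
* **Baseline means** $\mu \sim N(8, 2^2)$, a typical log2-expression
  location; mean structure never enters the within-timepoint statistics.
* **`dnb_de = TRUE`**: the planted DNB genes also receive the
  post-transition mean shift $\delta$ (default $3\sigma_0$), so a
  differential screen retains them and the full pipeline is coherent with a
  design in which DNB members are sought within differentially expressed
  genes. A shift constant within each timepoint provably leaves SD~in~,
  PCC~in~, PCC~out~ and CI untouched. Strictly null simulations set it
  `FALSE`.
* **Reproducibility**: one seeded stream with a fixed draw order (means,
  role assignment, then per timepoint the factor and the noise matrix);
  identical seeds give byte-identical series.

What the generator does *not* emulate — and hence what a green test does not
establish: count noise and the RNA-seq variance–mean relationship (values
are Gaussian on a log-like scale), library-size and batch effects,
heavy-tailed or structured (multi-module) backgrounds, and any mechanistic
bifurcation dynamics. Green recovery tests establish that the statistics and
the search behave as designed under the stated world, not that real data of
a given design will yield a detectable DNB.

## Candidate screening

`one_vs_rest_screen()` is a deliberately simple, fully self-contained
stand-in for a count-model differential-expression stage: per gene and per
timepoint, a two-sided Welch t test of that timepoint's samples against all
others, Benjamini–Hochberg adjustment within each comparison (global BH
optional), candidates = the union at `q < 0.05`. It performs no
normalization, dispersion estimation or shrinkage; anyone with a preferred
DE tool can bypass it entirely by passing an explicit candidate list. Under
a 1000-gene global null the screen yields on average about one false
candidate per run; planted $3\sigma$ shifts at 10 replicates are recovered
with recall ≈ 1. The small `ddct_fold_change()` utility computes the
standard $2^{-\Delta\Delta C_t}$ qPCR relative expression.

## Member ranking

`integrated_rank()` combines two per-gene indices over the dominant group:
*index one*, the gene's degree in the subgraph induced by the group divided
by $L$, the total number of links among group members (the induced subgraph
is the reference implied by normalizing to "links among all DNB genes";
whole-network degree is available as an option); and *index two*, the number
of reference pathways containing the gene as a percentage of the reference
collection size (default: the number of loaded GMT sets; set 185 to mirror
the MSigDB KEGG collection the scheme was designed around). No combination
rule is canonical, so the default is the minimal-assumption equal-weight
mean $0.5\,\mathrm{idx}_1 + 0.5\,\mathrm{idx}_2/100 \in [0,1]$, with
configurable weights. Exact ties are broken lexicographically and flagged.

## Validation design

Every statistic has an independent oracle in the test suite: brute-force
double-loop correlation and group statistics (agreement to 1e−12), a
hand-coded BH step-up, `stats::t.test` against the vectorized Welch path,
closed-form `expected_ci`, and planted ground truth for the search. Three
properties deserve comment:

* **Convergence (CI limit)** is asserted on the Monte-Carlo estimate — the
  per-timepoint mean over 50 seeds — because a single seed's CI at 500
  replicates still carries ~4% relative sampling noise.
* **Null flatness** is asserted on the CI profile of a *fixed* (planted)
  group: a post-selection profile is inflated at its own argmax by
  construction, having been chosen as the maximum over a few hundred
  clade–timepoint scores. The flatness property belongs to the statistic,
  not to the winner of a search over noise.
* **Recovery bounds** (critical timepoint in ≥ 95/100 runs, median
  membership Jaccard ≥ 0.6) are asserted at the strong-effect settings with
  10 replicates; at 3 replicates sample correlations are too noisy for any
  such guarantee, which is why the search warns there.

## Known limitations

The search cost grows with candidates² per timepoint (clustering) and
clades × timepoints (scoring); thousands of candidates are fine, whole
transcriptomes should be screened first. CI has no significance measure
here — none is established for it — so CI values are comparable across
timepoints within one run, not across datasets. The excess rule needs at
least two timepoints (with one it falls back to `"max"`). Gene identifiers
are matched exactly and case-sensitively across expression, network and
pathway inputs.
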