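---
title: "Selecting and validating RT-qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating RT-qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative RT-qPCR quantification stands or falls with its reference genes:
every fold change is a ratio against the reference signal, so any
condition-dependent drift in the reference propagates one-for-one (on the
log scale) into the reported biology. Classical housekeeping genes —
rRNA, actin, GAPDH — were chosen for their cellular role, not for
measured invariance, and in developing tissues they are often the least
stable part of the assay. `refstab` implements a complete
discovery-and-validation workflow for this situation:

1. **screen** a multi-experiment RNA-seq compendium for genes that are
   abundant and stable everywhere, not just on average;
2. **score** the surviving candidates on replicated Cq measurements with
   four established stability statistics (geNorm M, NormFinder,
   BestKeeper, pairwise delta-Ct);
3. **merge** the four rankings into one consensus by cross-entropy
   Monte-Carlo rank aggregation;
4. **size** the reference panel with the geNorm pairwise-variation series;
5. **validate** the recommendation by delta-delta-Cq quantification of a
   biologically structured target and Pearson concordance across
   normalization choices.

Because the workflow is usually applied to data that cannot be
redistributed, the package ships a synthetic-data generator that plants
known stability structure, so every stage is testable end to end against
ground truth.

## Screening statistics

For gene $g$ in experiment $e$ with samples $x_1,\dots,x_n$, the package
uses the sample coefficient of variation
$\mathrm{CV} = s / \bar{x}$ (with the $n-1$ standard deviation) and the
within-experiment mean FPKM. Two screening modes exist:

* **MEAN** (lenient): per-experiment means and CVs are averaged across
  experiments and the thresholds (defaults FPKM $\ge$ 100,
  CV $\le$ 0.2) are applied to those averages. Genes that are stable *on
  average* pass, including genes that misbehave in a few experiments.
* **SIMULTANEOUS** (stringent): the thresholds (defaults FPKM $\ge$ 100,
  CV $\le$ 0.15) must hold in *every* experiment. The per-experiment pass
  sets are reported (the Venn strata), and the candidate set is their
  intersection.

Both modes compare inclusively ($\ge$, $\le$), reading the thresholds
literally. MEAN averages per-experiment statistics rather than pooling
samples (pooling is available via `pooled = TRUE`); SIMULTANEOUS applies
the abundance threshold to the per-experiment mean by default, with
`per_sample_fpkm = TRUE` for the stricter per-sample reading. These were
genuinely open choices; both alternatives are exposed and the defaults are
the ones we consider the most natural reading of "thresholds applied to
the mean of the experiment data sets" versus "applied simultaneously".

## From Cq to quantities

All stability statistics operate on strictly positive relative
quantities. Replicated Cq values (default 4 biological replicates) are
collapsed to one value per gene and sample — mean by default, median as an
option — *before* any stability analysis, because the analysis unit of the
workflow is the sample, and an unbalanced treatment of replicates would
leak replicate noise into the stability scores. Collapsed Ct converts via

$$Q_{gs} = E_g^{\,\mathrm{Ct}^{\min}_g - \mathrm{Ct}_{gs}},$$

where $E_g$ is the gene's amplification factor per cycle (fold per cycle;
ideal 2.0, accepted range 1.6–2.2). Efficiency tables given in percent are
converted as $E = 1 + \mathrm{pct}/100$, the standard qPCR convention.
The per-gene minimum-Ct anchoring makes $\max_s Q_{gs} = 1$; every
statistic downstream is invariant to that per-gene constant, so the
anchoring is cosmetic but makes matrices comparable and testable. All
logarithms in the package are base 2, matching cycle semantics at
$E = 2$: one cycle = one log2 unit. Missing cells are a hard error —
nothing here imputes.

## The four stability statistics

**geNorm.** The pairwise variation of genes $j,k$ is
$V_{jk} = \mathrm{sd}_s\!\left(\log_2 Q_{js}/Q_{ks}\right)$ and the
stability of $j$ is $M_j = \mathrm{mean}_{k \ne j} V_{jk}$. The iterative
ranking repeatedly removes the gene with the largest $M$ (ties broken
lexicographically by gene id) until two genes remain; those two are
mathematically inseparable (each one's $M$ is the symmetric $V_{jk}$) and
are reported tied at ranks 1–2 in lexicographic order — a deterministic
output is required because the ranking feeds rank aggregation. geNorm
runs on linear quantities; for FPKM input we likewise use raw values, not
logs, since the statistic itself is already log-ratio based.

**Pairwise delta-Ct.** The score of $j$ is the mean over partners $k$ of
$\mathrm{sd}_s(\mathrm{Ct}_{js} - \mathrm{Ct}_{ks})$, in cycles. With all
$E = 2$, $\log_2 Q_{js}/Q_{ks} = \mathrm{Ct}_{ks} - \mathrm{Ct}_{js}$, so
the delta-Ct score *equals* geNorm M exactly. This identity is the
package's central numerical cross-check: two independently coded paths
must agree to $10^{-9}$ on random tables, which pins down the SD
denominator ($n-1$ everywhere), the log base, and the quantity
convention all at once.

**BestKeeper.** Descriptive: per gene the arithmetic and geometric mean
Ct, extrema, dispersion and $\mathrm{CV}\% = 100 \cdot \mathrm{SD} /
\overline{\mathrm{Ct}}$; the BestKeeper index is the per-sample geometric
mean of Ct over candidates, and each gene is correlated (Pearson, with a
two-sided p-value) against the index. Dispersion is the sample SD about
the arithmetic mean by default; the original spreadsheet's mean absolute
deviation about the geometric mean is available via
`dispersion = "mad"` — secondary descriptions of the tool disagree, so
both are supported and the default is documented rather than silently
chosen. Genes with SD > 1 cycle are flagged inconsistent; a zero-variance
gene yields an `NA` correlation with a flag instead of an error. The
ranking key is SD (CV% reported alongside); p-values are descriptive and
deliberately uncorrected.

**NormFinder.** On $y = \log_2 Q$, each sample is centered across the
candidate genes, removing the common per-sample component. Ungrouped, the
naive variance $t_j$ of gene $j$'s centered residuals mixes every gene's
noise: under the additive model
$\mathbb{E}[t_j] = \sigma_j^2 (1 - 2/k) + \tfrac{1}{k^2}\sum_l \sigma_l^2$.
The closed-form inversion

$$\hat\sigma_j^2 = \Big(t_j - \frac{\sum_l t_l}{k(k-1)}\Big)\,
\frac{k}{k-2}, \qquad \text{clipped at } 0,$$

is unbiased (we verified this against a Monte-Carlo oracle before
freezing it), and the reported stability is $\hat\sigma_j$ in log2 units.
With group labels (defaulting to cultivar when present), the group mean
$z_{jg}$ of the centered residuals yields the intergroup deviation
$d_{jg} = z_{jg} - \bar z_{j\cdot}$ (summing to zero over genes in every
group), which is shrunk towards zero by the empirical-Bayes factor
$\gamma^2 / (\gamma^2 + \hat\sigma^2_{jg}/n_g)$, with $\gamma^2$ the
across-(gene, group) variance of $d$ minus the mean sampling variance
(clipped at 0); the stability is the mean over groups of
$|\tilde d_{jg}| + \sqrt{\hat\sigma^2_{jg}/n_g}$, combining systematic
group-dependence with noise.

A precision caveat that matters in practice: the correction subtracts an
estimate of the *panel-wide* noise share, so a single gene's variance is
estimated with absolute sampling error of the order of the panel's
average variance divided by $\sqrt{n}$, regardless of how small that
gene's own variance is. With three candidates of variances 0.01, 0.25 and
1.0 at $n = 200$ samples, the 0.01 gene's estimate is therefore only
order-of-magnitude informative (its estimate can clip to zero) even
though the *ordering* of the three genes is recovered essentially always.
Rankings are robust; small variance magnitudes on small panels are not.

## Consensus ranking

The four method rankings (and, on the RNA-seq side, the per-experiment CV
rank lists) are merged by minimizing
$\Phi(\pi) = \sum_i w_i\, d(\pi, \text{list}_i)$ over permutations
$\pi$, with $d$ the Spearman footrule (default) or Kendall distance and
unit weights by default — the workflow gives no reason to privilege one
method. The minimizer is found by the cross-entropy method: a $k \times k$
item-position probability matrix starts uniform; each iteration samples
$N = 10k^2$ permutations position-by-position with renormalization over
unplaced items, takes the best $\lceil 0.1 N \rceil$, and updates the
matrix towards the elite frequencies with smoothing weight 0.25; the
search stops after 15 non-improving iterations (or 1000 total). These
defaults mirror the published defaults of the cross-entropy
rank-aggregation literature and, on random instances with $k \le 7$,
recover the exact brute-force optimum (enumeration of all $k!$
permutations, available as `aggregate_brute()` for $k \le 8$) in at least
49 of 50 instances for both distances — the sampler is seeded, so this is
reproducible. The exact enumerator is kept as a first-class function, not
a test helper: on small panels there is no reason to accept a stochastic
answer.

## How many reference genes?

Given the geNorm ranking, the normalization factor over the $n$ best
genes is the per-sample geometric mean of their quantities, and

$$V_n = \mathrm{sd}_s\!\left(\log_2
\mathrm{NF}_n(s)/\mathrm{NF}_{n+1}(s)\right), \qquad n = 2, \dots, k-1.$$

Small $V_n$ means the $(n+1)$-th gene no longer changes the factor. The
optimal $n$ is the smallest with $V_n$ strictly below 0.15 (the
conventional cutoff, read literally as "below"), or $k$ if none clears
it. The recommended reference set is the top-$n$ of the *consensus*
ranking, so the final call uses all four methods, not geNorm alone.

## Delta-delta-Cq validation

`relative_expression()` computes efficiency-aware folds: on the log2
scale, $\log_2 Q_g = -\mathrm{Ct}_g \log_2 E_g$ per gene, the
normalization factor is the geometric mean over the reference set, and
profiles are anchored at a calibrator sample (default: the sample where
the target's Ct is highest, i.e. its expression minimum — the workflow
does not dictate a biological calibrator, so the package picks a
deterministic one and lets the user override). With $E = 2$ everywhere
this reduces exactly to $2^{-\Delta\Delta \mathrm{Ct}}$, and a two-gene
reference at constant Ct 20 and 22 behaves identically to a single
reference at 21. `compare_normalizations()` correlates the fold profiles
of alternative reference schemes (Pearson, on linear folds by default;
`log2_folds = TRUE` for the log scale) against a designated standard
scheme. A reference drifting by $+1$ cycle per developmental stage
inflates apparent folds by exactly $2^{\text{stage offset}}$ — the
analytic signature of a bad reference that the validation stage is
designed to expose.

## The synthetic-data generator

`simulate_fpkm()` emulates a multi-experiment compendium: nine
experiments of eight stage-samples each by default, with three gene
classes. Planted stable genes have mean FPKM 300 and within-experiment
CV 0.08 in every experiment — comfortably inside the screening
thresholds, as a known-positive class should be, but with realistic
sampling noise at $n$ = 8–10 samples per experiment.
Housekeeping-like genes (15 by default, echoing the size of a
traditional housekeeping panel) are stable (CV 0.08–0.12) in most
experiments but elevated (CV 0.25–0.45) in two: stable *on average*, so
they pass the MEAN screen and fail the SIMULTANEOUS screen — the pitfall
the stringent screen exists for. Background genes draw a log-normal mean
(median 50 FPKM) and a per-gene CV around 0.5, typical of regulated
transcripts across development. Values are log-normal with the exact
relation $\sigma_{\ln} = \sqrt{\ln(1 + \mathrm{CV}^2)}$, so mean and CV
are controlled exactly in expectation.

`simulate_ct()` emulates the validation panel in cycle space:

$$\mathrm{ct} = \mathrm{base}_g + b_s + \mathrm{trend}_g \cdot
(\mathrm{stage}_s - 1) - \log_2 \mathrm{fold}_{gs} + \varepsilon,$$

with a shared per-sample effect $b_s$ (loading/RT variation, SD 0.15
cycles by default), optional per-gene linear stage drift, an optional
planted fold-change profile (a 4-fold induction lowers Ct by exactly 2
cycles), and Gaussian replicate noise — the standard qPCR error model in
cycle space. Default geometry is 16 samples (8 stages × 2 blocks) × 4
replicates. Both generators draw every gene from its own substream,
seeded by a deterministic hash of (master seed, gene index), so outputs
are bit-identical under a fixed spec regardless of evaluation order.

What the generator does **not** emulate: read-level sequencing noise,
tissue mixtures, correlated regulation between genes, amplification
inhibitors, or heavy-tailed outliers. Passing the recovery suites
therefore shows that the statistics identify the stability structure they
are defined on — it does not certify performance on pathologies the model
does not contain, and real compendia should still be screened with both
modes and inspected.

## Numerical and reproducibility choices

* SD uses the $n-1$ denominator everywhere, asserted by the
  geNorm/delta-Ct identity test.
* All threshold comparisons in screening are inclusive; the pairwise
  variation and Ct-QC cutoffs are strict, following the usual phrasing of
  those rules ("below 0.15", "above 30").
* Every ranking tie, anywhere, breaks lexicographically by gene id; the
  geNorm final pair is reported tied and ordered lexicographically.
* Negative variance estimates (NormFinder, $\gamma^2$) clip to 0.
* Writers serialize doubles with 17 significant digits, so
  write-then-read round trips are bit-exact and pipeline reruns are
  byte-identical.
* The Monte-Carlo aggregator and both simulators are fully seeded;
  `run_pipeline()` derives all stage seeds from one master seed.

Test and validation problem sizes — 100 random 20 × 16 tables for the
identity check, 50 aggregation instances at $k \le 7$, a 2,000-gene
compendium for screening recovery, 100 six-gene Cq panels for tier
recovery — were chosen so the full suite exercises every estimator at
realistic panel sizes while running in well under a minute.

## A worked run

```{r pipeline, eval = FALSE}
report <- run_pipeline(default_pipeline_config(seed = 42))
report$recommended        # the two planted near-noiseless genes
report$pv$series          # V_n series; optimal n = 2
report$stability          # four scores + ranks per candidate
```

The numbered scripts under `analysis/` run the same workflow as a
narrative: simulate, screen (both modes, with truth-class tallies),
stability panel, consensus (with brute-force cross-check where feasible),
optimal-n, and delta-delta-Cq validation, writing all tables under
`results/`.

## Known limitations

* geNorm-family statistics reward *co-stability*: a coregulated unstable
  pair can score deceptively well. The four-method consensus and the
  concordance validation mitigate but cannot eliminate this.
* NormFinder variance magnitudes are unreliable for very small panels
  (see above); use the ordering, or enlarge the panel.
* The grouped NormFinder model assumes two or more samples per group and
  treats groups as exchangeable; it is not a substitute for a designed
  mixed-model analysis of confounded experiments.
* Rank aggregation treats the input lists as exchangeable experts; if one
  method is known to be inappropriate for a design (e.g. BestKeeper's SD
  on genes of very different abundance), drop or down-weight its list.
* The pipeline recommends `optimal_n` genes from the consensus ranking;
  when candidate quality is uniformly poor the pairwise-variation series
  may never cross the cutoff, and the honest answer — use all $k$, or
  redesign the panel — is what the package reports.
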