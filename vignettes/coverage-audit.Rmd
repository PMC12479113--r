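---
title: "Auditing coverage gaps in TF ChIP-seq compendia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing coverage gaps in TF ChIP-seq compendia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfcoverage)
```

## The problem

A transcription-factor (TF) ChIP-seq experiment measures the genome-wide
binding sites of one TF in one biological sample, so a compendium of such
experiments covers a two-dimensional space of TF-sample pairs. Because a
ChIP-seq experiment is only meaningful where the TF is actually expressed,
the biologically relevant part of that space is the set of *expressed*
pairs, and the interesting audit object is the set of **unmeasured pairs**:
TF-sample combinations where the TF is expressed but no experiment exists.
This package builds that audit: it calls expression per (TF, cell line),
enumerates unmeasured pairs, quantifies how unequally experiments are
spread over TFs and cell types, measures how the gaps degrade two
downstream uses of the data (regulatory-TF lookup near promoters, and
GWAS-SNP annotation), asks whether a different acquisition order would
have served those uses better, and ranks unmeasured pairs worth doing
next.

All statistical machinery is validated on a synthetic-world generator with
planted ground truth; real compendium tables (ChIP-Atlas-style metadata,
HPA-style expression, KnockTF-style DEG counts, TF-marker lists, GWAS SNP
tables) are consumed through the same readers.

## Expression calls: the one-step threshold

For each TF, its expression values across cell lines are sorted ascending
and a one-step function is fit: every breakpoint $k \in 1..n-1$ splits the
values into a low block and a high block, and the fit minimizes

$$\mathrm{SSE}(k) = \sum_{i \le k}(v_i - \bar v_{low})^2 +
  \sum_{i > k}(v_i - \bar v_{high})^2 .$$

The threshold is the midpoint $(\bar v_{low} + \bar v_{high})/2$, and a
cell line is called expressed when its value is **strictly** above it
(values exactly at the threshold are not-expressed; the original
formulation is silent, so strictness is an explicit, configurable
convention). Ties in SSE are broken toward the smallest breakpoint, which
yields the most conservative expressed set. This is the binary variant of
the StepMiner idea; the two-step extension and the original F-statistic
are deliberately out of scope because only the binary call feeds the
audit.

Numerical choices:

* **Scale.** nTPM-like values are heavy-tailed, so `call_expression()`
  fits the step on the `log1p` scale by default and reports the threshold
  back on the data scale. On the raw scale the midpoint threshold sits far
  inside the expressed component of a log-normal mixture and recovery
  degrades badly; on the log scale, simulated mixtures separated by
  $4\sigma$ are recovered with per-pair accuracy above 0.95, approaching
  1.0 as $\sigma \to 0$. `fit_step()` itself is scale-agnostic.
* **Flat profiles.** A TF whose range is below
  $10^{-9}\max(1, \text{range})$ offers no step evidence; it is flagged
  flat and called not-expressed everywhere rather than thresholded inside
  numerical noise.
* **Missing values** are excluded from the fit, never imputed; rows with
  fewer than two values are reported as unfittable, not guessed.

Class-level calls use the "at least one" rule: a (TF, class) pair is
expressed when any constituent cell line is called expressed.

## Cell-line name matching

Expression and metadata resources spell cell-line names differently
("K-562", "K562", "K 562"). Matching is greedy one-to-one record linkage:
names are canonicalized (case fold; whitespace/hyphen/underscore/period
removal), scored with Jaro-Winkler similarity (standard definition,
prefix bonus $p = 0.1$, prefix cap 4), ranked by similarity with
lexicographic tie-breaks, and accepted at a configurable threshold
(default 0.9) *only if* the raw names carry identical digit multisets —
the digit check runs on raw names so canonicalization cannot erase the
one character that distinguishes K-562 from K-563. Greedy ranked matching
was chosen over optimal assignment because it is deterministic, auditable
(the full candidate log is returned), and adequate at compendium scale.
Because the original join's threshold and normalization are unpublished,
matching is validated by property (recovery of known pairings under name
perturbation), not by reproducing a specific line count.

## The inventory and inequality measures

The pair universe is {TFs with an expression call} x {samples in the
ontology mapping}. Each pair receives exactly one status: `measured` if at
least one experiment exists (regardless of the expression call),
`unmeasured` if expressed but not measured, `not_expressed` otherwise.
Measured pairs outside the universe (TFs never assayed by RNA-seq) are
surfaced separately instead of being forced into a status.

Inequality of experiment counts uses the mean-absolute-difference Gini

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x},$$

computed over all entities in the universe *including zeros* (an
unmeasured TF is part of the inequality, and the corresponding Lorenz
curves span all TFs/cell types). Twice the area between the diagonal and
the Lorenz curve equals $G$ exactly, which the tests verify to $10^{-9}$.
A flag excludes zero-count entities for sensitivity analysis. The
counterfactual Gini assumes every expressed pair had been measured once —
its per-TF count is the TF's expression breadth — and isolates the
inequality intrinsic to biology from the part added by uneven attention.
Spearman correlations (publications vs experiment counts; early- vs
late-period counts) use Pearson on average ranks, which is exact under
ties, rather than the $6\sum d^2$ shortcut.

## Cover ratios

Coordinates are BED-style 0-based half-open throughout; 1-based TSS and
SNP positions are converted on ingest (a SNP at position $p$ becomes
$[p-1, p)$), and "overlap" means at least one shared base, so abutting
intervals do not overlap. Promoter windows are TSS $\pm$ 500 bp
(symmetric; strand ignored), clipped at position 0.

* **Reg-TF cover ratio** (per cell line, per year): the fraction of the
  cell line's expressed genes — its top 25% by expression, with ceiling
  rounding and deterministic symbol-order tie-breaks — whose promoter
  window overlaps at least one peak from that cell line's experiments
  deposited up to and including the target year.
* **GWAS-SNP cover ratio** (per cell-type class by default, per year):
  the fraction of all de-duplicated GWAS SNPs overlapping at least one
  peak from the entity's experiments up to the year. The denominator is
  always the full SNP table. The level is a required parameter because
  the statistic is also meaningful per cell line; class is the default.

"Measured until the target year" is inclusive of the target year.
Cumulative pooling makes both annual series monotone nondecreasing, and
both are invariant to how peaks are split across files — properties the
tests enforce.

## Acquisition-order simulation

To ask whether a different history would have covered GWAS SNPs faster,
deposit dates are randomly permuted over the fixed experiment set of one
entity (the date multiset is conserved exactly), the annual GWAS-SNP
trajectory is recomputed per order, and each order is scored by
span-normalized trapezoidal AUC:

$$\mathrm{AUC} = \frac{1}{y_n - y_1}
  \sum_{k} \frac{r_k + r_{k+1}}{2} (y_{k+1} - y_k) \in [0, 1],$$

the time-averaged ratio of the piecewise-linear trend. The normalization
makes AUCs comparable across year ranges; a plain mean-of-years variant is
available behind a flag since the original metric is not spelled out. One
hundred shuffles are the default. Because every order eventually contains
every experiment, the final-year ratio is identical across orders — a
useful internal consistency check.

The comparison of selected orders (top-3/bottom-3 by AUC) against the real
order subsamples experiments uniformly without replacement (90% and 50%
retention, $\lceil fN \rceil$ kept, 50 subsamples per order and fraction by
default — the original count is unstated), recomputes AUCs, and applies a
two-sided Welch $t$-test with Satterthwaite degrees of freedom. The Welch
statistic is computed in closed form with an explicit degenerate branch
(both samples constant: $t = 0$, $p = 1$, flagged) because the textbook
formula is undefined there. Trajectory recomputation over thousands of
subsampled orders is driven by precomputed per-experiment SNP hit sets, so
a trajectory is a cumulative union of index sets rather than repeated
interval work; the tests verify the fast path equals the direct
computation.

## Prioritization

The impact proxy for a (TF, sample) pair is the number of differentially
expressed genes (DEGs) after knocking the TF out or down. Group
comparisons (marker vs non-marker TFs; measured vs unmeasured pairs) use
the Wilcoxon rank-sum test — exact by full enumeration when
$n + m \le 12$ with no ties, otherwise the normal approximation with tie
and continuity corrections, with the two-sided $p$ reported as exactly 1
when the statistic equals its null mean. No multiple-testing correction is
applied: each comparison is a single planned test, as in the source
analysis.

**Hidden gems** are the unmeasured pairs worth doing next: status
unmeasured, DEG count strictly above 1000 (the printed inequality is
strict, so exactly 1000 is excluded), and the TF annotated as a cell-type
marker. Multiple knockout records of one pair aggregate by maximum DEG
count (most permissive evidence of impact; mean is available). The filter
is monotone in the threshold and invariant to row order and to duplicated
lower-count records.

## The synthetic world

The generator emulates the statistical structure the audit assumes, with
every knob exposed in `world_config()`:

* **Attention skew.** Experiments are assigned to TFs (and, independently,
  cell types) by sequential preferential attachment,
  $P(\text{next} \to t) \propto (\mathrm{count}(t) + 1)^\alpha$. One knob
  reproduces both the Lorenz-curve skew and the early/late rank
  correlation: $\alpha = 0$ gives near-uniform counts (Gini < 0.3),
  $\alpha = 5$ gives strong concentration (Gini > 0.6).
* **Expression.** Each (TF, cell line) pair is truly expressed with
  probability $\pi$; values are log-normal with log-means
  $\mu_{low} < \mu_{high}$ and common $\sigma$ — heavy-tailed like real
  nTPM values. The truth is recorded, so call accuracy is measurable.
* **Peaks.** A fraction of each experiment's peaks falls inside promoter
  windows of genes expressed in that experiment's cell type, the rest are
  uniform; gene space and TF space coincide so expression, promoters and
  peaks share one namespace. A `tf_specific_peaks` mode confines each
  TF's peaks to a dedicated genome block, which makes coverage accrue
  with TF *diversity* rather than raw experiment count — the regime where
  acquisition order matters.
* **DEG counts and markers.** Log-normal DEG counts with a positive
  log-scale shift for marker TFs. A configurable number of hidden gems is
  planted among expressed-but-unmeasured class pairs: their TFs are
  marked, their DEG counts pushed strictly above the gem threshold, and —
  so that recovery has a unique right answer — every *other* unmeasured
  marker pair is clamped to the threshold or below.

Every component draws from a sub-seed derived deterministically from the
master seed, so a world is byte-identical across runs and across
partial regeneration of single components.

Default study conditions (chosen once as a realistic small compendium,
and used by the analysis scripts and the acceptance script): 60 TFs, 30
cell lines in 6 classes, 600 experiments over 2009-2023,
$\alpha = 1.5$, $\pi = 0.3$, $\mu_{low} = 0$, $\mu_{high} = 4$,
$\sigma = 0.8$ (5-sigma separation), a 2 x 1 Mb genome, 20 peaks of
200 bp per experiment at 50% TSS enrichment, 500 SNPs, and 2 planted
gems. These sizes keep a full pipeline run under a minute while leaving
every statistic away from degenerate regimes.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real genome sequence and chromatin context, GC
or open-chromatin peak-calling biases, antibody quality, correlated
expression across related cell lines, ontology curation errors, and the
actual value distributions of HPA/ChIP-Atlas beyond the stated
mixture/skew structure. Conclusions about real compendia require running
the same pipeline on the real tables through the format adapters.

## Degenerate inputs and edge policies

* All-zero count vectors have no Gini/Lorenz; they error rather than
  return 0.
* Groups with zero expressed pairs get an *undefined* unmeasured
  fraction (`NA` + flag), not 0.
* Duplicate rsIDs keep the first occurrence; duplicate experiment IDs are
  fatal; metadata rows with unparseable dates are dropped and enumerated
  in a load report (dropped + kept = input rows, always).
* Readers never coerce silently; conflicting cell-type-to-class mappings
  are fatal.

## Known limitations

* The expression threshold is global per TF; context-specific low-level
  expression is invisible to a one-step fit.
* DEG counts are a crude impact proxy (knockdown method, recovery time
  and cell context all move them); the gem filter is a shortlist
  generator, not a ranking.
* Greedy name matching can in principle be beaten by optimal assignment
  on adversarial inputs; at compendium scale with the digit guard this
  does not occur in testing.
* The acquisition-order simulation permutes dates over a fixed experiment
  set; it does not model the counterfactual choice of *which* experiments
  would have been done under a different policy.

## Reproducing the analyses

The numbered scripts under `analysis/` run the whole audit on the default
synthetic world and write their tables under `results/`;
`scripts/acceptance.R --seed <int> --out <path>` recomputes the headline
quantities from scratch and writes them as JSON. Problem sizes are the
default study conditions above (100 shuffled orders, 50 subsamples per
order and fraction).
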