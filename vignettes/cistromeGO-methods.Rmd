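---
title: "Regulatory potential and rank-based enrichment: the cistromeGO model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulatory potential and rank-based enrichment: the cistromeGO model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A transcription factor (TF) ChIP-seq experiment yields thousands of binding
intervals (peaks). The biological question is which genes the TF directly
regulates and which biological processes those genes implement. Tools that
assign peaks to genes by a hard distance cutoff produce a binary
target/non-target call that degrades when a cistrome has tens of thousands
of peaks: too many genes become "targets" and enrichment tests lose their
signal. cistromeGO instead gives every gene a continuous *regulatory
potential* (RP) score, ranks all genes by it, and tests gene sets directly
on the ranking with a threshold-free statistic, so no target cutoff is ever
chosen.

# Regulatory potential

For a gene $g$ with transcription start site (TSS) $t_g$, every peak $i$
whose center $c_i$ lies within $15\,d_0$ of $t_g$ on the same chromosome
contributes a weight that decays exponentially with distance:

$$
\mathrm{RP}_g \;=\; \sum_{i\,:\,|c_i - t_g| \le 15 d_0} 2^{-|c_i - t_g|/d_0}.
$$

The decay distance $d_0$ is a half-life: a peak on the TSS contributes 1, a
peak at $d_0$ contributes $1/2$, at $2d_0$ a quarter, and at the window
boundary $15\,d_0$ a negligible $2^{-15}$. We fix the half-life form
$2^{-d/d_0}$ because it makes "$d_0$ = decay distance" literal and keeps
every weight an exact power of two at multiples of $d_0$; a
logistic-shaped decay (as used in some target-prediction lineages) differs
only in the shoulder and would not change any ranking-level conclusion at
the window sizes used here. The window boundary is closed
($|c_i-t_g| \le 15 d_0$) so that results do not depend on floating-point
behavior exactly at the cutoff.

Conventions that the implementation pins down:

* Coordinates are 0-based half-open for BED input; the peak center is
  $\lfloor (start + end)/2 \rfloor$.
* Strand is ignored: the weight depends only on $|c_i - t_g|$.
* A gene annotated with several isoform TSSs is scored per TSS and takes
  the **maximum** — an isoform with a strongly bound promoter should not be
  diluted by unbound alternative starts.
* Genes on chromosomes without any peak score 0 and stay in the universe;
  every annotated gene participates in scaling and ranking.

Raw RP scores are min–max scaled to $[0,1]$ per dataset. Some genes attract
peaks in almost any ChIP-seq experiment (broadly open promoters); to
correct for this, a per-gene *baseline* — the median of the gene's scaled
RP over a collection of reference cistromes — can be subtracted, giving the
adjusted RP in $[-1,1]$. `computeBaseline()` implements exactly that
median; with no baseline table the adjustment is the identity. The gene
rank $R^{RP}$ orders genes by decreasing adjusted RP, with mid-ranks on
ties (required for the rank-product arithmetic) and lexicographic gene-id
order for deterministic output.

# Choosing the decay distance

TFs differ in where they bind. Promoter-dominant factors (E2F-like) place
most significant peaks within 1 kb of a TSS; enhancer-dominant factors
(nuclear receptors) mostly bind distally. `classifyTF()` ranks peaks by
their $-\log_{10}$ p-value and measures, for the top 2000, 5000, 10000 and
all peaks (each subset only when that many peaks exist), the fraction of
peak centers within 1 kb of the nearest TSS. If **any** fraction exceeds
0.20 the cistrome is called promoter-dominant and $d_0$ defaults to 1 kb;
otherwise enhancer-dominant with $d_0 = 10$ kb. The subsets protect the
call against low-significance noise peaks: a sharply promoter-bound factor
with a long noisy tail still shows a high fraction in its top peaks.
"Within 1 kb" is closed and "exceeds" is strict; peaks with no
significance score can only be judged on the "all" subset. A user override
of $d_0$ bypasses the defaults but the classification report is still
emitted.

# Integrating differential expression

When a perturbation experiment on the TF is available (knock-down,
stimulation, ...), its DGE table supplies an independent ranking $R^{DE}$
by differential-expression p-value, optionally restricted to up- or
down-regulated genes. The two rankings are combined by the **rank
product** $R^{RP}_i \cdot R^{DE}_i$: genes near the top of both lists —
bound *and* responsive — get the smallest products and are the best
direct-target candidates. The gene universe of the combination is the
intersection of the two lists, and both ranks are re-computed within the
intersection (from the input ranks, which keeps the operation symmetric in
its two arguments); genes observed in only one data type are dropped and
counted rather than given fabricated ranks. No significance is attached to
the product itself — it is used purely as an ordering.

As a diagnostic, the package also reports ROC and precision–recall curves
asking how well adjusted RP alone predicts the DE-significant genes
(default label rule `padj < 0.05`, falling back to the raw p-value when no
adjusted column exists). The AUROC is computed by a full threshold sweep
with tie-aware trapezoids, which makes it exactly the Mann–Whitney
$U/(n_+ n_-)$ statistic.

# Threshold-free enrichment: the minimum hypergeometric test

Given the final gene ranking and a gene set (GO term, pathway), membership
is written as a 0/1 series down the ranking. For each prefix length $n$,
the hypergeometric tail
$\mathrm{HGT}(n) = P[X \ge b_n]$, $X \sim \mathrm{Hypergeom}(N, B, n)$,
measures surprise at seeing $b_n$ members in the top $n$. The **mHG
statistic** is $\min_n \mathrm{HGT}(n)$ — the best cutoff is chosen by the
data, not the user. Because this minimum is itself selected over $N$
cutoffs, it is not a p-value; the exact p-value is the probability, under
uniform random placement of the $B$ ones, that the minimum is at most the
observed statistic.

That probability is computed exactly by a dynamic program over the
$(n, b)$ prefix lattice. The implementation (C++) runs the DP in
*probability space*: the walk that reveals the series one rank at a time
steps to a member with probability $(B-b)/(N-n)$, so each lattice cell
holds the probability of reaching it without having entered the rejection
region $\{(n,b): \mathrm{HGT}(n,b) \le s\}$; mass entering a rejection cell
is added to the p-value and absorbed. Every intermediate quantity is a
probability in $[0,1]$, so the computation cannot overflow for any $N, B$
(path *counts* would exceed double range already at $\binom{5000}{2000}$).
The per-row tails are built by a descending pmf recurrence, giving
$O(NB)$ total cost. Two numerical guards: rejection membership is decided
with relative tolerance $10^{-12}$ (so the cell that attains the minimum is
always counted despite round-off between `phyper` and the recurrence), and
a p-value that underflows double precision is clamped to the smallest
positive double rather than reported as 0. The test suite verifies the DP
against exhaustive enumeration of all $\binom{N}{B}$ arrangements for
every $N \le 12$.

Ranking ties are broken by gene id before the series is built (the mHG
needs a total order; a deterministic tie-break beats an arbitrary one),
and the number of ties is reported.

## Term filtering and reporting

Terms are intersected with the ranking universe, and kept only with 10 to
2000 members after intersection: smaller sets are statistically
unreliable, larger ones too generic to say anything about one TF's
program. Near-duplicate terms (Jaccard index strictly above 0.85) are
collapsed by a greedy pass that keeps the larger (post-intersection) set,
with ties broken by set id. Each surviving term gets the mHG statistic,
its optimal cutoff $n^*$, the exact p-value, a Benjamini–Hochberg FDR
across the tested collection (each GMT collection is tested and corrected
separately), and a fold-style enrichment score
$(b_{n^*}/n^*)/(B/N)$ at the optimal cutoff. The full table is always
written; the "reported" companion is restricted to FDR < 0.2.

# The synthetic-data generator

`fixtureSpec()` describes a toy study: evenly spaced genes on a handful of
chromosomes, one planted target program, background peaks, and a DGE table
with planted signal. Defaults — 5000 genes spaced 100 kb on 5 chromosomes,
a 50-gene planted term, 50 null terms with log-uniform sizes spanning
5–2500 (so both size filters fire), Poisson(3) signal peaks per bound
target at exponential(200 bp) distances from the TSS, 10000 uniform
background peaks, planted $-\log_{10} p = 4 + \mathrm{Exp}(1)$ against a
uniform null — were chosen once as a desk-scale caricature of a mid-sized
TF experiment: strong but imperfect binding signal (about 5% of targets
draw zero peaks), a background peak density of one per 50 kb, and DE
signal clearly separated from the uniform null. All randomness derives
from a single integer seed; identical specs produce byte-identical files.

What the generator deliberately does **not** emulate: real chromosome
lengths and gene clustering, isoform structure, peak-width variation,
correlated backgrounds (open-chromatin bias), or the heavy-tailed
significance distributions of real peak callers. Passing tests on these
fixtures therefore demonstrate the *machinery* — exactness of the
statistics, correctness of the plumbing, recovery of planted signal under
the stated noise — not performance on real cistromes.

# Problem sizes and runtime choices

The shipped tests and the acceptance script run the planted-fixture
pipeline at 5000 genes / ~10000 peaks / 51 terms over 20 seeded
replicates, enumerate the mHG oracle for all $N \le 12$, and calibrate the
null on 2000 random terms over a 1000-gene universe. These sizes give
every stochastic check a comfortable margin (binomial standard errors well
inside the asserted bands) while keeping a full run in the low minutes on
a single core; the mHG DP itself handles $N$ in the tens of thousands.

# Known limitations

* The decay form is fixed (half-life exponential); only $d_0$ is tunable.
* The rank product carries no significance estimate, by design.
* Terms are flat gene sets: no GO DAG propagation or semantic similarity.
* Baselines are only meaningful when computed over (or supplied from) a
  reference collection matching the annotation's gene universe.
* mHG statistics below roughly $10^{-300}$ clamp at the double-precision
  floor; orderings among such extreme terms follow the clamped values and
  should be read as "indistinguishably extreme".
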