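---
title: "Methods: quantification and integrative analysis of two-channel m6A arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification and integrative analysis of two-channel m6A arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meriparray)
```

# The measurement model

A MeRIP two-channel array splits each RNA sample by anti-m6A
immunoprecipitation: the methylated fraction is labeled in one channel
("IP"), the supernatant in the other ("Sup"), and both hybridize to the
same probes. If a transcript has total abundance $E$ and a methylated
fraction $\pi$, the channels ideally measure

$$\mathrm{IP} = A_{s,\mathrm{IP}}\, E\, \pi, \qquad
  \mathrm{Sup} = A_{s,\mathrm{Sup}}\, E\, (1-\pi),$$

where $A_{s,c}$ is an unknown per-array-per-channel scale (labeling
efficiency, scanner gain, hybridization). Exogenous spike-in RNAs at fixed
nominal amounts are measured on every array channel and absorb the same
$A_{s,c}$, so they identify it.

**Normalization.** For each array channel the anchor
$s_{s,c} = \mathrm{mean}_{\text{spike-ins}} \log_2(\mathrm{raw} + \varepsilon)$
is subtracted from every probe's $\log_2(\mathrm{raw} + \varepsilon)$;
the grand mean $G$ of all anchors is added back. Subtraction on the log2
scale is division by the geometric-mean spike-in level on the linear
scale, so any multiplicative $A_{s,c}$ common to all probes of an array
channel cancels exactly; $G$ only restores an interpretable absolute level
and cancels in every ratio the pipeline forms. An equally defensible
convention would divide by the linear-scale arithmetic mean of spike-ins;
we chose log-scale anchoring because it is exactly invariant under
multiplicative array effects and matches two-channel practice.

**Quantification.** With linear normalized values $ip$ and $sup$,

$$\mathrm{m6A\%} = 100\,\frac{ip}{ip + sup}, \qquad
  \mathrm{expression} = ip + sup.$$

When several probes map to one transcript their log2-normalized values are
averaged per channel first (the standard two-channel summarization; the
bundled generator emits one probe per transcript, so this is usually a
no-op).

**The $\varepsilon$ floor.** $\log_2(\mathrm{raw} + \varepsilon)$ with
$\varepsilon = 1$ fluorescence unit (default) guards against zero
intensities in scanner exports. The floor biases low-intensity probes
upward by up to $\varepsilon/(\mathrm{raw}\,\ln 2)$ log2 units; in
validation runs on simulated data — whose intensities are strictly
positive by construction — we set `epsilon = 1e-12` so that exactness
checks are not limited by the floor rather than by the arithmetic under
test.

# Differential screening

Each transcript is tested separately on the two layers with a
pooled-variance (Student's) two-sample t-test, SCI vs sham:

- methylation: on the raw m6A percentages; fold change is the ratio of
  group means. A logit-scale option (`meth_on_logit = TRUE`) is available
  because percentages are bounded, but raw percents are the default as the
  simplest convention for this platform's statistic.
- expression: on $\log_2(\mathrm{expression})$; fold change is
  $2^{\Delta \text{mean}}$ (geometric).

Screening calls hyper/hypo (methylation) or up/down (expression) at
fold change $\ge$ 1.5 — the boundary is inclusive, a "1.5-fold cutoff"
being read as a minimum — and raw $p < 0.05$. Benjamini–Hochberg adjusted
p-values are computed within each layer × biotype stratum and reported
alongside, but screening deliberately uses raw p-values, matching the
platform convention for these arrays. With $n = 3$ per group the t-test
has 4 degrees of freedom; the pooled (rather than Welch) form is used
because it is the classical "Student's t-test" and the two groups are
processed identically. Degenerate inputs are resolved exactly: when both
groups have zero variance, $p = 1$ for equal means and $p = 0$ otherwise.

# Nine-quadrant integration

The conjoint analysis places every transcript in the 3×3 grid
{hyper, ns, hypo} × {up, ns, down}. An axis is non-ns iff
$|\log_2 \mathrm{FC}| \ge 1$ (fold change $\ge 2$, boundary inclusive)
**and** raw $p < 0.05$ on that axis; both gates are applied on both axes
because the conjoint lists are intersections of the two differential
lists. The four corner modes are reported; hyper-up and hypo-down are the
concordant ("DME", differentially methylated and expressed) modes, and the
discordant corners are computed and reported as well even where a study
only highlights the concordant ones.

# lncRNA classification and cis targets

Positional classes are assigned by precedence against coding genes:
exon-sense-overlapping (same-strand span overlap that is not strict
containment — an identical span counts here), intronic (strict same-strand
span containment; with span-level annotation, containment stands in for
intron residence), natural-antisense (opposite-strand overlap),
intronic-antisense (opposite-strand containment), bidirectional (TSSs
within 1 kb on opposite strands without overlap), else intergenic. The
taxonomy is the standard array-annotation one; the 1-kb promoter window is
configurable.

Cis targets are mRNAs whose span lies within 100 kb of the lncRNA span:
same chromosome, gap between 0-based half-open intervals $\le$ the window,
boundary inclusive, strand-agnostic, distance 0 for overlaps. Measuring
between span boundaries (rather than TSSs) is the simplest defensible
anchor when none is prescribed. lncRNA function is then predicted by
enriching the union of the cis-target gene symbols of a lncRNA list.

# Enrichment

Over-representation of a study list against user-supplied GMT sets uses the
one-sided hypergeometric upper tail $P(X \ge k)$, computed by summing the
pmf (exact; $p = 1$ when $k = 0$). The universe defaults to all annotated
genes of the matching biotype — the array background, the convention for
microarray enrichment — rather than a whole-genome background; both the
study list and each set are intersected with the universe before counting.
No term database is bundled: the engine accepts any GMT, and tests use
synthetic sets, because database-version-dependent term lists are not
reproducible properties of the method.

# PPI network and MCODE

Edges are kept when the combined confidence score is **strictly** greater
than the cutoff (default 0.4); the wording "greater than 0.4" is taken
literally even though the common STRING "medium confidence" convention is
$\ge$, and the cutoff is configurable. Self-loops are dropped and duplicate
edges keep the maximum score.

MCODE is implemented from scratch following the published algorithm.
Vertex weight: the highest $k$-core of the subgraph induced by the closed
neighborhood $N[v]$, weight $= k \times$ density of that core. Complex
growth: seeds are processed in decreasing weight order (ties
lexicographic); from an unvisited seed with weight $w$, neighbors join in
breadth-first order when their weight is at least $w (1 - \mathrm{vwp})$,
each vertex joining at most one complex (first claim wins by rank, the
standard single-membership behavior). Defaults mirror the Cytoscape
plugin: vwp $= 0.2$, haircut on, fluff off, no loops. Haircut replaces a
complex with its 2-core; when the 2-core is empty — the complex is a
single edge, the minimal admissible module of score $2$ — the grown
complex is kept, so minimal modules are not silently destroyed. Complexes
are ranked by score $2E/(n-1)$ (density × size), ties broken by size then
seed id; a 44-node module with 289 internal edges, for example, scores
$2 \cdot 289 / 43 = 13.442$.

# The synthetic generator

`simulate_experiment()` emulates a 3-vs-3 two-channel experiment at desk
scale (defaults: 2,000 mRNAs + 500 lncRNAs, one probe per transcript, 10
spike-ins at $2^{10}$):

- sham methylated fraction $\pi \sim \mathrm{Beta}(2, 6)$ (mean 0.25 —
  moderate modified fractions with a realistic right tail);
- sham expression $E = 2^{N(10, 1.5)}$ (typical log2 intensity range);
- per-array-channel factors $A = 2^{N(0, 0.25)}$, the nuisance the
  normalization must remove;
- replicate noise $2^{N(0, 0.25)}$ independently per transcript × sample ×
  channel (no noise model is prescribed by the platform; 0.25 log2 units
  is a stipulated, realistic choice);
- spike-ins receive the array factor but no biological noise, which makes
  the normalization exactly identifiable and its test sharp;
- planted effects (defaults: 100 hyper-up, 100 hypo-down, 50 hyper-only,
  50 up-only, split between biotypes proportionally): expression effects
  add $\pm 1.5$ to $\log_2 E$; methylation effects add $\pm 2$ to the
  log2 **odds** $\pi/(1-\pi)$, keeping fractions inside $(0, 1)$ for any
  effect size.

**Why planted baselines are truncated.** An odds fold change of $2^e$
yields a percent-m6A fold change of $2^e (1+o) / (1 + 2^e o)$ at baseline
odds $o$, which is below 2 whenever $o > 1 - 2^{1-e}$: a transcript already
half methylated cannot double its percentage. So that every planted effect
is expressible as a fold change at the screening scale, baselines of
methylation-planted transcripts are drawn from the same Beta truncated to
$\pi \le 0.3$ (giving percent fold changes $\ge 1.53$ at $e = 1$ and
$\ge 2.1$ at the default $e = 2$, with margin). The truth table stores
`true_meth_log2fc` on the measured scale — the log2 percent ratio implied
by the planted odds effect — so noise-free recovery is exact by
construction and testable to $10^{-9}$.

**Power under small odds effects.** The noise model fixes what is
detectable: with per-channel log2 noise of 0.25, the log2 odds (hence, to
first order, the logit of the percent) has SD $0.25\sqrt{2} \approx 0.354$
per replicate, so a 1-log2-unit odds effect gives a pooled-t noncentrality
of $1/(0.354\sqrt{2/3}) \approx 3.46$ at $n = 3$ per group — two-sided
power $\approx 0.74$ at $\alpha = 0.05$, before the fold-change gate
(which bites because the percent ratio $2/(1+o) < 2$ approaches 1.5 as
$o \to 1/3$). Detecting modest odds shifts reliably at this noise level
needs larger effects (the default $e = 2$), more replicates, or lower
noise; this is a property of the design, not of the implementation.

**What the generator does not emulate.** Multiple probes per transcript,
dye bias, spatial artifacts, background signal, intensity-dependent
variance, and correlated transcripts. Tests passing on this generator
therefore validate the arithmetic, calibration and bookkeeping of the
pipeline under its own model assumptions — not robustness to the full mess
of real arrays.

# Numerical and reproducibility choices

- All output reals are written with 12 significant digits, making reruns
  byte-identical and round-trips exact to that precision; coordinates are
  0-based half-open everywhere (noted in each file header) so interval
  arithmetic has no off-by-one ambiguity.
- The generator consumes randomness in a fixed order from a single seed;
  the pipeline itself is deterministic.
- Ties: enrichment results sort by p then set id; MCODE seeds by weight
  then vertex name; clusters by score, size, seed id.
- Problem sizes in the test suite (hundreds to 2,500 transcripts, graphs
  up to 8 nodes for exhaustive oracles, 1,000 genes for all-pairs interval
  checks) are chosen so every oracle can be computed by brute force while
  the suite stays fast.
- The exported functions and `run_pipeline()` are the interface; there is
  no shell entry point, since the package's users drive it from R scripts.

# Known limitations

- The spike-in anchor assumes spike-in probes behave multiplicatively like
  biological probes on the same array channel; additive background is not
  modeled (no background subtraction, dye-swap or quantile step).
- Student's pooled t at $n = 3$ is fragile to variance outliers; a
  moderated (empirical-Bayes) test would be more powerful but is outside
  this pipeline's convention.
- Span-level annotation cannot distinguish truly intronic lncRNAs from
  exon-overlapping ones; the "intronic" classes are span-containment
  proxies.
- Enrichment ignores the GO DAG and pathway topology; it is a plain
  over-representation engine over whatever sets are supplied.
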