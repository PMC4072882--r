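---
title: "Methods: negative-binomial DE between polyp types with heterogametic adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: negative-binomial DE between polyp types with heterogametic adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`polypDE` analyses bulk RNA-seq of the three polyp types of a colonial
hydrozoan — gastrozooids (feeding), gonozooids (reproductive) and
dactylozooids (defensive) — with twelve libraries: four per polyp type,
the gonozooid four split two male / two female. This vignette is the
package's own account of the statistical model, the staged adjustment for
gametogenic expression, the choices made where the design was open, and
what the synthetic benchmarks do and do not demonstrate.

## Counting model

The expression matrix is built from SAM alignments of paired-end reads
against the transcriptome: a fragment contributes one count to transcript
$t$ iff both mates carry primary alignments referencing $t$. Pairs with an
unmapped mate, mates split across transcripts, unpaired records and
secondary/supplementary alignments contribute nothing. This is
deliberately strict — no fractional assignment of multi-mappers, no
rescue of discordant pairs — so a count is always a whole concordant
fragment on a single transcript. Whether the original rule additionally
required the proper-pair flag is not knowable from the counting contract
alone; `polypDE` requires only "same reference, both primary", the
minimal reading.

Counts $k_{ij}$ for transcript $i$ in library $j$ are modeled negative
binomial with mean $s_j q_i$ and variance $\mu + \alpha_i \mu^2$, where
$s_j$ is a library size factor (median-of-ratios over transcripts with
all-positive counts; no pseudo-reference fallback is applied, and the
size-factor routine refuses matrices where the reference set is empty
rather than silently switching estimators) and $\alpha_i$ a
per-transcript dispersion.

## Dispersion estimation: two engines

Both engines start from a method-of-moments estimate. With normalized
counts $r_{ij} = k_{ij}/s_j$, base mean $q_i$, pooled within-condition
sample variance $w_i$ and shot-noise term $z_i = q_i \cdot
\overline{1/s_j}$:

$$\alpha^{raw}_i = \max\!\left(0, \frac{w_i - z_i}{q_i^2}\right),$$

and a trend $\alpha(q) = a_1/q + a_0$ ($a_0, a_1 \ge 0$) is fitted to the
positive raw values by iterated weighted least squares with gamma-style
weights $1/\hat\alpha^2$ (closed-form and robust at this scale; a local
regression would add flexibility the downstream tests do not need). If
the fit degenerates the global mean raw dispersion is used, with a
warning.

* The **conservative** engine takes $\alpha_i = \max(\alpha^{raw}_i,
  \alpha(q_i))$: no transcript is ever tested with less than the trend
  dispersion. This sacrifices power for safety and is the stricter of the
  two engines by construction.
* The **shrinkage** engine maximizes, over a log-spaced grid
  ($10^{-4}$–$32$, 80 points), the transcript's Cox–Reid adjusted profile
  log-likelihood (condition means profiled out via normalized-count group
  means; the CR term $-\tfrac12 \sum_c \log \sum_{j\in c}
  \mu_{ij}/(1+\alpha\mu_{ij})$ removes the downward bias of plug-in
  means) plus a weighted average of the same likelihood over the 500
  transcripts nearest in base mean. The window is realized as a centered
  rank window on transcripts sorted by base mean, which makes the local
  term a rolling mean computable in $O(nG)$. The prior weight defaults to
  **10 prior degrees of freedom**, i.e. the local term is weighted by
  $10/\mathrm{df}_{res}$ pseudo-transcripts. An earlier formulation
  weighting it by 10 full pseudo-transcripts (~80 prior df here)
  over-shrank genuine high-dispersion outliers and pushed the observed
  FDR on 10%-non-null mixtures above its nominal target; the
  degrees-of-freedom convention is the one the weighted-likelihood
  literature uses and restores calibration.

Conditions with fewer than two libraries contribute nothing to either
estimate: their fitted mean equals the observation and carries no
dispersion information.

Dispersion is estimated once per analysis from the full library universe
of that analysis under a declared condition grouping, then reused for
every pairwise test. The grouping matters: binning male and female
gonozooids as one condition absorbs the heterogametic differences into
$w_i$ and inflates dispersion; splitting them (`"split"`) removes that
component and increases power. This inflation-versus-split contrast is
itself one of the package's reported diagnostics.

## The exact test

Two groups $A, B$ are compared conditionally on their total
$K_S = K_A + K_B$. With pooled concentration $\hat q = K_S/(\sum_A s_j +
\sum_B s_j)$, each group sum is modeled NB with mean $\mu_A = \hat q
\sum_A s_j$ and variance equal to the **sum of the per-library NB
variances**, $\sum_{j \in A} (\hat q s_j + \alpha (\hat q s_j)^2)$ —
an effective group dispersion $\alpha \sum s_j^2 / (\sum s_j)^2$, about
$\alpha/n$ at equal depths. Treating the sum as NB with the per-library
$\alpha$ instead would overstate its variance roughly $n$-fold and
collapse the type-I error far below nominal; the per-library-variance
form keeps the 4-vs-4 raw $p<0.05$ fraction at 0.03–0.05 in the
package's null benchmarks. The p-value sums, over all splits $a+b=K_S$,
the probabilities of splits no more likely than the observed one (ties
included — the conservative direction), normalized by the total. Splits
are enumerated exactly up to $K_S = 10{,}000$; beyond that a normal
approximation to the conditional split distribution (with continuity
correction) takes over. $p$ is clamped into $(0,1]$ and a transcript with
zero counts in both groups is *not tested* (distinct from $p=1$), and
excluded from the Benjamini–Hochberg adjustment's $m$. BH was chosen for
`p_adj` because both classical count-based DE tools default to it. One
known quirk of the "sum of less-likely splits" two-sided rule: when the
effective dispersion exceeds 1 the conditional split distribution is
U-shaped and a perfectly balanced split is no longer modal, so an
identical-counts transcript can receive $p<1$; BH keeps such cases far
from significance.

Fold changes are $\log_2((\bar r_A + 1)/(\bar r_B + 1))$ with a
pseudo-count of one normalized count to avoid infinities; the sign is
anchored to the first-named condition.

## The staged heterogametic adjustment

Male and female gonozooids are morphologically identical apart from
their gametes, so male-vs-female expression differences are attributed
to gametogenesis. The workflow:

1. DE between the two male and two female gonozooid libraries
   (dispersions under the split grouping of all twelve libraries).
2. Partition at $p_{adj} < 0.05$: `male_up`, `female_up`, `nonsig`.
3. **Black branch** — cross-polyp DE on `nonsig` with all libraries.
   **Red branch** — `female_up` transcripts are putative maternal mRNAs
   (deposited for embryos, yet possibly somatically relevant), re-tested
   with the female gonozooid libraries removed so the gonozooid condition
   is represented by male libraries only. `male_up` transcripts are
   excluded from the template pool entirely; no mirrored male branch
   exists, and that asymmetry is preserved as designed rather than
   "fixed". Each branch is BH-adjusted within itself — they are separate
   analyses whose results are combined — and the output rows carry a
   `branch` label. For the dactylozooid-vs-gastrozooid comparison both
   branches still apply (the partition changes the tested set, the split
   grouping changes dispersions); the red branch there uses all eight
   non-gonozooid libraries. Red-branch dispersions are estimated from the
   ten libraries that branch actually uses — including the female
   gonozooid libraries in a branch whose premise is their removal would
   reintroduce the confound being removed.

**Known limitation.** The screen and the red branch share the male
gonozooid data. The screen preferentially captures female-up transcripts
whose male counts dipped low by chance, and in the red branch that dip
can masquerade as a gonozooid-down somatic effect (a winner's curse).
On default synthetic data this produces on the order of 1–10 spurious
red-branch calls per 5,000 transcripts among captured pure-gametic
transcripts, so "captured gametic transcripts never reappear" holds only
approximately, not as an invariant. The black branch and the exclusion
of `male_up` are structural and leak nothing.

## Consensus polyp-specificity

With three pairwise comparisons under both engines, a transcript is
called specific to polyp $X$, direction up, iff under **both** engines it
is significant with the $X$-higher sign in **both** comparisons involving
$X$ and non-significant in the third; down mirrors with $X$-lower signs
(the third comparison's sign is unconstrained). Transcripts significant
in all three comparisons receive no call — they do not fit the
three-circle summary — and are counted separately in the output metadata.
Engine agreement requires both significance and sign agreement. In the
Venn-style summary the intersection of two polyps' circles equals the
down-count of the excluded polyp: down-regulation in one polyp is
equivocal up-regulation in the other two.

## Diagnostics

Library distances are Euclidean over $\log_2(r_{ij}+1)$ — the transform
is unstated in the workflow this package re-implements, and this choice
is simple, monotone and reproducible. Classical (Torgerson) scaling
embeds the distance matrix in 2-D; axes are ordered by eigenvalue and
each axis's sign is fixed so its first nonzero loading is positive, so
embeddings are comparable across runs (up to the row-order dependence of
that convention). Removing the screen-significant transcripts moves the
male and female gonozooid libraries toward each other relative to the
other polyps — clustering by polyp type rather than sex — which the
package quantifies as the within-gonozooid to gonozooid-to-other
distance ratio.

## The synthetic-data generator

`simulate_counts()` emulates the study conditions: 12 libraries in the
design above; baseline means $q_i$ log-uniform over $2^2$–$2^{12}$
(spanning the dispersion–mean trend); dispersions log-normal with
log-mean $\ln 0.1$ and log-sd 0.8 (typical bulk RNA-seq magnitude);
library depth factors spread ~2.7-fold (the study does not state its
depth asymmetries; this is a plausible choice made once, not fitted);
default effect magnitude 3 log2 units. Effect classes: null (82%),
up/down in each polyp (1.5% each), male- and female-gametic (3%/4%,
modulating only the matching-sex gonozooid libraries), and
maternal-somatic (2%): a +2 log2 female-gametic effect **and** a
gonozooid-wide somatic effect — the class the red branch exists to
rescue. One root seed feeds per-stage derived streams, and all
per-transcript draws run in transcript order, so enlarging the
simulation extends it without reshuffling earlier transcripts.

What the benchmarks show: calibration (type-I, FDR), recovery and
ranking behaviour under an NB world that matches the model family, and
the directional effects of the adjustment (dispersion drop, power gain,
maternal rescue). What they do not show: robustness to outliers and
count contamination, multi-mapping ambiguity, GC/length biases,
correlated libraries, or any misspecification of the NB family — real
data carry all of these, and passing here does not certify them. SAM
fixtures use fixed dummy sequences and flags 99/147 for concordant
pairs; they exercise the counting contract, not read-level realism.

## Problem sizes and numerics

The shipped tests run the statistical checks at 1,000–10,000 transcripts
and 1–10 seeds per property, sizes at which the measured quantities are
stable to well within their acceptance bands on a single CPU. The exact
test's enumeration cap (10,000), the dispersion grid (80 points), the
trend IWLS (10 iterations) and the tie tolerance in the rejection sum
($10^{-12}$ relative, in log space) are fixed constants; the screening
level $\alpha = 0.05$ and all thresholds are arguments, nothing is
hard-coded. Degenerate inputs — empty partitions, all-zero transcripts,
a screen at $\alpha = 1$, collinear distance configurations — fall back
to defined behaviour (empty branches, not-tested markers, 1-D embeddings
with a warning) rather than errors.

## Interface shape

The package exposes the pipeline as composable functions whose central
results are classed objects with `print`/`summary`/`plot` methods
(`de_table`, `dispersion_fit`, `gametic_partition`,
`specificity_calls`), in the style of classic R modelling code; a single
fitting function would not fit a multi-stage pipeline, but each stage's
result behaves like a fitted-model object. `run_pipeline()` orchestrates
the stages and writes TSVs plus a JSON manifest with per-stage row
counts and file hashes; a thin `Rscript` wrapper (`inst/exec/polypde`)
exposes the same stages as subcommands.
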