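---
title: "Modeling dual-guide CRISPRi genetic interaction screens"
author: "dualscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dual-guide CRISPRi genetic interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

## The experiment this package models

A dual-guide CRISPRi screen expresses two sgRNAs from one lentiviral
cassette, silencing two genes per cell. Sequencing the integrated cassettes
at the start of the screen (T0) and after 14 days of growth (T14,
approximately ten population doublings) measures each construct's fitness
effect as a log2 fold change (LFC) of its abundance. Constructs that deplete
much more than expected from the two single-gene effects mark negative
genetic interactions; when each single knockdown is tolerated but the
combination is not, the pair is synthetic lethal.

`dualscreen` implements the full computational path of such a screen:

1. **Library design** — tiered guide ranking, mismatch-variant selection for
   strong-phenotype genes, the combinatorial pairing scheme, and the oligo
   pool.
2. **Counting** — exact protospacer matching of paired reads into an
   element-by-sample count matrix.
3. **Normalization** — median-ratio size factors anchored on non-targeting
   (NT) constructs, a T0 representation filter, pseudo-counted LFCs,
   essential-guide calling and mismatch-variant substitution.
4. **Interaction model** — guide efficacies, gene effects and pair
   interactions fitted jointly; sensitive/strong scores with the
   clip-at-zero, negative-sign reporting convention.
5. **Downstream** — synthetic-lethal calls, annotated networks, Ward
   clustering of interaction profiles, 2-D embedding, cross-cell-line
   comparisons.
6. **Simulation** — a generator producing ground-truth parameters, counts
   and FASTQ reads with the statistical structure the analysis assumes.

## Library design rules

Genes are split into three tiers that determine how their candidate guides
are ranked: growth phenotypes for K562-essential genes (tier 1), the average
phenotype across screens in which the gene scored for recurrent hits
(tier 2, at least four screens), and activity-prediction regression scores
otherwise (tier 3). For genes with strong knockout growth phenotypes each
transcription start site contributes its top guide plus a *mismatch variant*
of that guide — a singly mismatched protospacer conferring partial knockdown
so that the construct survives long enough to report interactions. Variants
need an on-target specificity score of at least 0.15 and are chosen by
measured relative activity within 0.47 ± 0.15 (closest to 0.47), falling
back to predicted activity closest to 0.5. Other genes contribute their top
two guides.

`buildPairSet()` then realizes the pairing scheme: one random orientation
("ab" or "ba", seeded RNG over lexicographically sorted gene pairs) per
unordered gene pair with all guide cross-products in that orientation; all
distinct same-gene guide pairs once, in guide-id-sorted orientation (the
orientation of same-gene pairs is not constrained by the screen design, so
we fix a canonical one); every targeting guide paired with all 15 NT guides
in both orientations; and all 225 ordered NT×NT combinations as negative
controls. A design over *G* genes therefore queries `choose(G, 2)`
gene-level interactions — 149,878 for the 548-gene design used throughout
the examples. Oligos are `upstream + protospacer_a + middle + protospacer_b
+ downstream` (148 nt); splitting on the constant regions recovers both
protospacers exactly, which the tests exploit as a round-trip invariant.

## Counting

Assignment mirrors an exact-matching (hamming distance 0) k-mer search:
each read's first 22 bp are scanned at offsets 0–2 for a 20-mer present in
the position-specific protospacer map (read 1 → position a, read 2 →
position b). Both guides must resolve and the ordered pair must be a library
element; otherwise the pair is logged as `too_short`, `bad_bases`,
`ambiguous` (a read matching two different protospacers is discarded rather
than guessed), `no_match_a/b`, or `invalid_pair`. Read conservation
(assigned + unassigned = total) is asserted in the tests. Whether read 2 is
sequenced protospacer-forward or on the opposite strand differs between
chemistries; `rcRead2 = TRUE` applies reverse-complementation first, and the
simulator writes both reads forward, which is the default.

## Normalization and LFCs

Size factors use the median-of-ratios method computed only on the NT×NT
constructs — the purest null set, since neither position carries a targeting
guide (`reference = "any_nt"` widens this to every NT-containing element).
The estimation is delegated to `DESeq2::estimateSizeFactorsForMatrix()` on
the reference rows; elements with a zero in any sample are excluded from the
geometric-mean reference, and at least one all-positive reference element is
required.

LFCs are `log2((n_T14 + p)/(n_T0 + p))` on normalized counts `n`, computed
per replicate after removing elements with fewer than 50 raw T0 reads in any
replicate. The pseudo-count `p` deserves a note. A fixed pseudo-count has
meaning only relative to sequencing depth: 10 reads is a gentle shrinkage at
500 reads per element and a heavy one at 50. We therefore specify the
pseudo-count in *reads at nominal coverage* (500 per element, the coverage a
screen of this design maintains) and anchor it to the dataset's own
reference coverage: `p = pseudo × referenceScale / nominalCoverage`, where
`referenceScale` is the geometric mean coverage of the usable reference
elements. At nominal depth this is exactly the conventional pseudo-count of
10; at any other depth it scales proportionally, which makes every LFC
**exactly invariant** to globally rescaling all samples' counts (the
acceptance suite checks agreement to 1e-9). `nominalCoverage = NULL`
restores the literal fixed pseudo-count.

Guides whose mean LFC across all NT-partner elements and replicates is
strictly below −3 are called essential; their single knockdown already
depletes so strongly that pair phenotypes cannot be read from the perfect
guide. For every essential perfect guide with a designed mismatch variant,
all elements containing the perfect guide are dropped and the variant's
elements carry the gene from there on. Essential guides without a variant
are retained with a warning — dropping them entirely would silently remove
the gene.

## The interaction model

For element *c* with guides *a* (gene *g*) and *b* (gene *h*) the expected
phenotype on the T14 LFC scale is

$$
\mu_c =
\begin{cases}
x_a y_g + x_b y_h + x_a x_b\, s_{gh} & \text{inter-gene} \\
x_t y_g & \text{guide } t \text{ with an NT partner} \\
\bigl(1 - (1 - x_a)(1 - x_b)\bigr)\, y_g & \text{same-gene pair} \\
0 & \text{NT} \times \text{NT,}
\end{cases}
$$

with guide efficacies $x \in [0, 1]$ (0 for NT guides), gene effects $y$ and
pair interactions $s$. The product $x_a x_b$ for pair efficacy and the
probabilistic union for same-gene pairs are the two bounded forms that
reduce correctly at $x \in \{0, 1\}$. The fit minimizes a ridge-penalized
(weight $10^{-3}$ on $y$ and $s$) weighted least-squares objective by
alternating conditional updates, each exactly solvable: $y$ per gene and $s$
per pair in closed form given $x$, and each $x$ by a clamped exact update.
Replicates enter as independent observations of the same $\mu_c$.
Convergence is declared when the largest absolute parameter change falls
below `tol` (default $10^{-4}$); the default fit is deterministic, and the
seed argument is provenance only.

**Identifiability.** Only products such as $x_t y_g$ are observable, so
after every sweep each gene that retains a full-activity (perfect) guide is
rescaled to put its largest guide efficacy at 1 (with $y$ and the affected
$s$ rescaled inversely). After mismatch substitution an essential gene is
represented only by its partial-activity variant; anchoring that guide at 1
would silently shrink the gene's effect and attenuate all its interactions.
Such guides are instead *pinned* to their recorded empirical (else
predicted) activity — measured values the library design consumes anyway —
and $y$ stays on the true single-knockdown scale. Initialization: $x = 1$
for perfect guides, the recorded activity (else 0.5) for mismatch guides;
$y$ from each gene's NT-partner means; $s = 0$.

**Saturation.** The pseudo-count bounds LFCs below by
$\log_2(p/(n_{T0} + p))$, about −5.7 at nominal coverage. Fitting the
pseudo-counted LFC directly therefore reads any depletion beyond the floor
as apparent positive epistasis, which concentrates exactly on the
biologically interesting strong pairs. When the LFC table carries its
normalized counts (output of `computeLfc()` always does), the fit instead
uses the de-saturated half-count-corrected log-ratio
$\log_2\!\frac{n_{T14} + 1/2}{n_{T0} + 1/2}$ with inverse-variance weights
$\left(\frac{1}{n_{T14} + 1/2} + \frac{1}{n_{T0} + 1/2}\right)^{-1}$:
near-floor observations become unbiased and appropriately uninformative
instead of biased. On simulated screens this change moves the correlation
between true and fitted interaction effects among truly interacting pairs
from roughly 0.75–0.83 to 0.89–0.95 without touching anything else.
`useCounts = FALSE` restores the plain LFC objective, which is also what
the brute-force oracle-equivalence tests exercise.

## Scores and conventions

With $T_{gh} = y_g + y_h + s_{gh}$ the model-implied full-efficacy double
knockdown, the **sensitive** deviation is $T_{gh} - \lambda (y_g + y_h)$
(equal to $s_{gh}$ at the default $\lambda = 1$) and the **strong**
deviation is $T_{gh} - \min(y_g, y_h)$, the effect beyond the stronger
single knockdown. Non-negative deviations are considered non-interacting and
clipped to 0, and scores are reported as values $\le 0$, so more negative
means stronger synthetic lethality. Pairs with sensitive score at or below
−1 are flagged synthetic lethal (cross-line comparisons use per-line
cutoffs, e.g. −1 for K562 and −0.5 for HeLa S3). Note one subtlety the
tests pin down: with two individually depleting genes the strong deviation
at $s = 0$ is $\max(y_g, y_h) < 0$, so the strong score can be negative
without any modeled interaction; the sensitive score is the synthetic-lethal
statistic.

The interaction heat map retains genes with at least one partner scoring
2 s.d. or more away from the mean non-zero sensitive score — implemented
two-sided on $|score - m|$ (with all scores $\le 0$ this picks strong
interactors; a `twoSided = FALSE` switch gives the one-sided reading) — and
clusters the symmetric score matrix (unqueried pairs at 0, the
non-interacting value) with Ward variance-minimizing agglomerative
clustering. The dendrogram is cut at a user-set `k` (default 20; the number
of clusters is not dictated by the method). Embedding uses the symmetric
strong-score matrix with no prior dimension reduction through a pluggable
embedder; the default is classical MDS because it is deterministic and
dependency-free, and any `function(matrix) -> n×2` (for instance a UMAP
implementation) can be swapped in — the backend is configuration, not
contract.

## The simulator, and what it does (not) show

`simConfig()` fixes the study conditions: 15 NT guides; 18% of genes
strongly essential with effects uniform on [−5, −3] (each carrying a top
perfect guide plus a mismatch variant, efficacy uniform on [0.3, 0.7] with
its measured activity recorded with s.d. 0.05 noise); neutral effects
N(0, 0.2); 10% of gene pairs interacting with effects uniform on [−3, −1];
perfect-guide efficacies uniform on [0.7, 1] with each gene's best guide at
exactly 1; ten doublings; 500 reads per element at T0 with lognormal
abundance skew (sdlog 0.5); Poisson counts (a negative-binomial dispersion
knob exists but defaults off — no overdispersion model is asserted by the
screen design); per-base sequencing error 0.001; two replicates. Truth
phenotypes are parameterized directly on the 14-day LFC scale
(`2^(phi × doublings/10)` growth), so fitted and true parameters compare
directly. T14 samples are renormalized to the common mean depth, as a
sequencer fixes total reads — this is what makes the NT-anchored size
factors do real work. FASTQ filler sequence is rejection-sampled so no
scanned window accidentally equals a library protospacer.

Passing recovery tests on these simulations shows the estimator inverts its
own generative assumptions at realistic depth and noise; it does not show
robustness to what the generator omits: guide-specific off-target effects,
replicate batch structure, overdispersion beyond Poisson, copy-number
artifacts, or time-dependent fitness. Those require real screens.

Default problem sizes in the tests (60 genes × 2 guides for recovery, 20
genes at depth 200 for the counting round-trip, 3 seeds each) keep the whole
suite under a minute while leaving every rate estimate far from its decision
boundary.

## Worked example

```{r example, eval = FALSE}
cfg <- simConfig(nGenes = 20, seed = 7)
truth <- simulateTruth(cfg)
counts <- simulateScreenCounts(truth)
res <- analyzeScreen(counts, truth@library)
recoveryReport(res$fit, res$scores, truth)
hits <- callSyntheticLethal(res$scores)
net <- buildNetwork(hits, cancerGenes = "G0003", drugTargets = "G0011")
```

## Numerical choices and limitations

* Ties in guide ranking and variant selection break lexicographically on
  guide id; orientation draws use a seeded RNG over sorted gene pairs —
  designs are byte-reproducible across platforms.
* The mismatch activity window 0.47 ± 0.15 is the closed interval
  [0.32, 0.62]; boundaries are admissible.
* Essential calling uses a strict inequality (a mean NT-partner LFC of
  exactly −3.0 is not essential); synthetic-lethal calling is inclusive
  (−1.0 is a hit). Both follow the stated conventions.
* Elements with zero T14 counts are retained (the pseudo-count bounds the
  LFC); only the T0 filter removes elements.
* One gene effect is fitted per gene symbol; multi-TSS genes are not split
  into TSS-level effects.
* The fit is a point estimate; posterior uncertainty on scores is out of
  scope, as are multi-condition (drug-modifier) designs and fuzzy read
  matching beyond exact 20-mers.
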