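---
title: "Methods: statistics and simulation design in scMesenchyme"
author: "scMesenchyme authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistics and simulation design in scMesenchyme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the statistical
model behind each stage, the defaults and why they are what they are, what
the synthetic-data generator does and does not emulate, and the design
choices made where the problem was genuinely open.

# The analysis problem

Smart-seq2 single-cell RNA-seq of the mouse lung mesenchyme across
perinatal development (E18.5, P1, P7, P21) and under postnatal hyperoxia
(80% O~2~ to P7, the standard bronchopulmonary dysplasia model). The
questions the pipeline answers are: which mesenchymal subtypes are
present and when; which genes distinguish them; whether hyperoxia arrests
the compositional and transcriptional maturation of the mesenchyme; how
pericyte signaling changes; and whether new cell states emerge.

# Quality control and normalization

Cells with fewer than 50,000 total counts or fewer than 400 detected
genes are discarded; both cut-offs are strict "less than", so boundary
cells are retained. Smart-seq2 libraries are deep (~10^6^ reads/cell), so
the count total is a reasonable proxy for uniquely mapped reads, which is
what the thresholds nominally refer to. Surviving cells are scaled to
counts per million (CPM). Zero-total cells are legal before QC and
illegal after: `cpmNormalize()` refuses them and points at
`filterCells()`.

# Feature selection

For each mouse separately, every gene gets a Fano factor
$F_g = \operatorname{Var}(x_g)/\operatorname{E}(x_g)$ on CPM values
(genes with zero mean score 0, so constant and absent genes never
qualify). A gene is "high" in a mouse when it ranks in that mouse's top
`nFeatures` (default 500); genes high in at least `majorityFraction`
(default 0.5) of mice are kept, ordered by the number of supporting mice,
then median Fano factor, then gene symbol. "High in most mice" is not
defined more precisely by convention, so both knobs are exposed; the
per-mouse-rank + majority-vote reading makes the selection robust to a
single outlier animal and invariant to cell order and mouse relabeling.
Fano factors are computed after CPM normalization, matching the stated
order of operations (normalize, then select); computing them on raw
counts changes the ranking only through per-cell depth, which CPM
removes.

# Embedding

The feature-restricted CPM matrix is transformed as
$\log_{10}(\mathrm{cpm} + 0.1)$ and projected onto the top 25 principal
components (cells as samples, gene-centered, no unit-variance scaling —
no scaling is the conservative reading when none is stated, and it keeps
strongly expressed markers influential). Log base 10 is a presentational
choice: any fixed base rescales all inputs uniformly and leaves the
principal subspace, and hence clustering, unchanged. Each component's
sign is fixed so that its largest-magnitude loading is positive, making
the embedding fully deterministic; t-SNE (seeded) is provided for
visualization only and is never used for statistics.

# Clustering, doublets and annotation

Leiden community detection runs on the exact k-nearest-neighbor graph
(Euclidean distance in PC space, k = 15, symmetrized, modularity
objective). The default resolution is 1.5, chosen on held-out simulations
(seed 99, separate from any test seed): the marker rules label whole
clusters, so mild over-clustering is harmless — two clusters of the same
subtype simply both receive its name — while under-clustering merges
distinct subtypes irrecoverably. Labels are renumbered by decreasing
cluster size.

Doublets are flagged as (a) members of clusters smaller than 10 cells, or
(b) cells expressing (CPM > 100) at least one gene from each side of an
incompatible marker pair. The shipped pair list combines the three broad
group markers (*Adh1*, *Tgfbi*, *Pdgfrb*), the *Acta1* panel against all
three, and within-group discriminators (e.g. *Wnt2* vs *Col14a1*,
*Cox4i2* vs *Tagln*, *Mki67* against non-proliferating markers). Pairs
that a genuine subtype coexpresses (e.g. *Hhip*+*Pdgfra* in ASM/MyoF
precursors, *Col13a1*+*Col14a1* in embryonic fibroblast precursors) are
deliberately excluded; doublets between transcriptionally adjacent states
are therefore invisible to the rule, which bounds recall below 1 by
construction.

Cluster annotation is rule-based: per cluster, a gene is *positive* when
its mean CPM exceeds 50 **and** more than 25% of the cluster's cells
express it above 50 CPM. The per-cell floor matters at Smart-seq2 depth,
where almost every gene has at least one read in most cells: with a
floor of zero the expressing fraction carries no information, and a few
contaminating cells can drag an off-gene's cluster mean over the
threshold and veto a correct rule through its negative requirements. The
first rule (in table order, most-specific first) whose positive genes are
all positive and negative genes all non-positive names the cluster.
Clusters matching no rule but positive for *Acta1* become `HA-novel-k`;
anything else is `unassigned` — novelty is reported, never forced into a
known label. A cluster is *proliferating* iff *Mki67* is positive.

# KS differential expression

For two disjoint cell sets the per-gene statistic is the classical
two-sample Kolmogorov–Smirnov distance
$D = \sup_x |\hat F_A(x) - \hat F_B(x)|$ on CPM values, computed with
proper tie handling (ECDF difference evaluated at the last index of each
tied run). A signed version $\pm D$ (sign of the mean difference, A minus
B) supports directional displays. P-values use the exact ties-aware
two-sample Smirnov distribution when both groups have ≤ 25 cells and the
asymptotic Kolmogorov tail with effective sample size $n_1 n_2/(n_1+n_2)$
otherwise; Bonferroni multiplies by the number of genes actually tested.
The average fold change is $\log_2[(\bar x_A + 0.1)/(\bar x_B + 0.1)]$,
with the pseudocount mirroring the embedding's. Gene selection follows
the two published modes: largest |KS|, or genes above a KS floor
(default 0.3) ordered by |fold change|.

The transcription-factor quadrant fingerprint scores each factor by
signed KS against two references; the quadrant of
(`enrich_x`, `enrich_y`) classifies it as specific to the focal type
(+,+), specifically absent (−,−), or one-sided. The axis statistic is
this package's choice — the original display does not name its
enrichment measure — and signed KS keeps the axes on the same
nonparametric scale as the rest of the workflow.

# Developmental-arrest statistics

**Compositional bootstrap.** Subtype composition vectors are built from
non-doublet cells of each (timepoint, condition) stratum. Per replicate,
$n$ cells (the smallest of the three stratum sizes, so each stratum is
equally represented — the "balanced" resampling) are drawn with
replacement independently from the focal stratum (hyperoxia P7) and the
two references (normoxia P1, normoxia P7), and the replicate records
$d(\text{focal}, \text{P7}) - d(\text{focal}, \text{P1})$ with $d$ the
total variation distance ($\tfrac12 L_1$; Euclidean available behind the
`distance` flag, and the distance used is recorded in the result). The
empirical P is the fraction of replicates ≤ 0, i.e. favoring P7; ties
count against the arrest hypothesis, the conservative direction. Each
stratum's resampling stream is seeded from the stratum identity rather
than its role, so exchanging the two references exactly negates every
replicate difference. Fine subtypes (not broad groups) form the
composition vector by default, with proliferating states kept separate;
a custom `subtypes` universe can merge them.

**Progression arrest.** Within one cell type, progression genes are
those with signed KS > 0 and KS ≥ 0.3 comparing normoxia P7 to normoxia
P1. For each, the hyperoxia effect is the signed KS of hyperoxia P7
versus normoxia P7, and the arrest fraction is the share of progression
genes with a negative effect. Two caveats are inherent to the
definition: at small per-stratum cell numbers the KS ≥ 0.3 detection
admits noise genes, diluting the arrest fraction toward 0.5; and under a
true null (progression preserved) the arrest fraction is a symmetric
sign statistic with expectation 0.5, so single-dataset values near 0.5
mean "no evidence of arrest", not a precise quantity.

# Ligand–receptor analysis

A pair is detected between a source and a target population (within one
stratum) when at least 20% — inclusive — of source cells express the
ligand and at least 20% of target cells express the receptor.
"Expressing" defaults to CPM > 0, meaningful at Smart-seq2 depth; a
nonzero floor is exposed (`exprFloor`). Genes absent from the matrix
count as 0% expressing, so user-supplied pair tables need not be
filtered to the measured gene space. The interaction strength is
$(\bar L \cdot p_\text{src}) \times (\bar R \cdot p_\text{tgt})$ — mean
ligand CPM times source abundance, times the receptor-side product —
with abundances over non-doublet stratum cells. The published wording
("product of cell type abundance and gene expression levels") does not
fix the factorization; the symmetric form is the default and the
source-side-only variant sits behind `abundanceMode = "source"`. The
20% rule is applied within each stratum, not globally. The shipped pair
table (`inst/extdata/lr_pairs_synthetic.tsv`) is a synthetic fixture in
the documented schema; export pairs from any ligand–receptor resource to
use a real database.

# Atlas co-embedding and ellipse reannotation

`harmonizeEmbed()` intersects the gene spaces, selects features on the
combined data (mice nested within source), runs joint PCA, and then
averages each cell's coordinates with its k nearest neighbors taken
separately from each source — a batch-balanced smoothing that pulls
matching states together without reproducing any specific published
integration tool; the contract, enforced by test, is that same-subtype
cells from the two sources co-locate. `ellipseReannotate()` fits the
mean and covariance of a focal population in the top components (2 by
default) and returns other-source cells within Mahalanobis radius
$e \cdot \sqrt{\chi^2_{0.95}(d)}$ — a rigidly expanded confidence
ellipse. The expansion (1.5) and coverage (0.95) are free defaults;
membership is monotone in the expansion, so the choice trades recall
against specificity transparently.

# The synthetic-data generator

`simulateCounts()` draws, per stratum, subtype labels from the stratum's
composition vector, a per-cell depth from a log-normal law (mean 5×10^5^,
sd 1.2×10^5^ counts), and gene counts from a negative binomial with
shape 2 around the subtype's expected profile. The default spec
(`defaultLungSpec()`) encodes the study conditions:

- **14 subtypes** whose marker logic matches the annotation rules
  (groups *Adh1*/*Tgfbi*/*Pdgfrb*; *Col13a1*/*Col14a1* fibroblast split
  with embryonic precursors coexpressing both; *Hhip*/*Pdgfra* ASM/MyoF
  split with a coexpressing precursor; *Mki67* proliferating variants;
  *Cox4i2* pericytes and *Tagln*/*Acta2* VSM), plus two *Acta1*+
  populations (HA1: *Tubb3*/*Actc1*; HA2: *Lgals3*/*Aqp3*) restricted to
  the hyperoxia arm. Early postnatal fibroblast states carry *Mest* as
  an early marker. Subtype identities beyond the rule-bearing markers,
  and all composition values, are this package's choices: the source
  reports compositions only graphically.
- **Composition over time** moves from precursor-dominated (E18.5)
  through an ASM/MyoF and proliferation peak (P7) to a fibroblast/mural
  adult-like profile (P21). The hyperoxia-P7 composition equals the P1
  composition on the 14 normal subtypes (rescaled by the 8% HA mass) —
  compositional arrest is built in by construction, which is what gives
  the bootstrap test a known ground truth.
- **Markers are near-binary**: a marker's baseline weight is multiplied
  by 8 in subtypes that carry it and by 0.005 in subtypes that do not,
  reproducing the on/off structure of the reference dot plots. Without
  the off factor, a 2,000-gene universe at 5×10^5^ depth puts every gene
  above any CPM threshold in every cell and the doublet-coexpression
  rule could not work even in principle.
- **Gene baseline weights are a property of the gene universe** (drawn
  from a stream seeded by the gene list itself): two datasets simulated
  from the same spec with different seeds share their biology and differ
  by a mild per-gene batch perturbation (log-normal, sdlog 0.15) plus
  sampling noise, the way replicate experiments do. Named genes
  (markers, progression panels, ligands) draw solid baseline weights
  (log-normal around 2); filler genes keep a long-tailed law.
- **Progression genes** (12 per progressing subtype: alveolar
  fibroblasts, early ASM, myofibroblasts, pericytes) triple their mean
  at P7/P21 in normoxia. By default hyperoxia blocks the progression;
  `progressionInHyperoxia = TRUE` is the no-arrest control.
- **Artifacts**: doublets (5%) are the sum of the cell's own draw and an
  independent draw from a random same-stratum profile — exactly the
  coexpression signature the QC rule targets; low-quality cells (5%)
  draw uniform depths of 10,000–35,000 counts, safely below the 50,000
  threshold.

What the generator does **not** emulate: gene–gene correlation beyond
subtype structure, empirical library-size distributions, ambient RNA,
batch effects beyond the mouse label and the per-dataset perturbation,
or any continuous differentiation trajectory. Tests passing on this
generator therefore demonstrate that the statistics recover structure of
the kind the model assumes — not that the pipeline is robust to every
artifact of real data.

# Problem sizes and determinism

The shipped tests run the full chain at five strata × 600 cells × 2,000
genes (the package's study-scale working size) and smaller sizes for
unit oracles; the bootstrap uses B = 1000 (power) and B = 500 over 20
seeds (null calibration); the type-I check uses 20 replicates of 200
genes × 50 cells per group. All stochastic steps take explicit seeds,
RNG state is restored after every seeded call, and the pipeline's
`summary.json` is byte-identical across re-runs of one configuration.

# Known limitations

- Marker rules act on whole clusters: a cluster merging two subtypes
  gets a single label, so annotation quality is bounded by clustering
  granularity (hence the over-clustering default).
- Doublet recall is structurally below 1 (adjacent-state doublets).
- KS-based progression detection is permissive at small n; arrest
  fractions from few cells should be read qualitatively.
- The asymptotic KS p-value ignores ties (conservative for discrete
  data); the exact branch handles them.
- No pathway enrichment, trajectory inference, imputation or ambient-RNA
  correction is provided; these are outside the package's scope.
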