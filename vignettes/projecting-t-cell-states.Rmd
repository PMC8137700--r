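---
title: "Projecting T cell states onto a frozen reference atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting T cell states onto a frozen reference atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

T cell scRNA-seq studies describe recurring transcriptional states —
naive-like, effector-memory (EM), precursor-exhausted (Tpex), terminally
exhausted (Tex), regulatory (Treg), follicular helper (Tfh), and so on —
but every study re-derives its own clusters, so states cannot be compared
across experiments, cohorts, or species. `tcellproj` takes the
reference-atlas view: integrate many datasets once into a curated map of
subtypes, freeze that map's coordinate systems, and interpret every new
experiment by *projection* into the frozen map. Because a projection never
modifies the reference, conditions profiled years apart remain directly
comparable.

The atlas consists of: an integrated (batch-corrected) expression matrix on
a consensus variable-gene space; per-gene centering and scaling vectors; a
PCA rotation matrix (default 50 components); a stored UMAP transform
fitted on the PCA embedding; an independent-component rotation (default 50
components, each a gene-loading axis read as a gene program); and one
subtype label per reference cell. Projection is, at its core, linear
algebra with frozen matrices: a corrected query matrix is centered and
scaled with the *atlas's* vectors and multiplied by the stored rotations,
and the stored UMAP transform turns PCA coordinates into map coordinates.

## Normalization and quality filters

Counts are normalized as `ln(1 + s·x/S)` with scale factor `s = 10000`,
which makes every kept cell satisfy `sum(expm1(normalized)) = s` exactly —
a convenient integrity check. Cells with zero totals are flagged at read
time and dropped (with a logged count) at normalization. Datasets that
already look log-normalized (non-integer values, or an existing normalized
layer) are passed through with a warning rather than normalized twice.

The T cell purity filter scores each cell as the mean normalized
expression over a marker panel (*Cd2, Cd3d, Cd3e, Cd3g, Cd4, Cd8a, Cd8b1*)
minus the mean over a non-T lineage panel (*Spi1, Fcer1g, Csf1r, Cd19*).
Cells score `T` when the difference exceeds `tau = 0` with at least one
marker detected, `Non-T` when the lineage panel dominates, `unknown`
otherwise; only `T` cells are kept, the per-class counts are reported so
removals can be audited, and the filter can be disabled. This marker-score
rule is deliberately simple and transparent; it is not a trained
classifier, and borderline `unknown` cells are discarded rather than
guessed.

Human data are mapped into mouse gene space before projection: genes
without an ortholog are dropped, one-to-many mappings prefer the pair
whose upper-cased mouse symbol equals the human symbol (then lexicographic
order), and many-to-one mappings sum their counts. The packaged ortholog
table (`orthologs_synthetic_subset.tsv`) is a small hand-assembled
demonstration subset — real analyses should supply a full table, e.g. an
Ensembl BioMart download, via `read_ortholog_table()`.

## Variable genes and integration

Per dataset, genes are ranked by standardized variance: a loess trend
(span 0.3, degree 2) of log variance on log mean predicts each gene's
expected standard deviation; counts standardized with it (clipped at
`sqrt(n)`) give a variance that is comparable across expression levels.
Cycling genes (packaged editable list), mitochondrial (`mt-`), ribosomal
(`Rps/Rpl`), predicted/non-coding symbols, and genes detected in <0.1% or
>90% of cells are excluded, and the top 600 per dataset are kept. The
consensus (default 800 genes) ranks genes by how many datasets selected
them, breaking ties towards genes from the largest datasets, then by best
within-list rank, then alphabetically — so the consensus is deterministic.

Integration connects batches with anchors: mutual nearest neighbors in
reciprocal-PCA space (fit on one batch, project the other, 30 components,
and vice versa). Three geometric choices matter and were made after
explicit failure analysis:

* Both matrices are centered with the *fit* batch's gene means. Centering
  a query with its own means slides a composition-skewed query (say, 90%
  exhausted cells — the typical tumor dataset) onto the reference
  centroid, anchoring it to the wrong populations.
* Each cell is additionally centered over genes, so a batch offset that is
  constant across genes cancels exactly instead of inflating every
  cross-batch distance. The gene-specific remainder of a batch effect is
  precisely what the anchor correction removes.
* A cell whose nearest cross-batch neighbor is much closer than its second
  (distance ratio < 0.4) keeps only that dominant match. For a query that
  contains near-duplicates of reference cells this collapses the anchor
  set to the duplicate pairs, whose expression differences are zero — so
  re-aligning the atlas's own cells applies exactly no correction.

Anchors are scored in [0, 1] as the product of two terms. *Consistency*:
the fraction of each anchor cell's 30 within-batch neighbors whose own
cross-batch partners fall inside the partner cell's neighborhood, averaged
over both sides and spread between its 1st and 90th percentiles (identical
batches, where every anchor is fully consistent, map to 1).
*Proximity*: `1/(1 + 5·max(0, D − 0.9))`, where `D` is the pair's
cross-batch distance over the larger of the two cells' median within-batch
neighbor distances. Consistency rejects haphazard matches; proximity
rejects coherent-but-distant matches between batches that share no
population, whose few mutual neighbors otherwise agree among themselves.
Anchors are filtered at 0.8 (an absolute cutoff by default; a percentile
mode is provided because both conventions are in circulation).

Batches are merged starting from the largest, adding the batch with the
most surviving anchors to the merged set; each incoming cell receives a
correction vector equal to the Gaussian-kernel-weighted average of its 100
nearest anchors' (reference − query) expression differences. A final
refinement pass re-corrects every batch's raw values with fresh anchors
against the integrated values of the other batches. This makes each
reference cell's integrated value a fixed point of the *same* operator
that later aligns queries to the finished atlas — without it, a reference
cell re-projected as a query lands where an intermediate merge left it,
several PCA units away from its stored position.

## Frozen spaces

PCA uses exact SVD on the centered (and by default unit-scaled) integrated
matrix. The UMAP (n_neighbors = 10, min_dist = 0.05, fixed seed) is stored
as a reusable transform. Two transform choices are deliberate: new points
are placed at the membership-weighted mean of their reference neighbors'
coordinates with zero optimization epochs, which is deterministic; and the
output is blended towards the nearest reference cell's stored coordinates
in proportion to proximity (weight 1 at distance zero, 0 beyond one local
PCA radius). The blend exists because the weighted-mean placement shrinks
points towards local centers — re-embedding the atlas's own cells at
default uwot settings left only ~40–60% within half a UMAP unit of their
stored coordinates; with tight neighborhoods and the blend, a cell
identical to a reference cell lands exactly on it, and genuinely novel
cells get the plain transform output.

ICA is fixed-point ICA (deflation, fixed seed) on the centered/scaled
matrix; the stored rotation is the exact linear map from gene space to
component space (the whitening pseudo-inverse), and components are
sign-normalized so each component's largest-magnitude loading is positive.
Components can be annotated against gene-set collections by the absolute
sum of loadings over each signature's genes, keeping the top three
signatures per component.

Cluster structure for annotation comes from shared-nearest-neighbor
clustering: a kNN graph (k = 20) on the chosen embedding, Jaccard edge
weights pruned below 1/15, Louvain modularity at a given resolution with a
fixed seed, ids renumbered by decreasing size. Resolution directly
controls granularity — around 0.1 recovers only well-separated lobes,
0.4–0.6 (the presets used for the tumor and viral atlases) subdivides them
into states. Labels themselves are always user-supplied after inspection;
the package does not auto-name biology.

## Projection and classification

Queries are aligned with anchors found against the atlas's integrated
matrix on the intersection of atlas variable genes with query genes (an
error below 100 shared genes suggests the wrong species; atlas genes
missing from the query are zero-filled, with a warning above 25% missing
since zero-filling biases the rotation). If no anchor survives filtering,
projection falls back to direct mode — frozen rotations without
correction — with a prominent warning; direct mode can also be requested,
and is the right tool for very small queries. Classification is a k = 20
majority vote in PCA space by default (UMAP space is available), with
ties broken towards the smaller mean neighbor distance and then the atlas
subtype order, and an optional confidence floor that relabels uncertain
cells `unassigned`.

Discriminant dimensions compare the query's and a baseline's coordinate
distributions per ICA component (two-sample Kolmogorov–Smirnov by
default, Welch t as an alternative), multiplying p values by the total
number of components — 50 — even when a subtype subset is analyzed, and
ranking by the statistic. Discriminant genes use per-gene Wilcoxon
rank-sum tests with Benjamini–Hochberg adjustment on the original
(pre-correction) normalized expression, reporting natural-log fold
changes of expm1-backtransformed means with pseudocount 1 (positive =
higher in the first condition), filtered at |logFC| > 0.25 and ≥10%
detection. These are deliberately generic tests: the statistical machinery
is standard, and the contribution is the frozen space in which the
comparison happens.

## The synthetic generator and what passing tests mean

`simulation_config()` defines the study conditions every packaged check
runs under: 6 datasets × 300 cells × 1200 genes, 5 subtypes with 40
marker genes each shifted by 1 natural-log unit, gene-wise Gaussian batch
offsets (sd 0.3), log-normal library sizes around 2500 counts,
negative-binomial dispersion 0.5, two datasets each missing one subtype
(the limited-overlap structure that makes multi-study T cell integration
hard), two samples per dataset except a single-sample final dataset, and
a mandatory seed. These sizes keep an atlas build around half a minute on
one core while leaving every stage non-trivial.

The generator exercises normalization, dispersion-based gene selection,
anchor correction, and label transfer, but it is not a biological claim:
marker blocks are disjoint, batch effects are additive in log space,
there is no doublet structure, no ambient RNA, no continuous
differentiation gradient, and subtypes are equally abundant within a
dataset. Passing tests therefore demonstrate that the machinery recovers
planted structure under realistic noise — not that any particular
biological dataset will project with the same accuracy.

The cross-validated benchmark removes half the samples of one dataset per
fold (all of them for a single-sample dataset), projects the removed
cells back, and reports the fraction within 1 UMAP unit and 5 PCA units
of their original positions plus label accuracy, pooled cell-weighted. By
default the reduced reference keeps the frozen spaces and merely loses
the held-out cells — that is how a frozen reference is actually used, and
radii are then directly meaningful. A full-rebuild mode (with Procrustes
alignment of the rebuilt spaces on shared cells) exists for diagnostics;
its radius metrics are dominated by how much the rebuilt embedding itself
moved rather than by projection error, which is why it is not the
default.

## Numerical choices and degenerate inputs

Fixed seeds are threaded through every stochastic step (UMAP fit, ICA
initialization, Louvain, control-gene draws, down-sampling), so an atlas
build is reproducible bit for bit. Genes with near-zero variance scale by
1 instead of exploding; all-zero query profiles embed to the finite image
of the origin; an all-zero gene row in a marker profile rescales to zeros
rather than NaN; a subtype absent from the control side of a fold change
is flagged `+Inf` rather than erroring; clonotype down-sampling sorts by
cell id before the seeded draw so input order cannot change the result.
Bundles saved by `save_atlas()` carry a version tag (checked on load) and
a probe set whose UMAP transform must reproduce stored coordinates within
1e-6, guarding against a UMAP model that silently fails to round-trip.

## Known limitations

Anchor correction assumes the query's populations exist in the reference;
a genuinely novel state will be dragged towards its nearest reference
region, and only the discriminant-dimension machinery (not the UMAP
position) will reveal the deviation. Zero-filling many missing genes
biases projections towards the origin of the missing dimensions. The
marker-score T cell filter is a heuristic, not a classifier. The packaged
ortholog table is a demonstration subset. And all packaged accuracy
numbers are properties of the synthetic study conditions described above;
real atlases should be validated with their own held-out data, for which
`crossvalidate_projection()` is provided.
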