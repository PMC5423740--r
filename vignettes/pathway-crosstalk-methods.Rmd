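---
title: "Dysregulated pathway discovery via a pathway interaction network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dysregulated pathway discovery via a pathway interaction network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Single-pathway enrichment treats pathways as independent, but disease
processes typically dysregulate *groups* of functionally coupled pathways.
`pinsel` implements a crosstalk-aware pipeline for two-group (disease vs
control) expression studies that identifies a small set of pathways whose
joint activity discriminates the groups. The pipeline has four stages.

**1. Standardization and filtering.** Expression is standardized per gene
over all samples, $z_{mn} = (g_{mn} - \bar g_m)/s_m$, with the $n-1$
(sample) SD; both groups are pooled because the reference distribution for
a gene is its behaviour across the whole cohort. Zero-variance genes are
dropped (they carry no information and break the division). Pathways keep
only measured genes and must retain at least 5 of them ("informative"
pathways) — small sets give unstable principal components and little
biological resolution. The size filter is applied *after* restriction to
measured genes, because an unmeasured member cannot contribute to the
activity score. Pathway IDs are then assigned once, as the 0-based
alphabetical rank of the surviving names, and never reassigned. PPI edges
must have confidence strictly greater than 0.2 (unit scale; STRING-style
0–1000 scores are divided by 1000) and both endpoints measured.

**2. Pathway activity and the seed.** The activity of pathway $k$ in
sample $n$ is the sample's coordinate on the first principal component of
the samples × member-genes standardized submatrix (column-centered, no
re-scaling beyond the global standardization — the genes already have unit
SD). We compute it by SVD. A PC's sign is arbitrary, so we fix it
deterministically: member genes are processed in byte-wise alphabetical
order and the loading coefficient with the largest absolute value is made
positive (first gene wins ties). This makes results reproducible and
invariant to the order genes appear in a GMT file; every downstream
quantity (|t|, AUC) is itself sign-invariant. The *seed pathway* is the one
with the largest absolute pooled-variance two-sample t statistic of its
activity between groups (Welch is available behind a flag). Ties break
toward the smaller ID.

**3. The pathway interaction network (PIN).** Genes are tested for
differential expression with a two-sided pooled t test at raw p < 0.05 —
deliberately uncorrected, as is common in screening steps; a
Benjamini–Hochberg flag exists for users who want FDR control. For every
PPI edge we compute the Pearson correlation of the two genes within the
disease samples and within the control samples separately. Two pathways
are connected if (a) they share at least one differentially expressed
gene, or (b) some PPI pair crossing them has
$\max(|r_{disease}|, |r_{control}|) > 0.8$. The edge weight is the sum of
$|r|$ over all PPI pairs crossing the two pathways, each unordered PPI
edge counted once even when both endpoints belong to both pathways.
Finally only the top 5% of edges by weight are kept
(`floor(0.05 * n_edges)`, ties at the cut broken toward the
lexicographically smallest ID pair); on a network of 239,216 pathway
interactions this keeps exactly 11,960.

Which condition's correlation feeds the weight sum is genuinely open. The
default here is `max_abs` — the larger of the two conditions' absolute
correlations, the same quantity used by criterion (b). The seemingly
natural alternative, disease-condition correlations only, has a defect we
found during development: disease-specific expression variance — the very
dysregulation the method is hunting — *deflates* disease-condition
correlations of affected genes, so the top-5% cut preferentially discards
the edges of dysregulated clusters. `disease`, `control` and `all_samples`
remain available as switches. The per-edge difference of the two
conditions' |r| is exported as a diagnostic column and drives no decision.

**4. Greedy selection by cross-validated SVM AUC.** Starting from the
seed, candidates are the pathways adjacent in the reduced PIN to any
already-selected pathway (the frontier grows with the set, matching the
expectation that dysregulated pathways form a connected cluster). Each
candidate set's activity features are scored by a linear SVM (C = 1,
features standardized inside each training fold) under stratified 5-fold
cross-validation repeated (default 100 times); with 8 controls a fold
holds only 1–2 controls, so per-fold AUC is noisy and we instead pool each
repeat's out-of-fold decision values into a single AUC, then average over
repeats. Fold splits depend only on the labels and the seed, never on the
features, so all candidates at a step are compared under identical splits
(common random numbers). The best candidate is added if it improves the
mean AUC by more than `min_improvement` (default 1e-6, i.e. strict
improvement), ties toward the smaller ID; the trace is therefore strictly
increasing and the procedure terminates. PCA loadings and the seed are fit
on all samples — seed selection precedes cross-validation, as wrapper
methods of this kind typically do — so the reported AUC is an internal
selection criterion, not an unbiased estimate of generalization error.

## The synthetic study generator

All tests and the acceptance analysis run on synthetic studies, because
the original microarray/PPI/pathway releases are external. The generator
emulates the study conditions: 15 disease vs 8 control samples, a pathway
collection with overlapping membership, a scored PPI network whose edges
preferentially connect co-pathway genes, and a planted cluster of
dysregulated pathways. Defaults: 1000 genes, 50 pathways of 10–20 genes,
adjacent pathways sharing 20% of their genes, 5 planted pathways, effect
size 2 SD on 50% of each planted pathway's genes, co-expression 0.8, PPI
probabilities 0.25 (within-pathway pair) and 0.015 (background pair),
confidences uniform on [0.15, 1] so the 0.2 filter bites.

Design choices worth recording:

* **Module-level co-expression.** Each gene is attributed to the first
  pathway containing it, and genes of a module are blended with a shared
  latent factor: $x = \sqrt{1-\rho}\,\varepsilon + \sqrt{\rho}\,f$. This
  keeps marginals standard normal, gives co-module pairs — and hence the
  PPI partners the network preferentially connects — correlation
  $\approx \rho$, and, crucially, gives *different* pathways independent
  activity noise. Tying factors to PPI connected components instead
  collapses to a single global factor (chained pathway overlaps plus any
  background PPI density merge all components), which makes every
  pathway's activity share one noise axis and the whole analysis
  degenerate.

* **Patient-level severity.** Affected genes in planted pathway $k$ are
  shifted by $\text{effect} \times s_{nk}$ in disease sample $n$, with
  $s_{nk} \sim N(1, 0.8^2)$ per patient and pathway. A constant shift
  makes 23-sample cross-validated AUC saturate at exactly 1.0 after one
  or two features — unlike real small cohorts, where studies of this
  design typically report AUCs in the 0.8–0.9 range even with dozens of
  pathway features. Severity heterogeneity
  is both biologically expected (patients differ in which pathways are
  dysregulated and how strongly) and what keeps classification difficulty
  realistic. The expected shift stays at `effect_size`.

* **A dense planted block.** The planted pathways are a consecutive block
  in ID order generated with elevated membership overlap (0.45 vs 0.2
  baseline). Curated collections are full of nested and sibling sets
  sharing many genes, and a crosstalk method can only see a dysregulated
  *cluster* if its members are actually interlinked; the elevated overlap
  realizes that premise and makes the block's position recoverable from
  the network structure the method actually uses.

What the generator does *not* emulate: microarray probe effects, batch
structure, non-Gaussian noise, MAS5/RMA artefacts, realistic PPI topology
(degree distributions, hubs) or the nested hierarchy of real pathway
databases. Passing tests therefore demonstrate correctness of the
computations and recoverability of a planted Gaussian signal, not
performance on real data.

## Numerical and degenerate-input conventions

* Alphabetical orderings (pathway IDs, canonical PPI pairs, tie-breaks)
  use byte-wise (`radix`) comparisons, so results do not depend on the
  locale.
* A zero-variance endpoint makes a correlation undefined; it is set to 0
  with a warning and counted.
* A gene with identical values in both groups gets t = 0, p = 1; a
  nonzero mean difference with zero pooled variance gets t = Inf.
* Single-gene pathways are permitted when `min_genes` is relaxed to 1;
  the activity is then the centered z-score itself with loading (1).
* A seed without edges in the reduced PIN returns a singleton selection
  with a warning rather than failing.
* All randomness (generator, fold splits) flows from explicit integer
  seeds through a save/restore wrapper, so package calls never perturb the
  caller's RNG stream and identical seeds give byte-identical outputs.

## Known limitations

* With 23 samples the CV AUC of even a single informative pathway
  activity is high (≈0.9 under the default planted conditions — the
  separability depends only on effect × affected-fraction / √ρ and the
  PCA tilt, not on pathway size), so the strictly-improving greedy rule
  typically stops after one to three additions. Recovering a planted
  cluster *in full* would require either weaker per-pathway signal than
  the default scenario pins down, more samples, or a stopping rule that
  tolerates transient dips; we keep the strict rule and report what it
  does. The seed pathway itself is recovered from the planted cluster
  essentially always, and the selected set classifies at mean AUC well
  above 0.85.
* The reported AUC is optimistically biased (selection on the same
  samples); a `--no-leakage`-style refit of loadings inside folds is out
  of scope here.
* Problem sizes in the test-suite simulations (50 pathways, 1000 genes,
  20 CV repeats, 20 replicates) were chosen so the whole suite runs in
  well under a minute per scenario while keeping Monte-Carlo error small
  relative to the asserted margins; the analysis scripts use the full 100
  CV repeats.
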