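---
title: "Methods: bipartite Y1H network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bipartite Y1H network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(y1hnet)
```

## The data model

A yeast one-hybrid screen yields binary evidence of direct TF binding
to a cloned promoter fragment. `y1hnet` represents the result as a
bipartite network: a deduplicated set of (TF, promoter) edges plus
optional annotation tables (promoter → pathway, TF → family, gene →
enzyme step + compartment). Three conventions are enforced at
construction:

* identifiers are uppercased (AGI gene codes are case-insensitive);
* duplicate edges collapse silently with a logged count — the assay is
  presence/absence, so multiplicity carries no information;
* the TF and promoter namespaces must be disjoint (bipartiteness); an
  identifier on both sides is treated as a data error, not a self-loop.

Screened promoters that attracted no TF are kept out of the detected
counts (`n_promoters`) and reported separately (`n_promoters_hitfree`),
because downstream set statistics are defined over detected
interactions. A promoter annotated to several pathways contributes its
TFs to each pathway's TF *set* — sets, never multisets, since the
Fisher contingencies below count distinct TFs.

## Exact enrichment machinery

Every test in the package reduces to a 2×2 table
(`a` in-group successes, `b` in-group failures, `c`/`d` the out-group)
with fixed margins, evaluated exactly under the hypergeometric law. The
pmf is computed in log space (`lchoose`) so universes of 20,000+ genes
lose no precision. Choices that were genuinely open, and how they were
settled:

* **Two-sided rule.** We use the minimum-likelihood definition — sum
  the probabilities of all tables no more likely than the observed one,
  with a relative tolerance of `1 + 1e-7` on the comparison. This is
  the convention of the widely used exact-test implementations, so
  adjusted p-values can be compared across toolchains. The tests verify
  agreement with `stats::fisher.test` to ~1e-9 over hundreds of random
  tables.
* **Odds ratio.** The unconditional sample OR `ad/bc`, not the
  conditional MLE: the regional-enrichment score only needs a monotone,
  cheap, reproducible enrichment measure, and the sample OR needs no
  iterative root-finding. It is `Inf` when only `bc` vanishes and
  undefined (`NA`) when both diagonal products vanish. An optional
  Haldane `+0.5` correction exists for the OR only — never for p.
* **Adjustment.** BH and Holm are implemented explicitly (step-up
  cumulative minimum / step-down cumulative maximum on the sorted
  order) and checked against `stats::p.adjust` exactly. Pathway-pair
  sharing defaults to BH; the family × compartment scan uses Holm. The
  adjustment family is always one joint batch: all `C(P, 2)` pathway
  pairs, or all (family, step, compartment) triples with ≥ 1 annotated
  gene.

## Pathway cross-talk

For pathways A and B with distinct TF sets of sizes `n_a`, `n_b`
sharing `n_shared` TFs, the table is `a = |A∩B|`, `b = |A\B|`,
`c = |B\A|`, `d = universe − |A∪B|`, tested one-tailed (greater). The
`d` cell uses the union construction because it is the only one that
guarantees non-negative cells for arbitrary overlaps. The universe
defaults to the number of TFs *screened* (2,039 in the emulated
screen), not detected — the assayed collection is the population from
which pathway TF sets are drawn; it is configurable.

The regional-enrichment score of a partner pathway is
`p_adj / odds_ratio`, ranked ascending. Ties break by larger
`n_shared`, then lexicographic label, so ranks are total and
reproducible. A zero OR maps to `+Inf` (ranked last); an undefined OR
excludes the pair with a warning rather than silently ranking it.

## Family × enzyme step × compartment enrichment

Plant TCA-cycle enzymes have isoforms targeted to mitochondrion,
plastid, peroxisome, and cytosol, so family-level regulation is
resolved at the (enzyme step, compartment) granularity: nine canonical
steps (PDH/PDC, CSY, ACO, IDH, OGD, SCL, SDH, FUM, MDH) by four
compartments. Localization is resolved before testing: experimental
evidence overrides consensus predictions, conflicting experimental
claims are an error naming the gene, and ambiguous consensus rows are
resolved deterministically (sorted, first kept). For each (family F,
step E, compartment C): `a` counts distinct F-family TFs binding ≥ 1
(E, C) gene, with margins completed from the full assayed collection —
the standard family-membership × binding-status construction; the
choice of margins is recorded in an output attribute. Two-sided
testing is deliberate: depletion of a family is as informative as
enrichment for the organization question.

## Conditional co-expression

Each edge's TF–target Pearson correlation is computed independently in
each expression compendium (no pooling — the datasets profile different
biology and different array designs). Missingness is explicit: a gene
absent from a dataset, or flat in it, yields `NA`, which never passes
the threshold and is never imputed. An edge's conditionality class is
the exact set of datasets with `|r| ≥ 0.8`. The threshold comparison is
`≥` (boundary values pass); 0.8 is the conventional "highly
co-expressed" cutoff for such compendia and is a parameter of
`classify_conditionality`. Gene-level matrices are required — probe
collapsing and normalization (e.g. RMA) belong upstream, and exact
Venn counts on real data are known to be sensitive to the probe
annotation used there.

## DEG validation

Targets of an induced TF are compared against the genes significant in
that induction contrast, one-tailed, over the universe of genes
*tested* for differential expression (the expressed set), not the
genome — DE testing is conditioned on expression, and using the genome
would inflate `d` and overstate enrichment. Targets outside the
universe are dropped with a warning. Pathway-level enrichment
additionally reports the recovered fraction `a / |pathway ∩ universe|`;
compartment-level enrichment restricts the universe to the pathway's
genes and tests compartment membership × DE status two-sided, reporting
both raw and BH-adjusted calls.

## What the generators emulate — and what they do not

Defaults were fixed once, to the conditions of the screen the package
emulates:

| parameter | default | rationale |
|---|---|---|
| assayed TFs | 2,039 | screen's prey collection size |
| promoters | 224 distinct, 226 pathway memberships | 12 pathways with membership counts 22/3/9/18/8/64/3/7/25/6/5/56; two genes sit in two pathways |
| base binding probability | 0.06 | observed density of such screens, ≈ 27,500 edges / (2,039 × 224), giving mean promoter degree ≈ 122 |
| TF breadth | log-normal, `sdlog` 0.8, mean 1 | TFs differ in promiscuity; mean 1 keeps overall density at base |
| compendia | development/root/pollen/osmotic/salt; 79/60/20/40/40 samples | sample counts typical of the public atlases |
| compartment weights | 0.5/0.2/0.1/0.2 mito/plastid/perox/cytosol | mitochondrial isoforms dominate TCA annotation |

Planted structure enters through the single edge-probability formula
`clip(base × breadth_t × boosts)`: a pathway-pair boost multiplies a
random co-regulator fraction's probability toward both pathways; a
family bias multiplies one family's probability toward one (step,
compartment) gene group. Planted co-expression uses the exact
construction `target = ρ·z_TF + √(1−ρ²)·ε`, so the population
correlation is ρ in the chosen dataset and 0 elsewhere. Planted DEG
sets draw the target overlap from Fisher's noncentral hypergeometric
distribution conditioned on the DEG count, which is precisely the
sampling model the estimated OR is later compared against. Every
generator derives its RNG stream from `(seed, generator name)`, so
adding a generator never perturbs the others and equal seeds give
byte-identical files.

The generators do **not** emulate: promoter-side affinity
heterogeneity (real per-promoter degrees span 1–509; simulated degrees
are narrower because breadth is TF-side only), microarray probe
effects and normalization artifacts, sequence-level binding, spatially
correlated expression noise, or overlapping multi-compartment
localization. Passing recovery tests therefore demonstrates
correctness and statistical power of the *pipeline* under a clean
generative model — not that real screens satisfy that model.

## Problem sizes and numerical choices in the tests

The test battery runs exact-oracle equivalence exhaustively for tables
with N ≤ 20 and on random tables up to N = 60, where brute-force
enumeration is instant. Planted-recovery properties run at full screen
scale (simulation of a 2,039 × 224 network takes ~0.1 s): 100 seeds for
pathway-pair recovery (boost 8 on two 3-gene pathways over a
breadth-homogeneous background — planted pairwise OR ≈ 6.5 — with the
planted pair required to rank first in ≥ 90%), 100 seeds for the ×4
family bias (top Holm hit in ≥ 85%), 50 replicates of 5-compendium
screens with `ρ = 0.95`, 40 samples (≥ 90% exclusive-correct, ≤ 5%
null pass — at n = 40 a null |r| ≥ 0.8 has probability ~1e-8), and 100
DEG draws at planted OR 4 over a 5,000-gene universe with 100 targets
and 400 DEGs (median estimated OR in [3, 5.5], power ≥ 0.8 at α =
0.05). The breadth-homogeneous background in the pair-recovery test is
deliberate: log-normal breadth induces genuine positive dependence
between *all* pathway pairs (promiscuous TFs bind everywhere), which
is a real feature, not a bug — but it means a planted pair competes
against global promiscuity, so sensitivity is measured on the clean
background and the promiscuity effect is exercised separately by the
study-scale end-to-end test.

## Known limitations

* Exact Venn counts of conditional co-expression on real compendia
  depend on probe-to-gene collapsing and annotation versions; this
  package consumes gene-level matrices and makes no attempt to
  reproduce probe-level processing.
* The sample odds ratio is biased away from 1 in small tables; for
  sparse families interpret `odds_ratio` jointly with `p_adj`, or use
  the Haldane option.
* `pairwise_pathway_sharing` treats pathway annotation as fixed and
  complete; unannotated promoters are an error, not an implicit
  background.
* The generators plant structure multiplicatively on edge
  probabilities; planted "odds ratios" for pathway sharing are
  therefore induced, not specified directly, and were derived
  analytically (see above) rather than tuned.
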