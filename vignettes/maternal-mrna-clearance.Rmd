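---
title: "Classifying maternal mRNA clearance during the MZT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying maternal mRNA clearance during the MZT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mztclear)
```

# The procedure and its assumptions

During the maternal-to-zygotic transition (MZT), the transcripts an oocyte
deposits are cleared by two routes: M-decay, executed by maternally
provided machinery (BTG4/CCR4–NOT) before zygotic genome activation (ZGA),
and Z-decay, which requires zygotic transcription products and acts around
and after ZGA (the 4–8-cell stage in human, the 2-cell stage in mouse).
`mztclear` classifies these routes from stage-wise expression profiles and
diagnoses their failure in development-arrested embryos.

The classification operates on E(s) = log2(mean FPKM(s) + 1). Its
assumptions are deliberately minimal:

* FPKM values are already normalized and comparable across stages; the
  package never recomputes expression from counts.
* Replicates within a stage are exchangeable, so the arithmetic mean of
  FPKM (taken before the log transform) is an adequate stage summary.
  Averaging before the log keeps E monotone in abundance and matches how a
  single published profile per stage would be used.
* A 2-fold change between consecutive stage summaries is biologically
  meaningful; noise below that margin is not interpreted. There is no
  per-gene error model — the rules are deterministic thresholds, which
  makes every boundary case reproducible.

Genes pass the maternal gate when mean GV FPKM is strictly greater than
the threshold (default 2). The four cluster predicates (see the README
table) are provably mutually exclusive; genes matching none — most
importantly up-regulated, zygotically induced genes — are UNCLASSIFIED
rather than silently dropped, so cluster sizes always sum to the gene
universe. Inequalities are applied exactly as stated (strict where strict),
so a gene sitting exactly on a boundary classifies deterministically.

ZGA dependence is decided from a matched control/α-amanitin pair. Among
Cluster II/III genes that actually decay in controls — pseudocounted ratio
(FPKM(post) + 1)/(FPKM(zygote) + 1) < 0.5 — a gene is `dependent` when the
treated log2 drop from zygote to the post-ZGA stage falls below the
stabilization margin while the control drop reaches it, i.e. the
transcription block abolished an otherwise 2-fold decay. "Stabilized" is
not self-defining; we fix it as the same 2-fold convention used everywhere
else (margin 1 in log2), exposed as `stabilization_margin`.

# Tunable parameters

All defaults live in `classifier_config()` and are surfaced by the CLI.

| Parameter | Default | Units / meaning |
|---|---|---|
| `maternal_fpkm_threshold` | 2 | FPKM at GV; strict `>` gate for the maternal pool |
| `pseudocount` | 1 | added to mean FPKM before log2; keeps E ≥ 0 and damps low-expression ratios |
| `log_margin` | 1 | log2 units ≡ 2-fold; the single fold-change convention used by clustering, morula extension, Group A/B and fold-change labels |
| `stage_triplet` | GV, zygote, 8-cell | human convention; set to GV, zygote, 2-cell for mouse |
| `decay_ratio_threshold` | 0.5 | pseudocounted post/zygote ratio pre-selecting decaying transcripts for the ZGA comparison |
| `stabilization_margin` | 1 | log2 drop under which treated decay counts as abolished |
| `zga_post_stage` | 8-cell | post-ZGA stage of the inhibition comparison |

Two deliberately exposed ambiguities: the post-ZGA stage of the
α-amanitin comparison defaults to the 8-cell stage, because human ZGA
occurs at the 4–8-cell stage and inhibited zygotes are cultured to the
8-cell stage before profiling, but `zga_post_stage` accepts any stage
(e.g. 2-cell for mouse-convention data); and the orientation of the
pre-selection ratio is configurable (`zga_ratio_orientation`), since
sources differ on whether the decaying-transcript criterion is stated as
post/zygote < 0.5 or its reciprocal. Similarly, qPCR relative levels
default to the conventional 2^(Ct_ref − Ct_gene) — low Ct means abundant —
but the literal opposite orientation found in some write-ups is available
as `convention = "gene_minus_ref"`. The genome build of the UTR annotation
is a plain config value (`source_genome_id` semantics); the package does
not reconcile build differences between alignment and annotation.

# The synthetic-data generator

`generate_stage_matrix()` emulates the structure the classifier consumes:
a log-normal baseline of log2 FPKM ~ N(5, 1.2) at the GV stage, class-
specific deterministic fold drops (default 4×, i.e. twice the rule
margin), and multiplicative log-normal noise of sd 0.25 on the log2 scale
— the magnitude of stage-to-stage technical scatter a log-scale analysis
of single-embryo FPKM has to tolerate. Default class proportions are the
observed composition of the 7271-gene human maternal transcriptome
(Cluster I 2372 : II 2259 : III 1109 : IV 1531), with 176/1531 of Cluster
IV planted to degrade by the morula stage. Two constructions make planted
truth exactly recoverable at noise 0:

* maternal baselines are truncated at log2 FPKM ≥ 4, so every planted gene
  clears the GV gate with margin even under noise; and
* fold drops are applied on the pseudocounted scale, FPKM(next) =
  (FPKM + 1)/fold − 1, so each planted drop is exactly log2(fold) in E
  units regardless of expression level, giving every gene the same margin
  (1 log2 unit at the default fold of 4) over the 2-fold rule.

`generate_amanitin_pair()` removes the post-ZGA drop for a planted
fraction of Cluster II/III genes in the treated matrix only.
`generate_utrs()` plants Poisson-distributed CPE/PAS motifs (Z-decay
defaults: 1000-nt UTRs at 8 CPE/kb and 6 PAS/kb, twice the M-decay rates
of 500 nt, 4 and 3/kb — the direction and rough magnitude of the observed
class contrast) into uniform-ACGT backgrounds on a stride-8 start grid,
which guarantees insertions never overlap; chance background matches can
still add counts, so the truth table records the post-hoc scan as
authoritative next to the planted count. When estimating motif-rate
contrasts from scans, `motif_background_rate()` provides the closed-form
uniform-background expectation (sum of 4^-length over the motif set) to
subtract. `generate_arrested_cohort()` plants M-decay defects as an
8-fold stabilization of a 6-marker panel plus a 4-fold down-shift of
BTG4/CNOT7/CNOT6L-like machinery transcripts against level-1 controls.

What the generator does **not** emulate: gene–gene correlation, dropout
and zero inflation of single-embryo libraries, GC/length biases, batch
effects, or any real UTR sequence composition (backgrounds are i.i.d.
uniform). Passing the planted-truth tests therefore demonstrates that the
implementation applies its rules correctly and tolerates log-scale noise
of the stated magnitude — not that the thresholds are optimal for any
particular real dataset.

# Numerical choices

* **Degenerate tests.** `t.test()` refuses constant data, but identical
  groups must compare cleanly: zero-variance two-sample comparisons
  resolve to t = 0, p = 1 when means agree and t = ±Inf, p = 0 when they
  do not. Likewise, a zero-residual one-way ANOVA (noise-free simulated
  replicates) resolves to p = 0 when group means differ and p = 1 when
  they do not, instead of propagating NaN.
* **Overlap significance.** Set-overlap enrichment uses the upper-tail
  hypergeometric probability (one-sided Fisher model). A t-test on a Venn
  overlap, as figure legends sometimes state, is not a defined
  computation; the hypergeometric model is the standard replacement and is
  verified against exhaustive enumeration for all universes up to size 12.
* **Motif scanning** counts every start position (overlapping matches all
  count; a position matching several motif variants counts once per
  variant), is strand-specific, and treats N as matching nothing. Whether
  published "in-house" scans counted overlaps is generally unstated; the
  overlapping convention is the only one with a clean compositional
  semantics, and it is pinned by an exhaustive position-by-position oracle.
* **PCA sign convention:** each loading vector is flipped so its
  largest-magnitude entry is positive, making coordinates invariant to
  sample order.
* **Multiple annotated UTRs** per gene: the longest is kept and the choice
  recorded (`multi_utr` attribute); zero-length UTRs are excluded from
  comparisons and reported. One length per gene is what downstream
  class comparisons need, and the longest isoform contains every motif
  site of the shorter ones.
* **Missing values** are hard errors naming the offending cell — never
  imputed — with one opt-in exception: `Undetermined` qPCR wells may be
  ceiling-imputed at Ct 40.
* **Concordance screening** of embryo cohorts (normal practice keeps only
  the mutually consistent majority) is a greedy heuristic: repeatedly drop
  the embryo with the lowest mean correlation until the subset's mean
  pairwise r reaches `r_min` (default 0.7). It is recorded as a heuristic;
  published cohort selections rarely state their procedure.
* **Technical vs biological replicates** in qPCR: technical replicates are
  averaged on the Ct scale (geometric mean of levels), biological
  replicates on the linear scale — the convention the ΔCt method implies.

# Problem sizes

The test suite validates the cluster rules by fuzzing 10^5 random
E-triples, the motif scanner against a brute-force oracle on 10^4 random
sequences of length 0–500, hypergeometric p-values by complete enumeration
over all universes ≤ 12, planted-cluster recovery on 10,000-gene matrices
(exact at noise 0, ≥ 95% at log2-sd 0.25), and the defect caller on 200
simulated embryos (complete detection at noise 0, ≥ 90% at sd 0.25, false
positives ≤ 5%). These sizes keep the full suite under a minute on one
core while leaving sampling error far below the asserted margins.

# Known limitations

* The pipeline consumes FPKM; it performs no normalization, batch
  correction or count modeling, and inherits whatever biases the upstream
  quantification carries.
* Thresholds are global, not gene-specific; transcripts with shallow but
  reproducible decay below 2-fold are invisible by construction.
* The Z-decay defect call rests on group-level enrichment, not a per-gene
  error model, and the M-decay marker rule presumes the panel transcripts
  were detected at all (fewer than four detected markers yields
  INDETERMINATE rather than a call).
* No gene-ontology or gene-set enrichment is included; those analyses
  depend on external ontology releases and are out of scope.
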