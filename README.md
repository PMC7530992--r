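# mztclear

Analysis of maternal mRNA clearance during the maternal-to-zygotic
transition (MZT) in preimplantation embryos, from stage-wise RNA-seq
expression matrices and qPCR Ct tables.

During the MZT, maternally deposited transcripts are removed by two
pathways: **M-decay**, driven entirely by maternal factors and acting
before zygotic genome activation (ZGA), and **Z-decay**, which requires
products of zygotic transcription (ZGA occurs at the 4–8-cell stage in
human). Failures of either pathway are associated with preimplantation
developmental arrest, which makes decay classification and defect
diagnosis clinically relevant to unexplained IVF failure. `mztclear` is
aimed at computational biologists working with oocyte/embryo
transcriptomes (bulk or single-embryo Smart-seq-style FPKM) who need a
tested, reusable implementation of this analysis.

## The model

Transcripts with FPKM > 2 at the germinal-vesicle (GV) stage are taken as
the maternal pool. With E(s) = log2(mean FPKM(s) + 1), each maternal gene
is assigned to exactly one cluster by 2-fold rules on the GV → zygote →
8-cell triplet (margin m = 1 on the log2 scale):

| Cluster | Rules | Interpretation |
|---|---|---|
| I   | E(GV) > E(zyg)+m and E(zyg) ≤ E(8c)+m | degraded before fertilization; M-decay |
| II  | E(GV) ≤ E(zyg)+m, E(GV) > E(zyg)−m and E(zyg) > E(8c)+m | degraded after ZGA onset; Z-decay |
| III | E(GV) > E(zyg)+m and E(zyg) > E(8c)+m | continuously degraded |
| IV  | E(GV) ≤ E(zyg)+m, E(GV) > E(zyg)−m, E(zyg) ≤ E(8c)+m and E(zyg) > E(8c)−m | stable through the MZT |

Genes matching no rule (e.g. up-regulated) are UNCLASSIFIED; the labels
are provably mutually exclusive and always sum to the gene universe.
On top of this core the package provides:

* **Morula extension** — flags the Cluster IV subset additionally degraded
  between the 8-cell and morula stages (same 2-fold rule).
* **ZGA dependence** — compares matched control and α-amanitin-treated
  (RNA-polymerase-II-inhibited) embryos: a decaying Cluster II/III
  transcript whose zygote → 8-cell drop vanishes under the transcription
  block is called ZGA-dependent.
* **3′-UTR features** — strand-specific overlapping scans for CPE
  (`TTTTAT`/`TTTTAAT`) and PAS (`AATAAA`/`ATTAAA`) motifs, UTR length, and
  pooled-variance t-test comparisons between M- and Z-decay classes.
* **Embryo QC and defect calls** — pairwise log-scale Pearson correlation,
  PCA, pseudocounted fold-change tables, hypergeometric set-overlap
  enrichment, the k-of-n marker rule for M-decay defects (≥ 4 of 6 panel
  transcripts accumulated with one-way ANOVA significance), and the Group
  A/B partition for Z-decay failure in 8-cell-arrested embryos.
* **qPCR quantification** — relative levels 2^(Ct_ref − Ct_gene) against a
  reference gene, with t-test/ANOVA group comparisons.
* **Synthetic data** — generators for every input above with planted
  ground truth (clusters, ZGA flags, motif counts, defect labels), so the
  whole pipeline is testable without any external download.

## Worked example

```r
library(mztclear)

sim <- generate_stage_matrix(n_genes = 2000, noise_sd = 0.25, seed = 42)
cl  <- classify_decay(sim$matrix)
cl  <- classify_morula_extension(sim$matrix, cl)
summary(cl)
#>            I           II          III           IV UNCLASSIFIED NOT_MATERNAL
#>          674          605          300          419            2            0

pair <- generate_amanitin_pair(sim$truth, zga_dependent_fraction = 0.5,
                               noise_sd = 0.25, seed = 43)
cl <- zga_dependence(pair$control, pair$treated, cl)
sum(cl$zga_dependent == "dependent")   # 449 of 904 tested transcripts

ut  <- generate_utrs(cl, seed = 44)
rec <- annotate_utrs(ut$sequences, cl)
compare_classes(rec, "length")
#> length: Student's (pooled) t-test, t = -24.92, df = 1277, p = 4.839e-112
#>    class   n     mean       sem median   q2.5 q25     q75    q97.5
#>  M-decay 674 511.7878  8.101802  484.5 198.65 359  626.75 1032.875
#>  Z-decay 605 976.0298 17.467684  899.0 400.60 675 1164.00 2067.100
```

The cluster table recovers the planted class proportions (at noise 0 the
recovery is exact); the ZGA call recovers the planted 50% dependent
fraction; and the UTR comparison exposes the planted contrast — Z-decay
UTRs are longer and carry roughly twice the CPE/PAS density of M-decay
UTRs, the feature pattern expected of cytoplasmic-polyadenylation-
regulated transcripts.

A thin command-line front-end over the same functions ships in
`inst/cli/mzt.R` (subcommands `classify`, `zga`, `utr`, `qpcr`,
`simulate`, `report`), writing a provenance JSON next to every output.

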