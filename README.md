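# evsmallrna

Small non-coding RNA profiling of extracellular-vesicle (EV) sequencing
libraries, for people analyzing small RNA-seq of EV preparations harvested
from conditioned cell-culture media — a setting where most reads are
nuisance sequence, the medium itself contributes RNA background, and group
sizes are tiny.

The package implements the complete analysis as tested, reusable functions,
plus a seeded synthetic-data generator with full ground truth so the whole
pipeline can be exercised and validated without external data:

- **Hierarchical read annotation** in strict stage order — spike-ins →
  outmapped nuisance sequence (adapter, rRNA, phiX, mitochondrial,
  poly-A/C homopolymers) → mature miRNAs with isomiR tolerance → genome
  with ≤1 mismatch and class assignment (tRNA, Y RNA, snRNA, snoRNA,
  piRNA) by ≥90% interval overlap. Stage counts plus discarded reads
  partition every library exactly.
- **isomiR calling**: a read is the minimal-edit reconstruction of a
  canonical mature miRNA under bounded terminal offsets (5′ ≤ 2 nt,
  3′ ≤ 4 nt) and at most one internal substitution, categorized as
  canonical / 5′ / 3′ / both-ends / seed or non-seed substitution / mixed,
  with per-miRNA dominant-type summaries.
- **Quantification and filtering**: CPM per class table, detection at
  >1 CPM in ≥2 samples, spike-in normalization
  (`count × reference / spike_total`, reference = geometric mean of
  spike-in totals), and the two-fold media background filter on
  normalized counts.
- **Differential expression**: the exact conditional test for
  negative-binomial counts (`Var = μ + φμ²`), with common and tagwise
  dispersion by conditional maximum likelihood (empirical-Bayes shrinkage,
  `prior.df = 10`), double-tail two-sided p-values, and
  Benjamini–Hochberg FDR — implemented directly and verified against
  enumeration oracles and an independent implementation.
- **Reporting**: UPGMA sample clustering on `log2(CPM+1)` (Euclidean
  distance), Newick export, media-versus-sample comparison tables, and a
  JSON-manifested artifact bundle.

See `vignettes/evsmallrna-methods.Rmd` for the model, the filtering rules,
all tunable parameters, and the generator's design.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data and narrate what they find; `Rscript analysis/01_simulate.R` through
`analysis/06_report.R` writes every table under `results/`. An end-to-end
run in a session looks like:

```r
library(evsmallrna)

design <- sim_design(seed = 1)        # 2 hPSC-like + 3 AT-MSC-like EV
run <- run_pipeline(design, read_level = TRUE)

round(run$composition$class_fractions, 3)   # per-sample class fractions
head(run$de$mirna[order(run$de$mirna$pValue), ])
table(run$groups$group)
```

On seed 1 the analysis chain prints (abridged):

```
Classified 131350 raw reads; per-sample partitions conserved.
mirna table: 45 features, 45 detected; media filter removed 5/5
  media-only and kept 40/40 genuine.
hPSC:  40 miRNAs summarized; 57% canonical-dominant, 42% 3'-dominant;
       65% of miRNA reads carry variation.
ATMSC: 40 miRNAs summarized; 30% canonical-dominant, 50% 3'-dominant;
       76% of miRNA reads carry variation.
Tested 45 detected miRNAs; 19 significant at FDR < 0.01.
Signature groups:  ATMSC_only 5 | excluded 13 | hPSC_only 11 | shared 16
Clustered 40 filtered miRNAs across 5 EV samples; groups in disjoint
  subtrees: TRUE
```

Reading this: every raw read was assigned to exactly one stage; all ten
media-background features (known from the generator's ground truth) were
excluded by the two-fold media rule while no genuine miRNA was lost; both
groups' isomiR dominance profiles match their designed archetype mixtures;
and the two sample groups separate cleanly in the dendrogram.

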