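# ThermoGx

Comparative genomics and photophysiology of thermophilic *Synechococcus*
A/B — the hot-spring cyanobacteria that include the most heat-tolerant
phototrophs known. Strains of this group sort into clades along a thermal
gradient (~50–73 °C), and the classic predictions for thermophily (smaller
genomes, purine loading, GC-rich RNAs, IVYWREL-enriched proteomes, massive
horizontal gene transfer) can be tested clade by clade. ThermoGx provides
the full analysis chain for that kind of study, for R users working on any
clade-structured bacterial system:

* **Composition** — genome GC and codon-position GC (GC1/GC2/GC3), purine
  (AG) content, RNA-gene GC, fraction of non-coding DNA, amino-acid
  composition, IVYWREL, and dipeptide successor frequencies such as
  P(Gly | Asp) used to study aspartate lability.
* **Pan-genome** — single-linkage protein ortholog clustering at an
  identity cutoff (Needleman–Wunsch, BLOSUM62, affine gaps), clade core
  genomes (single-copy in every member), clade-unique gene calling with the
  coverage/E-value screen `E ≤ 1e-50`, coverage ≥ 50 %, relaxed per gene to
  `min(best within-clade E / 2, 1e-10)`, and fragment-based average
  nucleotide identity (reciprocal best 1020-bp fragments).
* **Phylogenomics** — supermatrix concatenation, Poisson-corrected protein
  distances `d = −ln(1 − p)`, neighbor-joining trees, per-branch gene
  concordance factors (gCF) and internode certainty
  `IC = 1 + p₁log₂p₁ + p₂log₂p₂` (signed), GC3 z-score outlier scans for
  horizontally transferred genes, and Nei–Gojobori (1986) pairwise dN/dS
  with Jukes–Cantor correction.
* **Trait models** — phylogenetic generalized least squares with an
  Ornstein–Uhlenbeck correlation structure `C_ij = exp(−α·d_ij)` (the
  corMartins model), α estimated by REML profile, with the OLS fit reported
  alongside; plus one-way ANOVA summaries.
* **Physiology** — Platt photosynthesis–irradiance fits
  `P(I) = Pₛ(1 − e^{−αI/Pₛ})e^{−βI/Pₛ}` by multi-start least squares and by
  a hierarchical Bayesian sampler for replicated curves; ¹⁴C assimilation
  arithmetic; oxygen-evolution slopes over the 5–10 s window; exponential
  growth-window fitting; thermal performance summaries (T_opt, CT_max,
  niche breadth); compensation points.
* **Synthetic data** — a seeded generator that emulates the study design:
  six clades on a 55–71 °C ladder (coolest basal), genome size declining
  with temperature, per-clade GC offsets, an Asp→Glu replacement gradient,
  clade-private genes, one *Thermus*-like transferred gene with donor-like
  GC3 restricted to the hottest clades, and P–I/growth/O₂ measurements.

## Worked example

```r
library(ThermoGx)

cfg <- syntheticConfig(seed = 1)      # 6 clades x 8 strains, 55-71 degC
res <- runAll(cfg, outDir = "run1")   # simulate -> ... -> report.json
str(res$report[c("size_pgls_slope", "size_pgls_F", "size_pgls_p",
                 "asp_slope_per_5C", "false_unique_core_calls",
                 "hgt_genes_flagged", "hgt_dnds")])
#> $ size_pgls_slope        : num -242
#> $ size_pgls_F            : num 333
#> $ size_pgls_p            : num 1.04e-22
#> $ asp_slope_per_5C       : num -0.0604
#> $ false_unique_core_calls: int 0
#> $ hgt_genes_flagged      : num 1
#> $ hgt_dnds               : num 0
```

Reading the numbers: genome size shrinks by ~242 bp per °C of collection
temperature under the PGLS model (F₁,₄₆ = 333, P ≈ 1e−22); aspartate usage
falls by ~0.06 percentage points per 5 °C (about −1.4 % in relative terms);
no core gene is ever miscalled as clade-unique; the implanted transferred
gene is flagged as a GC3 outlier in every recipient genome; and its dN/dS
against the other recipient clade is ≈ 0, i.e. purifying selection.
Per-stage tables (`composition.tsv`, `unique_genes.tsv`,
`branch_support.tsv`, `platt_fits.tsv`, ...) land in `run1/`.

Individual stages run standalone, e.g.

```r
sim <- generateGenomes(cfg)
compositionReport(sim$genomes)            # per strain + clade means
pangenomeAnalysis(sim$genomes)            # cores / unique genes
gc3OutlierScan(sim$genomes[["c6_s1"]])    # HGT candidates
pglsFit(genome_size ~ collection_temperature, sim$traits, sim$tree)
```

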