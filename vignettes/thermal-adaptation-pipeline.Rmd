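---
title: "Models and methods behind the ThermoGx pipeline"
author: "ThermoGx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the ThermoGx pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ThermoGx analyses temperature adaptation in clade-structured bacteria —
the motivating system is the thermophilic *Synechococcus* A/B group of
alkaline hot springs, whose clades sort along a ~50–73 °C gradient. This
vignette explains the models the package implements, the assumptions they
make, the tunable parameters that matter, and the choices made where the
design was genuinely open. The worked entry point is:

```{r}
library(ThermoGx)
res <- runAll(syntheticConfig(seed = 1), outDir = "run1")
```

## Coordinates and containers

Genomes are `GenomeRecord` objects: a `DNAStringSet` of contigs, a
`GRanges` of features (CDS/rRNA/tRNA/gene), an `AAStringSet` proteome, and
strain metadata (clade, collection temperature in °C). All intervals use
the 1-based closed convention shared by GFF3 and `GRanges`, so annotation
import performs no coordinate arithmetic at all and every interval
operation (union length for the non-coding fraction, overlap merging) is
delegated to `IRanges`. This removes the classic off-by-one class of bug
at the cost of differing from the 0-based half-open convention common in
Python tooling; the boundary is the file format, which both conventions
read identically.

## Composition statistics

All base-composition statistics pool counts across sequences and exclude
ambiguity codes (including N) from numerator and denominator, so GC is
never biased by ambiguous draft-assembly positions. Codon-position GC
(GC1/GC2/GC3) pools codons of all coding sequences, keeps stop codons, and
applies a partial-codon policy: the default trims a trailing partial codon
with a warning (draft annotations contain edge-truncated CDS), a strict
mode errors instead. "Non-coding" defaults to *not covered by any
CDS/rRNA/tRNA feature* — structural RNA genes are functional, not
intergenic — with `includeRna = FALSE` exposing the CDS-only definition,
since published "% non-coding" values are ambiguous on this point.

Amino-acid composition is a 20-residue vector (X, stop symbols and the
rare translated U/O are excluded, matching heat-map style presentations);
clade means are unweighted by genome size, matching per-strain heat-map
presentation. IVYWREL is the exact sum of the Ile/Val/Tyr/Trp/Arg/Glu/Leu
entries. The Asp–Gly context statistic is the conditional successor
frequency P(next = Gly | current = Asp), pooled across proteins with no
counting across protein boundaries; a terminal Asp has no successor and
leaves the denominator.

## Pan-genome inference

Protein pairs are aligned globally (Needleman–Wunsch, BLOSUM62, gap open
11 / extend 1 — the classic BLASTp scoring). Identity is identical
positions over alignment columns including gaps (BLAST `pident`
semantics); mutual coverage is the fraction of alignment columns where
both sequences hold a residue, relative to each length. Orthologs are
single-linkage clusters over pairs passing both cutoffs — deliberately the
transitive-closure semantics, verified in the tests against an independent
brute-force closure. Defaults mirror the study design: 95 % identity
within clades, 70 % across clade cores, 50 % coverage. A shared-k-mer
prescreen (three distinct 4-mers) skips clearly unrelated pairs; it is an
admissibility filter for the desk-scale regime, and `prefilter = FALSE`
restores exhaustive alignment.

A clade core cluster is present in *exactly one copy in every clade
member*. Unique-gene calling follows a two-stage design: clade cores are
first linked across clades at 70 % identity, and only clade-restricted
candidates enter the homology screen, where a candidate stops being unique
if an out-of-clade local alignment passes coverage ≥ 50 % and E ≤ 1e−50
(Karlin–Altschul `E = K·m·n·e^{−λS}` with the standard gapped constants
λ = 0.267, K = 0.041). Candidates surviving the strict pass are re-screened
at the relaxed threshold `min(best within-clade E / 2, 1e−10)` — the
rationale being that a cross-clade hit nearly as strong as the gene's own
within-clade hits is evidence against uniqueness even when it misses the
strict cutoff. Note the direction: a larger relaxation floor raises the
threshold and can only *shrink* the unique set.

ANI uses the orthologous-fragment scheme: both genomes are chopped into
non-overlapping 1020-bp fragments, fragments are matched by best local
alignment on either strand, and ANI is the mean identity over reciprocal
best pairs with identity ≥ 30 % and aligned coverage ≥ 70 % of the
fragment. When no pair qualifies the result is flagged undefined rather
than reported as a number.

## Phylogenomics

Species and gene trees are estimated by neighbor joining on
Poisson-corrected distances `d = −ln(1 − p)` over mutually ungapped sites.
This is a deliberate substitution for maximum-likelihood search, which is
outside the package's scope; the concordance machinery accepts any
imported Newick species tree, so an externally inferred ML tree can be
scored directly.

For each internal species-tree branch, a gene tree is *decisive* when at
least two taxa of each side of the bipartition remain after restriction to
the gene tree's taxa. gCF is the percentage of decisive gene trees whose
restricted bipartition set contains the branch. IC compares the branch's
frequency f₁ with the frequency f₂ of its most frequent conflicting
bipartition: with pᵢ = fᵢ/(f₁+f₂), `IC = 1 + p₁log₂p₁ + p₂log₂p₂`, negated
when f₂ > f₁ so that the score spans [−1, 1]; no observed conflict gives
IC = 1 and a branch with no decisive gene tree is reported as undefined
(NA), never 0. Multifurcating gene trees that neither contain nor conflict
with a branch stay in the gCF denominator by default
(`multifurcation = "conflict"`); `"abstain"` drops them.

The GC3 outlier scan standardizes per-gene third-position GC against the
genome's gene population (genes ≥ 100 codons; at least 20 genes so the
variance is stable) and flags |z| ≥ 3 as horizontal-transfer candidates —
the compositional signature of a recently acquired gene whose donor codon
usage has not yet ameliorated.

dN/dS is the Nei–Gojobori (1986) pathway-counting estimator: per-codon
expected synonymous sites averaged over the two sequences (substitutions
to stop codons count as nonsynonymous), observed differences partitioned
along minimal mutational paths with equal weights and stop-containing
paths excluded, proportions Jukes–Cantor corrected
(`d = −(3/4)ln(1 − 4p/3)`). The frozen test values were computed with an
independent pathway-counting implementation. dS = 0 yields an undefined
ratio flag rather than a number.

## Phylogenetic regression

Trait–temperature models use generalized least squares with the
Ornstein–Uhlenbeck correlation `C_ij = exp(−α·d_ij)` on patristic
distances (the corMartins structure; non-ultrametric trees are accepted
because distances, not times, enter the kernel). α ≥ 0 has units of
1/branch length; α → 0 approaches a degenerate all-ones correlation (a
warning), α → ∞ the identity, i.e. ordinary least squares. When
estimated, α maximizes the restricted likelihood on a 31-point log grid
spanning 10⁻³–10³ refined by golden-section search — a profile that is
cheap, deterministic, and immune to bad starting values. The slope F-test
compares the full and intercept-only GLS fits with the same correlation;
R² is computed on GLS-whitened responses. Because the study system itself
reported that phylogenetic correlation was effectively erased, every
`PGLSFit` carries the parallel OLS summary so both paths are visible. The
implementation is cross-checked in the tests against `nlme::gls` with
`ape::corMartins` at fixed α.

## Photophysiology

The Platt model `P(I) = Pₛ(1 − e^{−αI/Pₛ})e^{−βI/Pₛ}` has initial slope α
(rate per μmol photons m⁻² s⁻¹), scale Pₛ, and photoinhibition β ≥ 0; the
maximal rate is Pm = Pₛ for β = 0 and
`Pₛ(α/(α+β))(β/(α+β))^{β/α}` otherwise. The default fit omits β, since the
reported quantities are Pm and α; `model = "with_beta"` enables it. The
least-squares fit runs Nelder–Mead from a deterministic 3×3 start grid
(α seeded by the secant through the first two distinct irradiances, Pₛ by
the maximum rate, each scaled by 0.5/1/2) on log-parameters, so positivity
is structural and restarts are reproducible. Standard errors come from the
Jacobian at the optimum. For replicated curves, a hierarchical sampler
draws replicate-level log-parameters from strain-level normal hyperpriors
centred on the pooled NLS fit (Metropolis-within-Gibbs: random-walk
updates for replicate parameters, conjugate draws for hyper-means,
half-normal priors on hyper-SDs), with 4 chains × 5000 iterations, 50 %
burn-in, a fixed default seed (1729), split-chain R-hat monitoring and a
non-convergence flag that is never silent. No ¹⁴C isotope-discrimination
factor is applied in the assimilation arithmetic (an optional multiplier
can be layered on by the caller); the formula is pure dimensional
analysis: labeled fraction × DIC pool → mass carbon, normalised by
chlorophyll mass and incubation time.

Growth rates fit ln(OD) against time. Candidate exponential windows are
runs of ≥ 3 consecutive points with positive slope and R² ≥ 0.9 (a 48-h
sampling cadence over ≥ 3 generations leaves few points, hence the minimum
of 3); among candidates within 0.02 R² of the best, the longest window
wins. The margin stage exists because the plain longest-qualifying rule
can swallow a lag or plateau shoulder point whose inclusive window still
clears 0.9, biasing μ low. A series with no qualifying window is a
"no growth" result, not an error. Thermal performance summaries stay on
the tested temperature grid: T_opt is the argmax of μ (ties resolved to
the cooler temperature — the conservative choice for a thermophile),
CT_max the hottest temperature with growth, niche breadth the span of
temperatures with μ ≥ 50 % of the maximum. Oxygen evolution is the OLS
slope over the 5–10 s window of the trace; the compensation point solves
`P(I) = R_d` by bracketed root search on the rising limb (≈ R_d/α in the
linear regime).

## What the synthetic generator emulates — and what it does not

`syntheticConfig()` encodes the study conditions: 6 clades × 8 strains on
a 55/57/60/63/68/71 °C ladder with the coolest clade basal; genome size
30 kb at 55 °C declining 250 bp/°C with 400 bp Gaussian noise (a
desk-scale miniature of the Mb-scale decline, preserving the
slope-recovery statistics); a lower GC for the coolest clade; aspartate
replaced by glutamate at 1.6 % (relative) per 5 °C via deterministic
pooled D→E swaps; 18 core gene families diverged by
composition-preserving shuffling (~8 % between clades, ~1 % within); 3
clade-private families built as permutations of shared composition
templates (identical residue pools, no cross-clade similarity — making
unique-gene ground truth unambiguous); and one transferred gene restricted
to the two hottest clades, sharing donor codons with GC3 offset +25
points, ~2 % synonymous per-strain divergence, and a residue pool matched
to the host so its insertion cannot distort the composition gradient. P–I
data use exactly the 13 irradiances of the assay design (0–1504 μmol
photons m⁻² s⁻¹) with Gaussian noise of 5 % of Pₛ; OD series have
lag/exponential/plateau segments sampled every 48 h; O₂ traces are linear
plus noise. Every generator is a pure function of (config, seed).

Deliberate non-realism, hence limits on what passing tests show about real
data: no indels or rearrangements (per-family "alignments" are trivially
columnwise), intergenic DNA is not inherited between related strains (so
whole-genome ANI between synthetic relatives understates the similarity of
real relatives), protein divergence is composition-preserving by
construction, and annotation is always exact. Real draft genomes violate
all four, which is why the composition, clustering and concordance
machinery is additionally validated against hand counts and brute-force
oracles rather than only against the generator.

## Numerical choices and desk-scale test sizes

Tie-breaks and degenerate inputs are pinned throughout: cluster ids are
ordered by their lexicographically smallest (genome, protein) member; NJ
inherits `ape::nj` determinism and clamps its occasional tiny negative
branch lengths to zero; a GC3 scan with zero inter-gene variance errors
rather than dividing by zero; saturation (p ≥ 1 for Poisson distances,
p ≥ 3/4 for Jukes–Cantor) raises an error rather than returning a complex
number. The test suite sizes were chosen to keep the full run in minutes
on one CPU while leaving the statistics meaningful: 1000-sequence
composition identities, 50 cluster-oracle instances of 20 proteins, 100
additive-matrix NJ recoveries, 200 OU slope-recovery and 1000 null
type-I-error PGLS replicates on a 64-leaf tree, 100 noisy Platt
replicates, 10 hierarchical-sampler runs, and 20 end-to-end seeds of the
default 48-genome study.

## Known limitations

Maximum-likelihood and Bayesian tree search, bootstrap support and model
selection are out of scope by design — import an external tree where those
matter. The E-value model is ungapped Karlin–Altschul applied to gapped
scores, the standard BLAST approximation; absolute E-values are therefore
calibrated only to order of magnitude, which is the resolution the
unique-gene rule needs. The hierarchical Platt sampler is a fixed-shape
Metropolis-within-Gibbs scheme, adequate for the two- to three-parameter
curves it targets, not a general-purpose MCMC engine. dN/dS is pairwise;
branch-specific estimates on a tree would require ancestral
reconstruction, which the package approximates only by choosing
representative pairs.
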