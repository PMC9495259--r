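---
title: "Multi-omics candidate-gene prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics candidate-gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsgsomics)
```

# The problem

Recurrence of focal segmental glomerulosclerosis (rFSGS) after kidney
transplantation is rare, so the cohorts available for molecular screening
are tiny — typically a handful of recurrence (RC), remission (RM) and
healthy-control (HC) subjects profiled from peripheral blood mononuclear
cells. With n = 3 per group no single assay is conclusive. The design this
package implements therefore *triangulates* three independent evidence
channels — exonic variant sharing, differential expression, and
pathway-level crosstalk — and accepts a gene as a top candidate only when
all three agree. A separate metabolomics arm characterizes the downstream
consequence of a candidate mutation in a cell model (mutant vs wild-type
lines with pooled QC injections).

# The variant channel

Variants are read from a genotyped VCF and joined to a tabular annotation
(gene symbol, function class, dbSNP id) keyed by chrom/pos/ref/alt;
multi-allelic records are split per ALT because the downstream rules are
per-allele. Only nonsynonymous SNVs are retained: synonymous changes do
not alter the protein, and nonsense calls are excluded to match the
screen's focus on missense-driven dysfunction (a `keep_nonsense` flag
restores them for conventional pathogenicity screens).

Two presence rules follow. *Stage 1*: carried by ≥ 2 subjects of a case
group and by no HC — a permissive shared-with-disease screen. *Stage 2*:
carried by **all** RC subjects, ≤ 1 RM subject, no HC — the
recurrence-association rule. "Carried" means genotype het or hom; the rule
is stated in carrier terms, so zygosity is recorded and reported (the
expected causal pattern is homozygous in all RC) but not filtered on
unless `require_hom = TRUE`. Group sizes come from the manifest, never
hard-coded, so the same rules generalize beyond 3+3+3.

No burden or association test is attempted: with three cases per arm,
set rules are the honest instrument, and their false-positive behaviour
is measured on null simulations instead of asymptotic theory.

# The expression channel

Abundances are TPM, already depth- and length-normalized, so a lognormal
noise model is appropriate and tests act on `log2(TPM + c)` with
pseudo-count `c = 1` (configurable). The test is Welch's two-sample t:
with n = 3 there is no power to verify equal variances, and for two
groups the nested linear-model F-test used by transcript-assembly
pipelines reduces to an equal-variance t, so Welch is the robust
near-equivalent. Genes with zero variance in both groups are untestable
and get p = 1. The reported fold change is computed on mean TPM,
`log2((mean_a + c)/(mean_b + c))`, with the first group over the second; a
DEG requires raw p < 0.05 *and* |log2FC| > 1. Raw p is the default (an
optional BH mode exists) — at these group sizes the screen is meant to be
sensitive, and the later enrichment stage carries its own FDR control.

The disease-related set is
`DEG(RC,RM) ∪ (DEG(RC,HC) \ DEG(RM,HC))`: genes separating recurrence from
remission, plus genes separating recurrence from healthy controls unless
they also separate remission from controls — those reflect
transplantation or immunosuppression rather than recurrence. Venn region
cardinalities are attached for reporting.

# Enrichment and crosstalk

Over-representation is the one-sided hypergeometric upper tail
`P(X ≥ k | N, K, n)` with the universe `N` set to the measured genes (the
expression matrix), not the genome — the standard conditioning for
expression-derived candidate lists. BH correction runs over the pathways
actually tested, i.e. those overlapping at least one candidate, matching
the behaviour of enrichment servers that only report overlapping terms.
Significance is strict: P_BH < 0.05.

Crosstalk edges score every unordered pair of eligible pathways
(significant and ≥ 3 candidate genes) with the Jaccard coefficient
`|A∩B| / |A∪B|` and the overlap coefficient `|A∩B| / min(|A|,|B|)`; the
edge score is their average and pairs sharing < 2 genes are dropped. The
gene lists A and B default to each pathway's *candidate overlap*: the
eligibility thresholds ("≥ 3 candidate genes", "≥ 2 overlapped genes")
only make sense on candidate genes, and scoring full catalogs would let
two pathways form an edge through genes with no disease evidence at all.
Because the defining sentence is genuinely ambiguous, a
`gene_scope = "full_pathway"` mode implements the other reading. Edge
output is sorted by descending score with deterministic tie-breaks
(shared-gene count, then lexical pair id) so artifacts are byte-stable; no
display cutoff is applied — ranking is the deliverable, drawing decisions
belong to the viewer.

Triangulation overlays the stage-2 genes on the DEG-built network (variant
genes do not create edges) and flags, per gene: `snp_hit`, `is_deg`, and
`in_crosstalk` — the latter by *full catalog* membership in a network
pathway, since a variant gene need not be a DEG to sit in a crosstalk
pathway. Ranking is by number of flags, then `snp_hit`, then |log2FC|;
tier 1 means all three flags. The expression direction in RC vs RM is
reported with a flat band of |log2FC| < 0.1.

# Metabolomics

The cascade begins at the quantified feature table (peak picking is out of
scope). Missing intensities are `NA`, never zero. A feature is kept when
detected in ≥ 50 % of QC injections **and** ≥ 80 % of test samples — the
removal rule is a union ("removed if < 50 % QC *or* < 80 % test"), so the
keep rule is the conjunction; both thresholds are configurable.

Imputation is k-nearest-neighbour over *features* (k = 10): neighbours by
Euclidean distance on jointly observed samples, inverse-distance-weighted
averages of the neighbours observed at the missing sample, with the
feature's own mean as fallback. Drift correction is a simplified QC-robust
spline correction: per feature, a smoothing spline of intensity versus
injection order fitted on QC injections only (df ≤ 4, at least 4 QCs
required), every sample divided by the trend normalized to its QC mean;
outside the QC-bracketed injection range the trend is held constant
rather than extrapolated. Exact spline hyper-parameters of published
QC-RSC implementations are not reproduced; the correction is deliberately
labelled simplified.

PLS-DA uses a 0/1 class response, autoscaled predictors and the NIPALS
algorithm with a fixed 2 components — matching the conventional
two-dimensional score plot and keeping fits deterministic rather than
cross-validated. VIP is computed from component weights weighted by
per-component explained response variance; squared VIPs average to exactly
1, so VIP ≥ 1 marks above-average importance. A feature is called
differential when VIP ≥ 1 *and* the raw Welch-t p on log2 intensities is
< 0.05 (the two stated criteria combined conjunctively; BH-adjusted FDR is
reported alongside). `plsda_permutation_test()` guards against the
method's tendency to separate even random labels at small n. Krebs-cycle
ratio presets (malate/citrate, fumarate/citrate, succinate/citrate) are
compared per sample by Welch's t-test.

# The synthetic cohort generator

`sim_config()` defaults describe the study conditions the package is
designed for:

| parameter | default | rationale |
|---|---|---|
| group sizes | 3 / 3 / 3 | the honest small-sample regime |
| genes | 500 | enough for calibrated DEG rates, fast tests |
| background variants | 400; 3 decoys | decoys pass stage 1 only, so the two filters are distinguishable |
| baseline TPM | lognormal, meanlog 3, sdlog 1.2 | typical PBMC abundance spread |
| replicate noise | sd 0.4 (log2) | ≈ 30 % CV between biological replicates |
| planted DE | 10 % of genes, &#124;log2FC&#124; ∈ [1.5, 2.5] | clearly past the 1.0 call threshold |
| causal gene log2FC | −1.5 | under-expression in recurrence |
| pathways | 40, sizes 10–50, 30 % chained overlap | creates crosstalk structure beyond the planted anchors |
| metabolomics | 6 + 6 samples, 4 QCs, 300 features, noise sd 0.5 (log2), 15 % missing | a minimal but realistic two-condition LC–MS design |
| discriminant metabolites | 10, shift = 2 noise SDs | detectable but not trivial for VIP |

The causal gene carries the full planted pattern: a homozygous
nonsynonymous variant in every RC subject (absent elsewhere),
under-expression in RC, and membership in two anchor pathways that share
several planted DE genes. It is planted at the median abundance level — a
well-expressed metabolic enzyme — so the pseudo-count does not erode its
fold change. Background variant patterns are rejection-sampled from
patterns that fail the stage-2 rule, which makes the null behaviour of the
filter exact by construction. The malate-role feature is shifted up and
the citrate-role feature down in the mutant condition, driving the
malate/citrate ratio increase; fumarate and succinate receive mild
(±0.3 log2) shifts that are not reliably called, mirroring a
direct-precursor pattern. Missingness is masked at random on background
features only, so the composition of the planted signal is deterministic;
real tables have missingness everywhere, including informative
(intensity-dependent) missingness the generator does not model.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: linkage structure between variants,
negative-binomial counting noise and batch effects in expression,
pathway-size bias in annotation databases, correlated metabolite modules,
and intensity-dependent missingness. The generator's role is to verify
the pipeline's logic and calibration, not to certify power on real
cohorts.

# Numerical and testing choices

Determinism is a contract: a fixed seed yields byte-identical cohorts,
artifacts and reports (no hash-order dependence; sorted outputs with
explicit tie-breaks everywhere). The packaged fixture (9 samples, 20
genes, 10 variants, 4 pathways, seed 42) is small enough that every
stage's expected output is hand-computable — exactly one stage-2
survivor, a four-gene DEG set, one crosstalk edge with JC = 1/2 and
OC = 2/3 — and it regenerates bit-identically from `make_fixture()`.

Test problem sizes are deliberately modest: recovery and null calibration
use 20 cohorts each at the default configuration; DEG-rate calibration
uses 50 label permutations of one null cohort with the fold-change
threshold set to 0, so the check isolates p-value calibration against the
nominal 0.05 (the mean permuted rate is required to sit within three SDs
of the permutation-rate distribution — Welch at n = 3 is mildly
conservative, which this band tolerates); VIP recovery uses 20
metabolomics simulations. The hypergeometric tail is verified against
exhaustive subset enumeration for every (N ≤ 12, K, n, k), BH against a
hand-coded step-up oracle, JC/OC against explicit membership arithmetic,
and the PLS-DA VIPs against an independent reference implementation where
available.

# Limitations

Stage rules are set-logic, not statistics: no population allele
frequencies, no relatedness handling, no genotype-quality filtering
beyond what the VCF already encodes. Expression testing is gene-level
only. Enrichment reproduces neither EASE-style modified scores nor
term-tree redundancy pruning, so pathway counts will differ from web
servers even on identical inputs. The QC spline correction is a
simplification. Group sizes below three per arm are rejected rather than
approximated. These are scope decisions: every threshold named above is a
single YAML line in the pipeline config, and the module surfaces accept
alternative settings where a different study design needs them.
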