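---
title: "Genome-based genus delineation and PUL profiling with ProkTax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based genus delineation and PUL profiling with ProkTax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProkTax)
```

## The problem

Bacterial genera in groups such as the marine *Marinilabiliales* are
increasingly delineated from whole genomes rather than 16S rRNA alone.
Two whole-proteome statistics dominate that practice:

* **AAI** (average amino acid identity): the unweighted mean percent
  identity over reciprocal best-hit (RBH) protein pairs between two
  genomes. Organisms sharing **AAI ≥ 65%** are commonly treated as
  congeneric.
* **POCP** (percentage of conserved proteins):
  $\mathrm{POCP} = 100\,(C_1 + C_2)/(T_1 + T_2)$, where $T_1, T_2$ are
  the proteome sizes and $C_1, C_2$ count proteins with at least one
  cross-genome hit at e-value $< 10^{-5}$, identity $> 40\%$ and an
  alignable region covering $> 50\%$ of the query. A **50–60%** band is
  the customary genus threshold, with 50% the operative bound here.

ProkTax computes both from protein FASTA input, summarizes their
within- and between-genus distributions, and turns joint threshold
exceedance into explicit genus-merge proposals. Around that core it
carries the companion analyses such studies run: detection of
polysaccharide utilization loci (PULs) from annotated gene tables, 16S
neighbor-joining trees with bootstrap supports, and KEGG-style module
completeness.

## Alignment layer and its statistics

All protein comparisons are optimal local alignments under BLOSUM62
with affine gaps (open 11, extend 1), computed by
`Biostrings::pairwiseAlignment()`. Identity follows the BLAST
convention — identical columns divided by alignment length, gap columns
included in the denominator — because the 40% POCP filter was defined on
BLAST output. E-values use the closed form
$E = K m n e^{-\lambda S}$ with fixed gapped-BLOSUM62 constants
($\lambda = 0.267$, $K = 0.041$) and $n$ equal to the total residue
count of the searched proteome; this reproduces BLAST semantics at desk
scale without re-estimating Karlin–Altschul parameters per matrix.
Residues without a BLOSUM62 column are scored through its `X` column.

One-way best hits keep, per query, the hit with the highest bit score
among those with $E < 10^{-5}$; ties break to the lexicographically
smaller subject id so results are reproducible bit for bit. Reciprocal
best hits are the intersection of the two directions. Because the two
directional alignments of a pair can differ when co-optimal alignments
exist, the identity assigned to an RBH pair is the **mean of the two
directional identities**; this makes AAI exactly symmetric in its two
arguments, which the rest of the package relies on.

The RBH quality filters for AAI are identity ≥ 30%, coverage ≥ 70% of
the shorter sequence, $E < 10^{-5}$ — values standard in AAI practice,
exposed in `aaiParams()`. POCP uses the strict inequalities of its
definition (`> 40%`, `> 50%`, `< 1e-5`), applied per direction with the
querying proteome's protein as the query. When no RBH pair passes the
filters, AAI is reported as explicitly undefined (`aaiDefined()` is
`FALSE`), never as 0.

```{r}
sim <- simulateProteomePair(nA = 20, nB = 20, nOrth = 12,
                            targetIdentity = 80,
                            lengthRange = c(80L, 150L), seed = 7)
computePairMetrics(sim$a, sim$b)
```

## Genus delineation

`summarizeGroups()` reduces the pairwise matrices to one
mean/min/max/n summary per metric per genus pair (intra-genus summaries
exclude the diagonal). `classifyPair()` applies the thresholds jointly:
*congeneric* iff AAI ≥ 65 **and** POCP ≥ 50 (inclusive bounds),
*distinct* iff both fall below, *ambiguous* otherwise. Ambiguity —
one metric passing — never drives a merge, mirroring the requirement
that the two metrics converge before taxonomic action.

`proposeMerges()` decides per **genus pair** from the *mean* of its
inter-genus pairwise values (published arguments are phrased in means
and ranges), then merges connected components of the congeneric graph.
Single-linkage transitivity is a modeling choice: it is the simplest
rule that can place two genera jointly into a third, which is exactly
the situation the method is designed for. Means are taken over all
genome pairs by default; restricting input to type strains is the
caller's choice of which genomes to include. The proposed name of a
merged component comes from a user-supplied nomenclatural priority
list (no automatic priority inference is attempted), falling back to
the alphabetically first member.

## PUL and gene-cluster detection

Input is a per-genome ordered gene table carrying collapsed annotation
classes (`GH`, `GT`, `PL`, `CE`, `AA`, `CBM`, `SULFATASE`, `TBDT`,
`SUSD`, `OTHER`), such as a digested dbCAN2 output. Marker genes are
degradative CAZymes (GT excluded), sulfatases, TonB-dependent
transporters and susD-like genes. Two markers belong to one cluster iff
their gene-ordinal distance is ≤ 10 (single linkage per contig; a
distance of 10 allows up to nine intervening genes). The
often-mentioned seven-gene scan window is treated as an implementation
detail of scanning: the within-ten-genes linkage clause is the only
criterion that can affect membership, so the window cannot change the
output. Strand is ignored; clusters never span contigs; clusters with
fewer than two markers, or with no degradative CAZyme, are discarded.
GT genes count toward per-genome CAZyme totals but never seed or join
clusters.

The three-way classification follows the susC/susD convention from the
PUL literature, since the class names are used in the field without a
formal definition: a **PUL** carries a TBDT and a susD-like gene at
adjacent ordinals plus at least one degradative CAZyme; a **PUL-like**
cluster has a TBDT or susD-like gene without that tandem; anything else
is a **CGC**. All three criteria are overridable through `pulParams()`
and `classifyClusters()`.

## 16S distances, neighbor joining, bootstrap

The multiple sequence alignment is an input (any standard aligner);
the package aligns only pairs, globally, for identity percentages.
Pairwise identity excludes every gap column from the denominator by
default (EzTaxon-like); a variant including internal gap columns is a
flag, because published similarity percentages are platform-dependent
and only approximately reproducible.

Distances are computed over pairwise-complete columns under p-distance,
JC69 or K2P; K2P is the default, matching the common choice for rRNA
distance trees in desktop phylogenetics software, as the model behind
published trees is rarely stated. Saturated pairs (logarithm argument
≤ 0) are flagged rather than silently clamped, and neighbor joining
refuses to run on them with advice to switch models.

Neighbor joining is the Saitou–Nei agglomeration with the standard Q
criterion. Two numerical choices are pinned down for reproducibility:
Q ties break to the smallest index pair, and negative intermediate
branch lengths are clamped to zero with the deficit moved to the sister
edge so path lengths through the new node are preserved (the display
convention of mainstream tree software). On additive matrices the
generating tree is recovered exactly; the test suite asserts topology
and path-length recovery to 1e-9 on random additive matrices of up to
8 taxa, cross-checking topologies against `ape::nj()`.

Bootstrap supports resample alignment columns with replacement
(default 1,000 replicates, seeded) and report, per internal edge of the
full-data tree, the percentage of replicate trees containing the same
leaf bipartition. Supports below 50 are retained in the tree but
flagged hidden for display, the usual convention for published trees;
`writeNewickTree(minSupport = 50)` applies the convention on export.
Replicates whose resampled matrix is saturated count as containing no
bipartition, which can only deflate supports, never inflate them.

## Module completeness

KEGG-style definitions are parsed with precedence minus > plus > comma
> space (parentheses override): space separates serial steps (AND),
comma separates alternatives (OR), plus joins complex subunits (all
required), minus marks optional components. Completeness is the
percentage of satisfied top-level steps — block-level, not leaf-level —
matching the step-fraction semantics behind published completeness
percentages. Optional components are excluded from numerator and
denominator, so an entirely optional block never contributes.

```{r}
moduleCompleteness("(K00001,K00002) K00003", c("K00002", "K00003"))
```

## The synthetic-data generator

The generator exists so every stage can be validated against known
truth, and its defaults are the regime the pipeline targets:

* `simulateProteomePair()` — proteomes of 100 + 100 proteins of 100–400
  residues, a controlled number of ortholog pairs mutated to a target
  identity. Mutations are substitutions only, so the realized identity
  of each pair is exact by construction and serves as the oracle for
  AAI/POCP parameter-recovery tests (the documented worked construction
  plants 60 full-length orthologs at 80% identity in 100+100 proteins,
  giving POCP 60 with $C_1 = C_2 = 60$). An indel-free model slightly
  flatters local-alignment identity at low targets (~50%), where
  end-trimming can raise measured identity by a point or two; the ±2
  recovery band in the tests reflects that.
* `simulateGeneTable()` — planted marker clusters with intra-cluster
  ordinal gaps within the linkage bound, separated by more than the
  bound from each other and from any background markers, so planted
  member sets are exactly what a correct detector must return.
* `evolveAlignment()` — sequences evolved down a known tree under the
  exact JC69/K2P transition probabilities, without indels.

What the generator does **not** emulate bounds what green tests prove:
no paralogy or domain shuffling (RBH on real genomes must contend with
both), no indels or compositional bias, uniform residue frequencies,
and no alignment error in the 16S input. Passing tests demonstrate
correctness of the statistics and algorithms under their stated
definitions, not robustness to annotation noise in real assemblies.

Problem sizes in the routine test suite are deliberately desk-scale —
proteomes of 12–100 proteins, 20 seeds per identity level, 200 planted
gene tables, 100 additive matrices, 100-replicate bootstraps — chosen
so the whole suite validates every contract in a few minutes while the
same code paths scale unchanged to real proteomes.

## Pipeline and reproducibility

`runFullAnalysis()` orchestrates the stages from a nested list or YAML
config (YAML is the package's config format; `defaultConfig()` prints
the structure). Stages with absent inputs are skipped with a logged
notice; referenced-but-missing files fail before any computation. Every
run writes `run.log` and `manifest.json` with input/output MD5
checksums, parameters, seed and package version; identical inputs and
seed reproduce identical checksums. All stochastic steps (generator,
bootstrap) run under a single seed recorded in the manifest. A thin
command-line wrapper lives in `inst/scripts/proktax.R`.

## Known limitations

* The aligner and parameters behind published AAI/POCP values are
  typically unstated; reproducing printed values for deposited genomes
  therefore carries aligner-choice uncertainty of a point or so, and
  the e-value layer uses fixed Karlin–Altschul constants rather than
  per-matrix estimation.
* Exhaustive all-vs-all Smith–Waterman is exact but not fast; at
  real-proteome scale (thousands of proteins) an external search
  engine's tabular output can stand in for the internal search.
* Whether published per-genome PUL counts require the susC/susD tandem
  or mere co-occurrence is not documented; per-genome counts from real
  annotations are therefore parameter-sensitive.
* Species-level metrics (ANI, dDDH), multiple sequence alignment,
  gene calling and CAZyme annotation are out of scope by design; the
  package consumes their outputs.
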