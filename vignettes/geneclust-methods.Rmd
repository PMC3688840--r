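---
title: "Methods: weighted positional clustering of genes and cluster significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted positional clustering of genes and cluster significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneclust)
```

## The problem

Genes that are co-expressed are often functionally related; functionally
related genes are frequently co-localized along a chromosome; and
co-localized, co-expressed genes are natural candidates for co-regulation by
shared transcription factors (TFs). `geneclust` analyses these three kinds of
co-occurrence jointly: it groups genes into *positional clusters* along each
chromosome under a configurable **weighted genomic distance**, and then asks
whether the resulting clusters are statistically surprising and how TF
repertoires and expression levels distribute across them.

The coordinate model is 1-based and inclusive (the Ensembl/Biomart
convention); BED input is converted on read. A gene is stored as its genomic
envelope `(chromosome, start, end, strand)` — transcript structure is out of
scope. Genes with unknown strand are rejected on load rather than guessed,
because the promoter-anchored metric depends on strand.

## Distance metrics

For two genes on the same chromosome, four base metrics are available, all
O(1), symmetric and non-negative:

* **positional** (default): `|start1 - start2|`;
* **functional**: distance between promoter anchors. The anchor is `start`
  for `+`-strand genes and `end` for `-`-strand genes, because standard
  annotation exports keep plus-strand coordinates for minus-strand genes;
* **centre**: `|centre1 - centre2|` with `centre = (start + end)/2`
  (possibly half-integer; derived distances are real-valued);
* **intragenic**: the gap between the gene bodies, clamped to 0 when they
  overlap. It never exceeds the positional distance for non-overlapping
  pairs.

Distances across chromosomes are undefined and raise an error: every
clustering algorithm partitions chromosomes independently.

## Weighting strategies

Weights multiply the base distance, so a factor below 1 pulls
attribute-similar genes together and a factor above 1 pushes them apart.
Multiplication is the only composition rule consistent with a single weight
acting as identity, and it lets several strategies combine freely.

* **uniform** — factor 1; combining it with any other weight is a no-op.
* **density** — local gene density at the inter-gene midpoint (count of gene
  starts in a window of width `W`, default 100 kb, divided by `W`) relative
  to the genome-wide mean density, clamped to `[eps, 1/eps]`. The same bp
  gap therefore counts as *farther* where genes are packed and *nearer* in
  gene deserts. The window default is a compromise between resolution and
  stability for gene-scale densities of typical eukaryotic chromosomes; it
  is a parameter, not a constant.
* **expression (ANOVA mode)** — `max(eps, 1 - p)` where `p` is the one-way
  ANOVA p-value for equality of the two genes' mean expression, with the two
  genes as groups and their replicate measurements as observations (at least
  two non-missing values per gene). Zero between-group variance returns
  `p = 1` by convention, hence the floor weight; zero within-group variance
  with distinct means returns `p = 0`. No normality check is applied — the
  mode simply assumes it, and the custom mode below is the fallback.
* **expression (custom mode)** — `max(eps, |e1 - e2| / (|e1| + |e2| + delta))`
  on scalarized expression values (mean by default); it works with a single
  value per gene. This normalized-absolute-difference form is this package's
  own choice of a bounded, scale-free similarity and is deliberately simple;
  it is exposed as a named strategy so alternatives can be plugged in.
* **tf** — `max(eps, 1 - J)` with `J` the Jaccard index of the two genes' TF
  name sets. Identical repertoires give the floor `eps`, disjoint ones give
  1, and two *empty* repertoires give 1: absence of annotation is treated as
  absence of evidence for similarity, not as similarity.
* **plug-ins** — any registered function of the two gene records and the
  evaluation context, referenced as `"plugin:<name>"`; returns are clamped
  into `(0, 1]` with a warning.

The floor `eps` (default 0.01) exists so that a weighted distance never
collapses to zero for distinct loci — identical TF sets or `p = 1` would
otherwise merge arbitrarily distant genes and destroy the positional
character of the metric.

Missing expression values are a distinct "not available" state throughout;
they are skipped by reducers, can never satisfy a filter threshold under the
default missing policy, and are never silently treated as zero.

## Clustering algorithms

**Sequential threshold scanning.** Genes are scanned per chromosome in
position order; gene *i* joins gene *i−1*'s cluster iff their weighted
distance is strictly below the threshold `T`, and opens a new cluster
otherwise. "Below" is read as strict; the boundary case is tested. Only
adjacent pairs are ever evaluated, so an `n`-gene, `c`-chromosome dataset
costs exactly `n - c` distance evaluations — the result object reports the
count, making the linear-time contract testable. Singletons are retained;
size filtering is post-processing. Because genes with identical starts are
ordered by end and then id, the scan is fully deterministic.

**1-D k-means.** Genes are embedded at the metric's anchor point (start,
promoter anchor, or centre; the intragenic metric has no point embedding and
is rejected) and Lloyd iterations run per chromosome. Three initializations:
`random` (k distinct gene positions), `uniform` (k evenly spaced points on
the chromosome, whether or not genes sit there), and `plusplus` (first
centroid uniform over gene positions, then D²-proportional draws), which
carries the usual O(log k) expected-competitiveness guarantee. Attribute
weights are *not* applied against virtual centroid points — a centroid has no
TF repertoire or expression vector to compare with — so k-means clusters on
the position embedding alone; this is a documented limitation. Empty
clusters are repaired deterministically by re-seeding at the gene position
farthest from its nearest centroid. `k = "auto"` uses the rule of thumb
`k = max(1, round(sqrt(n/2)))` per chromosome; this simple rule is kept in a
single swap-point function should a different optimal-k criterion be
preferred. Whether to cluster chromosomes jointly or separately was open;
per-chromosome was chosen for consistency with the other two algorithms.

**Max-gap clustering.** Given an ortholog map against a comparison genome:
(1) restrict the dataset to genes with at least one ortholog, in chromosome
order; (2) link two such genes iff the number of *non-orthologous* genes
between them, counted over the full background annotation, is at most
`maxgap`; clusters are the transitive closure of adjacent links (equivalent
to the all-pairs relation, since any spanning pair bounds its adjacent
sub-gaps); (3) discard clusters smaller than `minsize`. The background
annotation is an explicit argument (defaulting to the dataset itself)
because gap counting is only meaningful over the full gene order. Only
orthology *presence* in the partner genome is used; requiring the partner
genes to co-cluster as well is a stricter variant deliberately not imposed.
Any two organisms covered by an ortholog table are accepted.

## Significance procedures

**Random-set comparison.** Draw `n` genes without replacement from a pool,
re-run the identical clustering, record the cluster count, repeat; compare
the observed count with the replicates by a one-sample t-test,
`t = (observed - mean)/(SD/sqrt(reps))`, one-tailed by default in the
direction "observed produced more clusters than random". The two-tailed
variant is exposed as an option. A caveat users should know: treating the
observed count as a fixed reference mean ignores its own sampling
variability, so under a true null this test rejects more often than its
nominal level; it ranks candidate clusterings usefully but its p-values are
anti-conservative by construction. Zero-variance replicate sets are reported
with a degenerate flag and p of 0, 1 or 0.5 by the sign of the difference.

**Neighbourhood model.** Per chromosome with `N` background genes of which
`n` are selected, the statistic is the number of background-adjacent pairs
with both members selected. Under uniformly random placement its mean is
`n(n-1)/N`, and the SD comes from the exact first two moments of the sum of
adjacency indicators (joint selection probabilities of 2, 3 and 4 distinct
slots); a permutation mode exists purely for verification. The analytic
moments are checked against exhaustive enumeration for all `N <= 12` in the
tests.

**TF co-occurrence.** A cluster is "positive" for a TF when any member gene
carries at least one site. For a TF pair, the 2×2 presence/absence table
over clusters is tested with the two-sided Fisher exact test (sum of
hypergeometric probabilities not exceeding the observed table's). The
"both vs only-one" marginal counts are reported alongside, since that view
of the table is also of interest but does not admit an exact test by itself.

**Expression contrasts.** Two gene groups are compared with the Mann-Whitney
U test: exact by full enumeration of group assignments (midranks for ties;
two-sided extremity measured by `|U - mn/2|`) up to a combined size of 20,
and the tie-corrected normal approximation above that, without continuity
correction. The exact path is validated against an independent enumeration
oracle and against `wilcox.test` on tie-free inputs. The intended contrasts
are "clustered TF targets vs clustered non-targets" and "clustered targets
vs unclustered targets", but any two id sets are accepted.

## Synthetic fixtures

The generators exist so every operation is testable without downloads, and
their defaults are the package's study conditions. `generate_genome` plants
blocks of genes whose consecutive start gaps are uniform on `[1, G_in]`
(default 10 kb) separated by gaps uniform on `[G_out, 2 G_out]` (default
200 kb): any threshold strictly between the bounds — such as the 83 kb
default used throughout the examples — separates blocks exactly, which gives
parameter-recovery tests a known answer. `generate_attributes` plants
block-shared expression means (block means `N(0, 2)`, replicate noise SD
0.25) and block-private TF repertoires carried with probability `q = 0.8`
against a background carry rate `q0 = 0.1`. `generate_ortholog_fixture`
withholds chosen interior block genes from the ortholog map so that known
non-orthologous "insertions" realize known gap counts. Everything is a pure
function of (specification, seed), and ground-truth labels travel beside the
dataset, never inside it, so production code cannot consume them.

What the fixtures do *not* emulate: realistic gene structure, overlapping
transcription, GC/composition effects, motif-level TFBS prediction noise, or
inter-chromosomal organization. Passing recovery tests therefore shows the
algorithms implement their contracts, not that any particular biological
dataset will cluster cleanly.

## Numerical and design choices

* Ties in gene order (identical starts) break by end then id; k-means
  assignment ties go to the lower centroid index; all RNG-dependent steps
  take explicit seeds. Reports are byte-deterministic given config, inputs
  and seed (the run manifest echoes the configuration minus the output
  location).
* The sequential threshold and the max-gap relation are strict `<` and
  `<= maxgap` respectively, matching their definitions; both boundaries are
  pinned by tests.
* Lloyd iterations stop when the largest centroid movement is at most
  `1e-6` bp or after `max_iterations` (default 100).
* Gene lists referencing ids absent from the annotation are kept as
  "unresolved", reported, and excluded from positional operations.
* Merges resolve attribute conflicts in favour of the left operand,
  deterministically.
* Inter-gene "distance between consecutive genes" in chromosome statistics
  is start-to-start by default (matching the positional metric), with an
  end-to-next-start option.
* The command-line interface is a single config-driven `run` entry point
  (`inst/cli/geneclust.R`) executing import → filter → cluster → stats →
  report in order; the individual stages are ordinary exported functions, so
  separate subcommands would only duplicate the library surface.

## Problem sizes used by the test-suite experiments

Oracle-equivalence checks run on 100 random fixtures of up to 500 genes;
k-means++ competitiveness uses 200 seeded runs against an exhaustive dynamic
programming optimum at k ∈ {2, 3}; calibration experiments use 500–1000
simulated null datasets; recovery comparisons use 20 generator seeds at ~200
genes each. These sizes make the whole suite run in well under a minute
while keeping Monte-Carlo error small relative to the asserted tolerances.

## Known limitations

* The random-set t-test's anti-conservativeness under a true null (above) is
  inherited from its definition; a predictive-variance correction would
  change the statistic and is not applied.
* K-means ignores attribute weights (no centroid embedding for attributes).
* TF analysis is promoter-level and per-gene; binding-site coordinates and
  enhancer/intronic sites are out of scope.
* No expression normalization is applied anywhere: inputs are taken as
  comparable, and making them so is the user's responsibility.
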