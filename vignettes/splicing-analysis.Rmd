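---
title: "Junction-based detection and group comparison of alternative splicing events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Junction-based detection and group comparison of alternative splicing events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceratio)
```

## Scope and data model

`spliceratio` analyses alternative splicing from splice-junction read tables
rather than raw alignments: the atomic evidence unit is one intron call per
sample — chromosome, first and last intronic base (1-based), strand, and the
number of uniquely mapped reads spanning it. Multimapped reads are always
discarded; they cannot be attributed to a single splicing choice.
Coordinates follow one convention end to end (GTF exons 1-based closed,
junctions on intronic bases) and are converted only at I/O boundaries (the
BED12 reader shifts the 0-based block coordinates).

A gene's annotation is condensed into a splice graph: nodes are the distinct
annotated exons, edges the introns between consecutive exons of at least one
transcript. Observed junctions are assigned to genes by coordinate
containment within the gene span with strand compatibility (junctions of
unknown strand match on coordinates alone — exact coordinate collisions
across strands are rare enough that the convenience outweighs the risk, and
such matches are visible in the output).

## Operational event definitions

The ten canonical event labels are well established, but their boundaries
are not standardised between tools, so the package fixes explicit,
mutually exclusive operational definitions:

* **ES** — a junction bridging donor *i* to acceptor *k* while an annotated
  inclusion path through exactly **one** annotated exon exists between them.
* **CE** — as ES with an annotated chain of **two or more** consecutive
  skipped exons (the cassette unit). Using the skipped-exon count as the
  sole ES/CE discriminator keeps the two labels disjoint and independent of
  whether the skip junction itself is annotated; tying CE to annotation
  status instead would make every fully annotated single-exon skip a CE and
  leave ES for novel junctions only, which contradicts how annotated
  skipping events are normally reported.
* **A5SS / A3SS** — two junctions sharing exactly one boundary; the shifted
  boundary is the donor (5′) or acceptor (3′) site, named in transcript
  orientation: on the minus strand the donor is the numerically larger
  coordinate side.
* **A5SS&ES / A3SS&ES** — an alt-site pair whose longer junction spans at
  least one complete annotated exon that the shorter path retains, i.e. a
  splice-site shift combined with an exon skip.
* **MXE** — exon pair (B1, B2) with both flanking junction sets present
  (observed or annotated) through a common upstream donor and a common
  downstream acceptor, and **no** junction between B1 and B2.
* **5pMXE / 3pMXE** — mutually exclusive exons that are transcript-initial
  (no annotated junction enters either exon; alternative first exons /
  alternative promoters) or transcript-terminal (no annotated junction
  leaves; alternative last exons). GTF exon records carry no
  polyadenylation sites, so transcript-terminal exons are used as the
  operational proxy for alternative 3′-end choice.
* **IR** — an annotated junction whose intron shows body-read coverage.
  A junction table cannot evidence a retained intron (retention produces
  no junction reads), so IR quantification requires an auxiliary per-intron
  body-count table; the synthetic generator emits one, and for real data
  any coverage counter over intronic intervals produces it. Requesting IR
  without the table is an explicit error rather than a silent skip.

### Disambiguation order

Several definitions can fire on overlapping junction configurations. The
classifier resolves them structurally rather than by a label priority list:

1. Skip events (ES/CE) are found first; every (skip junction, inclusion
   junction) pair of a recognised skip is recorded as a *decomposition pair*.
2. MXE and its 5p/3p variants are detected from exon pairs; the junction
   pairs forming each MXE's two paths are marked *consumed*.
3. Alt-site classification then runs over all remaining junction pairs
   sharing exactly one boundary, skipping decomposition and consumed pairs;
   the `&ES` variant is assigned when a complete annotated exon lies in the
   differing region.

Without step 1, every ES would also surface as a spurious `A3SS&ES`
(its skip junction shares a donor with its first inclusion junction);
without step 2, the two entry junctions of an MXE would surface as an
alt-site pair. The structural order keeps the ten definitions disjoint,
which is what makes the one-event-per-type fixture return exactly ten
events with an identity confusion matrix.

Event deduplication is by (gene, type, alternative region, junction sets);
output order and event ids are deterministic (coordinate-sorted, ties by id).
An event is *known* iff every junction of both forms is annotated.

## Quantification and the group test

Per sample, `AS ratio = as_reads / (as_reads + m_reads)`, undefined when the
denominator is zero (undefined ratios are dropped per sample, never
imputed). The *RASE ratio* is the signed difference of group-mean ratios —
the simplest statistic a 0.2 threshold on a [0, 1] scale can refer to — and
significance uses the classic two-sided pooled-variance Student t-test on
the per-sample replicate ratios (not on pooled counts, which would discard
replicate variability). The joint rule is `|RASE ratio| > 0.2` and
`p < 0.05`, with at least two defined ratios per group.

Numerical edge cases are fixed as follows: when both groups are constant
and equal the test carries no evidence and returns (t = 0, p = 1) with a
warning; constant but unequal groups return signed infinite t with p floored
at the smallest positive double so that p stays in (0, 1]. Events whose
AS + M support falls below 10 reads in any sample (configurable) are
excluded before testing — low-count ratios are too unstable to compare —
and the exclusion count is reported. Raw p at 0.05 is the calling criterion;
a BH-adjusted column is emitted alongside for users who want FDR control,
but it does not enter the significance flag.

Under the null (equal inclusion in both groups, binomial sampling at depth
100, 3 vs 3) the test holds its nominal level: the measured type-I fraction
at p < 0.05 over 2,000 simulated events is within 1.5 percentage points of
5%. With a planted inclusion difference of 0.3 under logit-normal replicate
noise (sd 0.2) the joint rule recovers well above 60% of events while
calling essentially no planted nulls; both figures are locked by seeded
tests.

## Expression layer

FPKM (`counts * 1e9 / (length * total)`) and CPM (`counts * 1e6 / total`)
are computed on a SummarizedExperiment carrying exon-union gene lengths and
per-sample totals (totals default to column sums). The differential caller
is an explicit stand-in for count-model packages: group-mean CPM fold change
with pseudocount 1 (taming zeros), two-sided Welch t on log2(CPM + 1), BH
FDR. It is labelled as such in the documentation and validated purely by
parameter recovery on synthetic data — concordance with a negative-binomial
GLM is a non-goal. Two threshold presets reflect common practice:
fold ≥ 1.5 (or ≤ 0.67) with FDR < 0.05 (the default), and fold ≥ 2 (or
≤ 0.5) with raw p < 0.01. qPCR knockdown checks use the standard 2^−ΔΔCT
formula on replicate-mean CTs against a housekeeping reference.

Enrichment is the upper-tail hypergeometric probability P(X ≥ overlap) with
BH correction across sets; gene sets are user-supplied GMT files because
ontology term contents are database-version-dependent. The universe defaults
to all genes in the expression matrix and is overridable — whether "all
genes" or "expressed genes" is the right universe depends on the capture
biases of the experiment, so both are supported.

## Networks and stratification

Correlations use Pearson by default (Spearman by argument) on
log2(CPM + 1) for expression — variance stabilisation — and raw ratios for
events, which are already bounded. The coexpression screen keeps positive
correlations only (r ≥ 0.6, p < 0.05), matching its use for finding genes
that rise and fall with the anchor; the splicing-factor/event stage
thresholds |r| > 0.7 at p < 0.01, since repression is as informative as
promotion there. Undefined-ratio samples are dropped pairwise; pairs with
fewer than three complete observations or zero variance are untested. Hubs
are ranked by the number of distinct connected events with lexicographic
tie-breaks, so rankings are reproducible.

Stratification takes the top-k and bottom-k samples by anchor CPM
(default k = 25), writes the excluded middle out explicitly, breaks boundary
ties lexicographically with a warning, and refuses all-equal input. The
shipped 50-sample cohort table has no boundary ties; re-stratifying its CPM
column reproduces its printed groups exactly, which the test suite asserts.

## What the generator emulates — and what it does not

The synthetic generator mirrors the module boundaries: it produces junction
tables, not reads, because the pipeline starts at junction tables and
desk-scale testing needs no aligner. Per planted event and replicate it
draws total depth (negative binomial; the default dispersion is infinite,
i.e. Poisson — overdispersion is available by configuration), perturbs the
group inclusion level with logit-normal noise (sd 0.2 by default), draws
inclusion reads binomially and splits each form's reads across its
junctions. Defaults encode the emulated study design: two groups of three
biological replicates, inclusion 0.65 vs 0.35 (a planted change of 0.3),
event depth 100. Expression matrices are Poisson around log-normal baselines
with planted fold changes (20 genes at 4-fold by default), an anchor-driven
coexpression block and weakly anchor-coupled splicing factors; a cohort
variant couples event ratios logistically to splicing-factor expression for
network tests.

Passing tests on these data demonstrate correctness of the statistics and
the classifier's logic, not robustness to everything real data does:
the generator has no alignment artefacts, no multimapping ambiguity, no
positional or GC bias, no correlated null events, and its junction counts
are conditionally independent given the event depth. Real junction tables
also contain junctions from genes absent from the annotation; those are
simply never assigned to a gene and remain visible only in the known/novel
partition.

Determinism: every generator entry point seeds R's RNG (Mersenne-Twister,
inversion sampling) from the configuration seed plus a fixed per-stage
offset, so a configuration reproduces its outputs byte-identically; the
test suite checks file-level identity.

## Problem sizes used by the shipped tests

The suite runs in well under a minute on one CPU: the classifier fixtures
use one gene per event type (10 genes), the null calibration 2,000 events at
3 vs 3 and depth 100, the recovery study 500 shifted plus 500 null events,
oracle comparisons cover all hypergeometric configurations with universes up
to 25 and 1,000 random p-vectors for the BH step-up rule, and the cohort
simulations use 50 samples. These sizes were chosen so each property is
measured with comfortable statistical margin while keeping the default test
run fast.

## Known limitations

* The ES/CE boundary (one vs several skipped exons) and the treatment of a
  multi-exon skip as one cassette unit are declared conventions; other
  tools may count differently.
* 3′-end mutually exclusive variants use transcript-terminal exons as a
  proxy for polyadenylation choice.
* The differential-expression caller is a stand-in; effect sizes for low
  counts are shrunk by the pseudocount and its p-values at n = 3 are
  t-distribution approximations.
* Paired designs, likelihood-based differential splicing (GLM/rMATS-style),
  exitrons, recursive splicing, GFF3 input and BAM-level junction
  extraction are out of scope.
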