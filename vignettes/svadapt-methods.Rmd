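---
title: "Validating structural variants from adaptive sampling runs"
author: "svadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating structural variants from adaptive sampling runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svadapt)
```

## The setting

Nanopore adaptive sampling is an in-silico target enrichment. While a
molecule threads through a pore, its first few hundred bases are compared
in real time against a reference of target regions; a match lets the read
finish (an *accepted*, on-target read), a mismatch ejects the molecule (a
*rejected*, off-target read). The result is a characteristic two-class
read population: long reads (N50 on the order of 10--16 kb) at 20--50x
depth over the targets, and short stubs (N50 ~520--600 bp) covering the
whole genome thinly at roughly 3--6x. Both classes are informative. The
accepted reads carry copy-number and breakpoint evidence over the
targeted rearrangements; the ejected reads form a free, genome-wide
low-pass dataset in which large copy-number variants (CNVs) outside the
targets remain visible.

`svadapt` implements the downstream analysis of such runs for validating
structural variants (SVs): read-fate classification and run statistics,
binned log2-ratio copy-number inference over the targets, a background
CNV scan restricted to ejected reads, clustering of breakpoint-spanning
split reads into junctions, and exhaustive reconstruction of
rearrangement architectures from copy-number segments plus junctions. A
synthetic run generator with planted SVs and exact truth sets backs the
entire test surface; everything below applies identically to real
alignments read from SAM/BAM or the plain-table dialect.

## Read fate and run statistics

A read is off-target **iff** its sequencing-summary `end_reason` equals
`"data_service_unblock_mux_change"` (the ejection signal); any other end
reason, including a completed `signal_positive` read, is on-target. The
partition is total; records with a blank end reason are conservatively
kept as on-target with a logged count. Reads with mean quality strictly
below Q10 are discarded before any analysis; a read at exactly 10.0 is
kept.

Run statistics follow the usual definitions. N50 is the largest length
L such that reads of length >= L contain at least half of all bases.
Per-region depth is aligned bases inside the region over region length,
using all passing reads. *Enrichment* is defined as autosomal on-target
mean depth over genome-wide depth of all passing reads -- not over
ejected-read depth only -- because that is the arithmetic that connects a
~28x target depth and a ~5x genome to an enrichment of ~3--7x.
Sample sex is a configuration input, never inferred; on a male X the
copy-number baseline is 1 instead of 2.

## Copy number over targets

Depth is computed in 500 bp bins tiling each target (mean aligned depth;
alignments clipped at bin edges -- the convention of standard binned
coverage tools). The per-bin log2 ratio is taken against a single
reference level: the length-weighted mean depth over *all* target bins
(male samples: chromosome X bins are excluded from the reference but
still receive ratios against half the autosomal reference). Normalizing
against all targets rather than against a variant's immediate flanks is
the crucial design point: a dip judged only against its flanks cannot be
told apart from two flanking duplications around a normal block, whereas
the absolute level against the external reference resolves it.
`disambiguateDelVsDup()` makes that argument explicit by labelling a
loss at the absolute cut-off "deletion (absolute)" and a neutral-level
block between two gain segments "two flanking duplications". With only
one target region there is no external reference and the annotation says
so.

Zero-depth bins are reported at a log2 floor of -5: unambiguous loss,
without propagating `-Inf` through downstream means.

### Segmentation

Windows of 10 consecutive bins (5 kb by default) are scored by the log2
ratio of their mean depth to the reference and classified as loss
(<= -0.415), gain (>= +0.32) or neutral; ties classify as aberrant.
The cut-offs are symmetric in copy-number space around the diploid
baseline (midpoints toward CN 1.5 and CN 2.5). Adjacent same-status
windows merge, and aberrant runs shorter than 3 windows are suppressed.

Status alone cannot separate distinct copy-number levels that share a
status -- triplicated flanks around a quintuplicated core are all
"gain" -- so each merged run is further split by recursive binary
segmentation on the window means (scaled-CUSUM change point, accepted
when the two sides' means differ by at least `minSplit`). `minSplit`
defaults to 0.4 log2 units: about three standard deviations of a
3-window mean at ~30x with ~10 kb reads, yet safely below 0.585, the
smallest same-status step the method is asked to resolve (CN 4 vs CN 6).
Adjacent segments that round to the same integer copy number re-merge.

Two numerical points matter at this depth. First, depth noise is
*correlated* over roughly a read length (several windows), so a plain
least-squares change point is dragged multiple windows toward a
correlated excursion that happens to sit next to a true step. Each
boundary between different copy-number levels is therefore re-placed by
a local AR(1)-whitened least-squares search with both segment means
pinned to their full-segment estimates; the lag-1 residual correlation
is estimated from the track itself. Second, a segment's level is
summarized as log2 of its mean depth ratio (not the mean of per-bin
log2), which avoids the Jensen bias of averaging logs at low depth.

The integer copy number of a segment is `round(baseline * 2^mean_log2)`
with baseline 2 (autosomes, female X) or 1 (male X), and the reported
status is derived from that estimate, so status and copy number cannot
disagree. A hemizygous male X target at half the autosomal depth is
thus CN 1, *neutral*.

Windowed thresholding at these defaults is deliberately simple (no HMM,
no circular binary segmentation) and has a known cost: on large control
regions it emits occasional short false aberrant segments, empirically
about one 3-window call per 1--2 Mb at 28x with 12 kb reads. For
confirmation of known loci -- the use case here -- this is immaterial;
for genome screening one would raise the window size above the read
length or the minimum segment length.

## Background CNV scan from ejected reads

Only off-target reads enter the background profile: stray accepted reads
aligning outside the targets would otherwise create regions of falsely
high coverage. Depth is computed in 10 kb bins genome-wide; bins
overlapping the exclusion set (target regions, plus any user-supplied
catalogue of common CNVs, centromeres and telomeres) are masked. Each
chromosome's reference level is the mean depth of its unmasked bins --
faithful to the source procedure; a median option exists for robustness
when a large event occupies a sizeable fraction of its own chromosome.
1 Mb windows with at least 50% of their bins unmasked are scored by the
log2 ratio of unmasked mean depth to the chromosome reference, the same
loss/gain cut-offs apply, and consecutive same-direction windows merge
into calls. A heterozygous deletion reports a mean log2 near -1, a
single-copy gain near +0.585, provided the chromosome dwarfs the event
(see "Problem sizes" below).

At ~4--5x the scan resolves events at the megabase scale; it makes no
claim about sub-100 kb events and performs no significance testing --
both out of scope by design.

## Junctions and architectures

Breakpoint evidence comes from split reads: supplementary alignments
give each read several blocks, ordered along the read by query offset.
Every consecutive pair of blocks yields one raw junction observation
joining the 3' reference end of the first block (in read orientation) to
the 5' reference start of the second. A junction side is (contig,
position, orientation) with orientation `tail` when the retained
sequence lies left of the position and `head` when it lies right; sides
are stored in canonical (contig, position) order so junction equality is
well defined and both traversal directions of the same junction
coincide.

Observations whose sides share contigs and orientations and agree within
`tol` (default 50 bp) on both positions cluster by single linkage.
Cluster positions are medians -- robust to soft-clip jitter -- and the
min--max interval of member positions is retained rather than forcing a
single base, since micro-homology or low-complexity sequence can make a
breakpoint genuinely unresolvable at nucleotide resolution. Clusters
with fewer than `min_support` (default 3) distinct reads are dropped;
both defaults are conservative for ~12 kb reads at >= 17x and are
plain arguments, not constants. Typing is standard orientation algebra:
different contigs give `TRA`; on one contig `tail->head` forward is
deletion-like, `head->tail` back is tandem-duplication-like, and equal
orientations are inversion-like.

`verifyBreakpoint()` grades an expected locus: a clustered junction with
sufficient support inside the interval confirms it at nucleotide
resolution -- for translocations a *single* side inside a targeted
interval suffices, which is what makes one-sided targeting work when the
partner breakpoint lies in unmappable repeats; otherwise an overlapping
aberrant copy-number segment gives depth-only support; otherwise the
verdict is not confirmed.

Architecture reconstruction treats a locus as a segment graph: nodes are
its copy-number segments (plus implicit flanking reference anchors),
edges are reference adjacencies and observed junctions, and each node
carries its multiplicity on the derived haplotype (for a heterozygous
event, total copy number minus one). `enumerateArchitectures()` performs
a depth-first enumeration of all anchor-to-anchor walks that consume
each segment exactly its multiplicity times, respecting orientations;
the search is exhaustive under a hard total-multiplicity cap of 20
rather than heuristic, so the *number* of solutions is meaningful: a
unique solution means the evidence pins the architecture, several
solutions reproduce the honest ambiguity that arises when no read spans
the full extent of a repeated block, and zero solutions flag copy-number
and junction evidence that no single haplotype explains.

## The synthetic run generator

`simulateRun()` emits a sequencing summary, alignment segments and a
truth set directly -- no sequence-level simulation or re-mapping, since
every in-scope computation consumes alignments. Its defaults are the
study conditions the package is calibrated to: 28x accepted-read depth
over the targets with N50 12 kb, 5x ejected-read depth genome-wide with
N50 560 bp, 5% of reads failing Q10, and every carrier read overlapping
a planted junction emitted as a split alignment.

Key modelling choices:

* **Read lengths** are log-normal with sdlog 0.9 (the long right tail of
  nanopore length distributions). The mean-log parameter is solved in
  closed form from the target N50: the N50 of a log-normal is the median
  of its length-biased distribution, `exp(mu + sigma^2)`, so
  `mu = log(N50) - sigma^2`. Realized N50s land within a few percent.
* **Placement** is budgeted, not Poisson-counted: within each region of
  constant copy-number multiplier, reads are drawn until their aligned
  bases reach `depth x multiplier x length`, each starting uniformly
  within one read length upstream of the region. Expected coverage is
  flat across the region, mean depth is pinned to configuration, and
  bin-scale noise remains Poisson-like.
* **Copy number** scales local read intensity by `cn / 2` (baseline 1 on
  a male X). Reads are clipped at internal copy-number boundaries --
  a real read crossing a junction is split-aligned there -- so depth
  steps are sharp, as in mapped data.
* **Junction-spanning reads** are carved out of the depth reads rather
  than added: the half on each junction side is an existing alignment
  clipped (or truncated, with a compensation read covering the removed
  interval) at the side position, and the two halves are fused into one
  two-segment read with orientations derived from the junction. Total
  depth therefore stays exactly budgeted; the earlier alternative of
  adding extra spanning reads distorts depth next to every junction. On
  an untargeted translocation partner side, where no accepted reads
  exist, the partner half is synthesized -- one-sided targeting still
  produces spanning alignments on the far side, as in real runs.
* **Heterozygosity** is modelled implicitly: depth multipliers use total
  copy number, and spanning-read counts use the carrier fraction (0.5
  for het). Ejected reads are never split: at ~560 bp they rarely span
  junctions informatively.
* **Quality scores** are truncated normal (mean 14, sd 3): passing reads
  above Q10, a configured fraction below; Q-failing reads appear in the
  summary but have no alignments, exactly as in a pipeline that discards
  them before mapping.

What the generator does *not* emulate -- and what passing tests
therefore do not show about real data: base-level errors and mapping
ambiguity, GC and mappability bias, soft-clip jitter at breakpoints
(junction positions are exact, so clustering tolerance is exercised by
construction rather than by realistic noise), segmental duplications
that defeat unique anchoring, and chimeric or adapter artefacts. The
depth statistics, by contrast, carry realistic Poisson-scale noise with
read-length correlation, which is the regime that actually stresses the
segmentation.

## Problem sizes used in the shipped checks

Scale choices in the tests and the acceptance script are scientific, not
incidental:

* The default toy genome is three contigs of 5, 5 and 3 Mb -- enough for
  every structural property (fate partition, N50 calibration, junction
  recall, architecture fixtures) at desk scale.
* The background-scan level checks use contigs of 60, 50 and 40 Mb with
  the 1 Mb event on a 50 Mb contig. The per-chromosome *mean*
  normalization includes the event itself, biasing the level by
  `log2(ratio / chromosome mean factor)`; only when the chromosome
  dwarfs the event (2% here, as for real chromosomes) is the expected
  loss level -1 within a few hundredths. On the 5 Mb default contigs the
  same deletion reads about -0.85 -- detected, but a biased level, which
  is why the small genome is used for detection fixtures and the large
  one for level checks.
* The complex-rearrangement fixture (copy number 4/6/6/4 with an
  inverted middle) is scored against a 35 Mb control target next to a
  1.2 Mb rearrangement target, mirroring the ~36 Mb target set of a full
  run: the all-targets reference includes the rearranged bins, and only
  a large control keeps that bias (log2 of about 1 + excess/total) inside
  the rounding margin of CN 6.

## Known limitations

Segmentation resolves boundaries to about one window at 28x with ~10 kb
reads; nucleotide resolution always comes from junctions, never from
depth. The background scan inherits the mean-normalization bias on small
chromosomes (use the median option there). No GC or mappability
correction is applied. The architecture search is exact but exponential,
hence the multiplicity cap; loci beyond ~20 segment copies need a
different approach. Balanced translocations leave no depth signature by
construction, so their verification rests entirely on junction support.
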