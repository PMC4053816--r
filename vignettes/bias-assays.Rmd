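---
title: "Measuring coverage and error bias in shotgun sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coverage and error bias in shotgun sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasassay)
```

# The model

Shotgun sequencing is modeled as sampling read start positions from the
genome; unbiased sequencing samples them uniformly, so the coverage of a
single base at mean depth $\mu$ is approximately Poisson($\mu$). All of the
package's coverage statistics are built on **relative coverage**

$$ r(b) = \frac{c(b)}{\mu}, \qquad
   \mu = \frac{\sum_{b \in \text{included}} c(b)}{|\text{included}|}, $$

where $c(b)$ counts read bases aligned to reference base $b$ under the CIGAR
`M`, `=` or `X` operators. Only those operators contribute to coverage:
deletions, reference skips, insertions, clips and pads add nothing. The
normalization makes $\bar r = 1$ over included bases by construction (the
package asserts this to $10^{-9}$), so data sets of different depths are
directly comparable.

Under the Poisson null, a base observed at or below relative coverage $t$
sits $(\mu - t\mu)/\sqrt{\mu}$ standard deviations below the mean
(`poisson_sigma()`). At 20× this is only $\approx 2.2\sigma$ for $t = 0.5$,
but at 198× it exceeds $12\sigma$ for $t = 0.1$: at high depth, ten-fold
undercoverage essentially cannot happen by chance, which is what licenses
reading deeply undercovered intervals as bias (or as sample/reference
differences — see the discovery cascade below).

## The inclusion mask

Statistics are computed over an inclusion mask: contigs selected by policy
(`all`, or a named subset such as the chromosomal/autosomal contigs — mobile
elements, plasmids, mitochondria and sex chromosomes are not equimolar with
the rest of the genome) minus every ambiguous base. Ambiguity means any
character outside `A`, `C`, `G`, `T` after upper-casing; soft-masking case
is deliberately ignored, since repeat-masked sequence is still alignable
sequence. Sliding windows that touch a masked base are dropped whole rather
than partially computed, so a masked base can never leak into any window
statistic.

## Read filter contract

All assays consume alignments through one reader with a fixed contract:
unmapped, secondary, supplementary and duplicate-flagged records are
excluded; MAPQ-0 records are **kept**. The latter matters: aligners place
multi-mapping reads at a random best hit, and those placements are the only
coverage signal available in repetitive or low-complexity contexts — exactly
the contexts the motifs target. Dropping MAPQ-0 reads would manufacture
undercoverage where there is none.

# Motifs

A bias motif is a `window`-base region whose centered `core` satisfies a
composition predicate. The standard set is GC ≤ 10 %, GC ≥ 75 % and
GC ≥ 85 % (window 200, core 100), (AT)$^{15}$ and G|C ≥ 80 % (window 130,
core 30); the generalized set used for filtering in the discovery pipeline
relaxes these to GC ≤ 13 %, GC ≥ 70 %, (AT)$^{10}$ (core 20) and
G|C ≥ 75 %. Three numerical choices deserve note:

* **Integer thresholds.** A core of length $C$ passes GC ≥ t iff
  $\#GC \ge \lceil tC/100 \rceil$ and GC ≤ t iff
  $\#GC \le \lfloor tC/100 \rfloor$. With $C = 100$ and $t = 75$ the bound
  is exactly 75 bases; integer arithmetic avoids any float-equality
  ambiguity at the boundary.
* **AT repeats accept both phases.** `ATAT…` and `TATA…` describe the same
  repeat tract; the predicate requires every core base to be A or T with
  adjacent bases differing, so any interruption (including an ambiguity
  code) disqualifies the core. Pure poly-A is rejected.
* **Extents count full windows.** A motif's genomic extent is the union of
  the full `window`-base windows whose cores qualify, not the cores alone:
  the whole window is the motif. This is the convention under which
  reference-derived extent tables are reported, and it is asserted
  equivalent to an independent brute-force scanner (every window start
  evaluated naively) on randomized sequences in the test suite.

Motif relative coverage is the arithmetic mean of $r(b)$ over the union of
included bases in the motif's intervals, each base once. Because motifs
aggregate thousands of loci, this mean is measurable at depths far below
what per-base statistics need; the `subsample_stability()` assay quantifies
this by repeatedly downsampling to a target depth (default 0.5×) and
reporting the per-motif mean and standard deviation across replicates.

# GC-bias curves and undercoverage tables

The GC-bias curve groups all 100-base sliding windows (step 1) by integer
window GC percent and reports the mean window relative coverage per bin. A
window's value is the mean of its 100 per-base values, so the curve composes
exactly with the per-base statistic; a bin is reportable only when the
genome holds at least `min_windows = 1000` windows of that GC content, which
suppresses bins whose estimate rests on a handful of loci.

Undercoverage tables report the fraction of included bases with $r = 0$
(exact zeros) or $r \le t$ for $t \in \{0.1, 0.25, 0.5\}$. These tail
fractions depend strongly on depth, so cross-platform comparisons first
downsample every data set to a common depth (`downsample_alignments()`,
pair-level: all records sharing a QNAME are kept or dropped together, since
mate coverage is correlated). Technology-mixture experiments
(`mix_experiment()`) compare a 50/50 mixture at matched total depth against
each pure component; complementary biases give a mixture better than both
components, while one-sided biases give an intermediate result.

# Error attribution

Per-base error counting follows fixed CIGAR conventions: a mismatch is an
aligned read base differing from the reference (an `N` call over an
unambiguous reference base is a non-matching call, hence a mismatch); a
deletion increments the counter of each reference base skipped by `D`; an
insertion of length $L$ charges $L$ to the reference base immediately after
the inserted sequence. The "immediately after" rule is undefined at record
edges, so a trailing insertion is charged to the last preceding aligned base
and a leading one to the first aligned base — the nearest aligned base
either way — which conserves total counts under any record splitting.

Error rates are fractions: error counts over mapped bases (coverage) in the
same region. Profiles bin every included base by the GC percent of the
100-base window **centered** on it (bases without a complete, fully included
centered window stay unbinned, and binned plus unbinned numerators must sum
to the genome-wide numerators — a conservation law in the test suite) or by
the length of its containing homopolymer run, capped at 15 so sparse
long-run bins aggregate. GC error bins inherit the 1,000-window
reportability rule of the coverage curve so panels are comparable.
Length-1 runs are kept as runs so homopolymer binning covers every base.

A known limitation: when the sample genuinely differs from the reference,
true variants are counted as errors, inflating rates. Separating variants
from errors is out of scope; the discovery cascade addresses the coverage
side of the same confounder.

# Bad promoters

For each transcription start site, the ratio of mean coverage in the
surrounding 200 bases to the surrounding 3,000 bases is computed; the 1,000
lowest-ratio genes (after keeping, per gene, the lowest-ratio TSS entry)
form the bad-promoter list, emitted as 200-base TSS-centered intervals.
Windows are symmetric about the TSS and strand is ignored for placement
(no strand-aware offset is defined for the assay); window means are taken
over included bases with clipping at contig ends; undefined ratios (zero or
unmeasurable far-window coverage) are excluded before ranking; ties break
lexicographically by gene name so selection is invariant to input order.
The near/far construction makes the score robust to regional depth
variation: it asks whether the immediate vicinity is depressed *relative to
its own neighborhood*.

# The discovery cascade

Uncategorized bias is what remains of the ten-fold-undercovered set
($r \le 0.1$) after removing, in order:

1. **Assembly evidence of sample/reference difference** — reference bases
   under `D` operators of sample-assembly contig alignments (sequence absent
   from the sample), and bases inside any sliding 100-base window of the
   aligned span with more than five alignment errors (mismatches + deleted
   bases + inserted bases), where read alignment would fail for biological
   reasons. The boundary is strict: five errors keep, six exclude. Windows
   slide on reference coordinates of contig-covered sequence; contigs longer
   than 100 kb are split (`split_contigs()`) into near-equal pieces no
   shorter than 50 kb before alignment, matching aligner input limits.
2. **Diverse-population consistency** — bases well covered ($r \ge 0.5$) in
   at least one diverse multi-individual data set yet undercovered
   ($r < 0.1$) in every data set of the focal sample: likely present in the
   population but absent from the sample.
3. **Similarity to known motifs** — the union of the generalized motif scans
   and the bad-promoter list.

The filters are set subtractions, so the surviving interval set is
independent of their order; only the per-base provenance labels (assembly →
diverse → motif, first applied wins) depend on it, and provenance counts sum
exactly to the bases removed. Surviving bases are re-merged into maximal
intervals and annotated with GC fraction and homopolymer N50; the report
carries the total base count, its fraction of the included genome and the
interval N50. N50 is the length-weighted median throughout: the smallest
length $L$ such that elements of length ≥ $L$ account for at least half the
summed length (homopolymer N50 uses run lengths clipped to the interval).
With empty filters the cascade reduces exactly to `undercovered_intervals()`.

# The synthetic-data generator

`sim_config()` / `simulate_reference()` / `simulate_alignments()` generate
the data every assay is validated on. The generator emulates the
*phenomenology* the assays measure, by construction rather than by
mechanism:

* **GC-dependent coverage bias**: fragment starts are sampled with weight
  `coverage_bias(GC)` evaluated on the 100-base window centered on the
  start, matching the assay's window convention. Planted interval weights
  multiply in, thinning every fragment that would overlap the locus
  (promoter-like depressions, uncategorized-bias loci).
* **Context-dependent errors**: per-base mismatch/deletion/insertion rates
  are base rates times optional GC-bin and homopolymer-length multipliers.
* **Ground truth**: reads are emitted *already aligned* (true placements,
  coordinate-sorted SAM) with an event log listing every injected event and
  its attribution position. Tests assert exact, position-level equality
  between `count_errors()` output and the log — there is no aligner in the
  loop, so conservation is exact, not approximate.

Defaults are the package's reference condition, chosen once: a 1 Mb genome
at 50 % GC, 100-base single-end reads at 50× depth, and error rates
(mismatch $3.0\times10^{-3}$, deletion $2.3\times10^{-4}$, insertion
$1.7\times10^{-4}$) typical of a modern short-read instrument. Events are
never injected at the first or last spanned base of a read, so the
edge-attribution rules are exercised by dedicated hand-built records rather
than by chance; consequently recovered indel rates carry a known
$(\ell-2)/\ell$ interior factor at read length $\ell$, which validation
accounts for explicitly.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: platform-specific error spectra (flow-order
effects, quality-correlated errors), PCR duplicates, chimeras, paired-end
insert-size variation (pairs are fixed-length), aligner behavior (mapping
ambiguity, clipping, misplacement), and true sample/reference variation.
The assays are validated as *measurements*; their interpretation on real
data inherits all the caveats of the upstream aligner.

# Statistical design of the validation

Two choices keep the stochastic checks honest:

* **Effective sample size.** Per-base coverage indicators are dependent
  within a read length (neighboring bases share most of their reads), so
  tolerances for genome-fraction statistics use $n_\text{eff} = L/\ell$
  independent draws, not $L$; a raw binomial standard error on $L$ bases
  would be anticonservative by roughly $\sqrt{\ell}$. Similarly, sliding
  windows within (window + read length) of each other are treated as one
  block when estimating the standard error of a GC-bin mean. Error-event
  checks use true binomial standard errors on mapped bases, since events
  are independent given the alignment.
* **Problem sizes.** Validation runs use 1 Mb genomes at 50× (conservation,
  parameter recovery, null behavior), 10× for Poisson-tail checks (the tail
  mass at 50× is unobservably small), and 0.2–0.3 Mb for the discovery and
  mixture fixtures — large enough that every reportable GC bin holds
  thousands of windows and planted effects are separated from noise.

Degenerate inputs are defined rather than fatal where a value can be
meaningfully undefined (empty motif after masking, zero far-window coverage,
fully masked interval → `NA`), and fatal where the computation is
meaningless (zero aligned bases, mask mismatch between combined tracks,
alignment to an unknown contig, downsampling above the available depth).

# Known limitations

* Published motif-extent tables for finished microbial genomes can be
  reproduced only when those multi-megabase references are supplied locally
  (`inst/extdata/references/`); they are not bundled. Whether such tables
  counted full windows or cores is not externally specified; this package's
  full-window convention is documented above and flagged wherever extents
  are compared.
* Reported genome sizes for some finished references imply exclusions beyond
  ambiguous bases that are not specified; the package applies only the
  stated policy (contig selection + ambiguity) and does not guess further.
* The discovery cascade's high-error-window filter slides on reference
  coordinates of the contig alignments; sliding on contig coordinates would
  differ slightly around indels.
* Fragment GC is summarized by the window centered on the fragment *start*;
  real protocols respond to whole-fragment GC. For the assay-validation
  purpose (inject a known function, read it back) the two conventions are
  interchangeable.
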