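---
title: "Methods: virome abundance, annotation, and the Pol I lifestyle marker"
author: "pondvirome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome abundance, annotation, and the Pol I lifestyle marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pondvirome)
```

This vignette describes the models and procedures the package implements,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic-data generators do and do not
emulate.

## The analysis in one paragraph

A shotgun virome survey assembles reads into contigs, predicts ORFs on
them, searches the ORF peptides against annotated protein databases, and
recruits the reads back to the contigs. This package takes over from
there: it turns per-base read depth into coverage, normalizes coverage per
gigabase pair (Gbp) of recruited reads so samples of different sequencing
effort are comparable, assigns each contig a taxon and each ORF a
functional subsystem by the maximum summed bit score over homology hits,
classifies family A DNA polymerase (Pol I) peptides into phage lifestyles
from the residue at reference position 762, and runs the standard
OTU-table computations (core membership, rarefaction, diversity,
Bray–Curtis) on the accompanying 16S data.

## Coverage and Gbp normalization

Coverage of a contig is its **mean per-base depth over all positions,
zeros included**. The zero-inclusive convention is what a samtools-depth
parser naturally produces once omitted positions are zero-filled, and it
makes one identity exact: an ORF whose window is the whole contig has ORF
coverage equal to contig coverage, with no tolerance needed. ORF coverage
is the mean depth inside the ORF's 1-based inclusive start–stop window and
is strand-independent.

Depth comes either from a samtools-depth three-column table
(`read_depth()`, which zero-fills) or directly from a SAM file
(`depth_from_sam()`). Only primary, mapped alignments count, so each
recruited read is counted exactly once; secondary and supplementary
records contribute neither depth nor denominator. Depth at a position is
the number of counted alignments whose reference-consuming CIGAR
operations cover it. Two boundary notes: deletions (`D`) count as covered
while skips (`N`) do not (the coverage semantics of the underlying
GenomicAlignments machinery), and `samtools depth` itself excludes `D` —
the conventions coincide on ungapped alignments, which is all the
simulator emits.

The normalization denominator is the **sum of reference-aligned bases**
of counted alignments, divided by 10^9. Aligned-base counting is the
default rather than full read lengths so that soft-clipped bases cannot
inflate the denominator; `depth_from_sam(..., bases = "read")` switches to
full read lengths for pipelines that prefer the other convention. One
shared Gbp per sample normalizes both contigs and ORFs. The key invariant
— tested, not assumed — is scale invariance: replicating the read set k×
multiplies every depth and the denominator by k and leaves every
normalized abundance unchanged to floating-point precision.

`log2_abundance()` is presentational only (radial abundance plots); its
pseudocount default in examples is small relative to the data and is never
used in any statistic.

## Maximum-sum-bit-score annotation

For taxonomy, every E-value-qualifying, taxid-annotated hit of every ORF
on a contig contributes its bit score to that taxid's sum; the largest sum
wins the contig. Summation is over **all** hits, not best-hit-per-ORF
(a `best_hit_only` flag provides the latter for sensitivity analysis), and
multiple HSPs of the same ORF–subject pair are summed as given. The
E-value cutoff is inclusive and defaults to 1e-3 for subsystem-database
searches. Ties — possible since bit scores are discrete — are broken
toward the numerically smallest taxid and flagged, so runs are
reproducible and tied calls are visible downstream. Subsystem assignment
per ORF follows the same rule with lexicographic tie-breaks.

The viral/non-viral split walks parent links in a user-supplied nodes
table (taxid, parent, rank, name) to a designated viral root; no live
taxonomy service is consulted, which keeps runs offline and reproducible.
Rank rollups sum normalized abundance per ancestor at the requested rank,
report unassigned contigs as an explicit "no known homolog" mass, and
conserve total abundance exactly — a property the tests assert at 1e-9
relative tolerance. Because "percent assigned" can be framed per contig or
per abundance mass, `assignment_summary()` reports both.

For functions, "only viral-associated functions" is ambiguous between
per-hit and per-ORF readings; the default is **strict mode** — recompute
the per-subsystem sums over viral-subject hits only — because it cannot be
contaminated by cellular homologs. Lenient mode (keep the assignment if
any contributing hit is viral) is provided; a per-contig mode (restrict to
viral-assigned contigs) would be a third reading and is intentionally not
the default. The subsystem→category hierarchy is supplied as a two-column
table; tests use a small phage-flavored hierarchy built in code.

## The Pol I lifestyle classifier

The residue at position 762 of the reference polymerase (E. coli
numbering; wildtype Phe) marks phage lifestyle: Phe762 or Tyr762 →
generally virulent, Leu762 → generally temperate, anything else — another
residue, an ambiguity code, a gap — unclassified. A peptide's call is only
meaningful if it spans the region of interest (ROI), reference positions
547–923; spanning is defined as carrying non-gap residues in the alignment
columns of **both endpoints**. The `roi_spec()` constructor validates at
load that the supplied reference really carries Ile547, Phe762 and Asn923,
so a mis-indexed reference fails fast instead of silently shifting every
call.

Candidates are first filtered on hit significance (E ≤ 1e-5, inclusive)
and peptide length (≥ 100 aa, inclusive). Mapping onto reference
coordinates uses **deterministic pairwise semi-global alignment** rather
than a multiple alignment: only reference-coordinate mapping is needed for
the classifier, pairwise alignment is deterministic and unit-testable, and
the ROI-restricted alignment is still exported as FASTA for external tree
building (tree inference itself is out of scope). Scoring is BLOSUM62 with
affine gap penalties 11/1 (the BLASTp defaults), configurable. The
alignment is ends-free in both sequences (overhangs unpenalized), every
reference position occupies exactly one column, and traceback ties are
resolved in a fixed operation order — match/mismatch, then gap-in-query,
then gap-in-reference — so identical inputs always give identical
alignments. The dynamic program is implemented in C++; tests verify its
scores against an independent aligner on hundreds of random peptide pairs
and verify planted substitutions are read back at their planted reference
positions.

One known edge: with pairwise alignment, a residue call adjacent to an
indel can in principle differ from what a joint multiple alignment would
have produced. The classifier flags nothing special here; the gap case
falls into "unclassified" by construction.

## OTU-table operations

- **Shannon diversity is reported in bits** (log base 2): a uniform
  community of S OTUs scores exactly log2(S). Base e is a common
  alternative; check the base before comparing across tools.
- **Rarefaction** subsamples each sample without replacement to an exact
  even depth under a caller-supplied seed, dropping (and naming) samples
  below the depth. Rarefied totals equal the requested depth always.
- **Core membership uses presence (count > 0) on raw counts**, not
  normalized data — normalization can neither create nor destroy presence.
  A group's core is the OTUs present in 100% of its samples; the shared
  core is the intersection across groups; a group's unique core subtracts
  every other group's core.
- The **">1% in at least one sample" display filter** is a strict
  inequality: a row whose maximum is exactly the threshold is dropped.
- **Bray–Curtis** is Σ|a−b| / Σ(a+b) per sample pair; it errors when two
  all-zero samples would make the quantity undefined.
- **Taxonomic collapse** sums counts over a lineage prefix (QIIME-style
  levels, 6 = genus); OTUs unnamed at the requested rank group under their
  deepest named ancestor, and totals are conserved.

CSS or other external normalizations are accepted as pass-through input
tables; the in-package normalization is relative abundance. Ordination,
UniFrac, and hypothesis tests (Tukey, ANOSIM, correlations) are standard
external statistics; this package emits the tidy tables they consume.

## The synthetic-data generators

The generators define the conditions every recovery test runs under; their
defaults are fixed and are not tuning knobs.

**Community** (`community_spec()`): four taxa × five contigs of 5–20 kb
with planted coverages {50, 10, 5, 2} — a Siphoviridae-dominated mixture
(Siphoviridae > Myoviridae > Podoviridae) plus one low-coverage non-viral
taxon. Reads of length 100 are placed uniformly at random, never
overhanging contig ends, so the realized mean depth equals
`n_reads × read_length / contig_length` and matches the planted coverage
up to read-count rounding (well under the 5% recovery tolerance); a tiled
placement is unnecessary because the mean is exact either way, while
uniform placement gives per-position sampling noise. The depth TSV is
computed by direct interval stabbing over the simulated placements —
independent of the SAM reader — so the two input routes cross-validate
each other. Hit tables give each ORF one planted hit and weaker decoy hits
at a fixed bit-score fraction < 1, so the planted taxid's per-contig sum
strictly exceeds every decoy's by construction; decoys carry no subsystem
label because they exist to challenge the taxonomy winner rule only.

**Pol I** (`pola_spec()`): peptides are windows of a surrogate reference
covering the ROI with random flanks; the planted class residue is written
at the site homologous to 762, substitutions land elsewhere at the
mutation rate (anchors excluded), and a designated fraction is truncated
inside the ROI so it cannot span. Defaults plant 17 Phe / 27 Tyr / 184 Leu
with 5% mutation — the class structure a late-season freshwater virome
shows — giving 228 spanning peptides. The surrogate reference is a fixed
seeded random peptide of length 1,000 with I/F/N written at 547/762/923:
it satisfies the anchor contract without shipping any real sequence, and
it is labelled synthetic everywhere it appears.

**OTU table** (`otu_table_spec()`): two filter fractions × three months ×
four replicates = 24 samples; a shared core of 277 OTUs, unique cores of
147 (1 µm) and 152 (0.2 µm), and sporadic OTUs bringing the total to
7,489; per-sample depths uniform in 60,000–100,000, all above the 55,307
rarefaction depth. Counts come from log-normal base abundances times a
planted per-OTU temporal trend, masked so sporadic OTUs are absent from at
least one sample of every group, with one read reserved per core OTU per
sample so core presence holds by construction while sample totals stay
exact.

What the generators do **not** emulate: sequencing error, quality scores,
paired ends, chimeras, uneven read placement from GC or mappability, real
database noise (decoys are clean and strictly weaker), or phylogenetic
signal in the peptides beyond the planted residues. Passing recovery tests
therefore demonstrates that the computations are correct on data matching
their stated assumptions — not that the upstream tools' artifacts are
handled, which is those tools' job.

## Determinism and numerical notes

- Every generator takes its seed from the spec and runs under a local RNG
  scope; global RNG state is never modified, and identical specs produce
  byte-identical files.
- Bit-score sums and coverage means are plain double-precision sums; the
  conservation checks (rollups vs totals) hold to 1e-9 relative or better.
- Alignment scores are sums of integers stored as doubles, so exact
  equality comparisons in the traceback are safe.
- Degenerate inputs error loudly rather than guessing: empty FASTA, empty
  depth profiles, zero-Gbp recruitments, zero-total samples in relative
  abundance, all-zero sample pairs in Bray–Curtis, hits referencing
  unknown ORFs, ORFs outside contig bounds, cycles in the taxonomy table.

## Problem sizes used in the test suite

The suite runs the default community (20 contigs, ~4 Mbp of simulated
recruitment), the default Pol I set (228 peptides against a 1,000-residue
reference), the default OTU table (7,489 × 24), a 1,000-instance taxonomy
oracle comparison, a 200-matrix core-OTU oracle comparison, and 100 random
Pol I funnel checks — sizes chosen so the whole suite completes in a
couple of minutes on one CPU while still exercising every stated tolerance
at the scale it is claimed.

## Known limitations

- SAM text only (no BAM/CRAM input), matching the formats contract.
- The viral test requires the caller to designate viral root taxids; it
  does not ship a taxonomy.
- Strict-mode viral restriction can unassign an ORF whose true function is
  supported only by cellular homologs of a viral gene.
- The per-contig reading of the viral-function filter is documented but
  not implemented as a mode.
- Pairwise (rather than joint) alignment near indels, as noted above.
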