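---
title: "circlong: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circlong: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream 5' splice site back-splices
to an upstream 3' splice site, closing a covalent circle. Short reads can see
the back-splice junction (BSJ) but almost never the full internal structure,
because the exons and forward-splice junctions (FSJs) of a circRNA are shared
with linear transcripts. Rolling-circle amplification (RCA) followed by
nanopore sequencing solves this: each raw read is a tandem concatemer of many
copies of one circRNA template, so a single read carries the complete isoform
several times over, and the redundancy can be spent on error correction.

circlong implements the computational side of that strategy: consensus
calling from tandem-repeat reads, two-copy concatemer spliced mapping,
high-confidence BSJ/FSJ calling, isoform cataloging with FSM/NIC/NNC
classification, gene assignment and naming, and the cross-sample statistics
used downstream (replicate similarity, differential isoform usage,
tissue-stable/specific calls, the specificity index tau, and inverted-Alu
flanking analysis). A ground-truth simulator makes every stage testable at
desk scale.

## Consensus calling

Each raw read is scanned for tandem periodicity by recording the distances
between consecutive occurrences of identical 11-mers. In a concatemer the
same k-mer recurs one template copy apart, so the distance histogram has a
strong mode at the template length; the mode is clustered with a 12 percent
relative tolerance, harmonics (near-integer multiples of a better-supported
period) are suppressed, and each surviving candidate is verified by aligning
two adjacent copies (at most 35 percent edits). A candidate must explain at
least two copies; reads without a verified period are dropped with a reason
code, mirroring the filter to tandem-repeat reads.

The draft copy is the period-length window with the highest density of
period-consistent k-mer votes -- a deliberate "cleanest copy" selection,
since error-dense regions destroy k-mers. Every copy (including partial
terminal copies) is then aligned to the draft with a banded edit-distance
aligner (band `max(16, m/6)` for unit length `m`), and a per-column vote is
taken: the majority base wins, a column is deleted on a strict gap majority,
and an insertion is added on a strict insertion majority. Ties keep the
draft base, which makes the two-copy case deterministic. A second pass
re-aligns all copies against the first-pass consensus. The reported copy
number is the aligned subread span divided by the consensus length, so an
error-free read of k exact copies reports exactly k.

With two copies and symmetric per-base errors no estimator can beat a single
copy at disagreement columns; the measurable gain at copy number 2 comes
from the clean-window draft selection and from the detector declining
low-support reads. From five copies on, majority voting dominates and the
consensus error falls well below the raw-read error.

When one read yields several consensus candidates, the optimal one is chosen
by (copy-number-weighted vote score, subread span, smaller subread start) --
a declared, deterministic ranking.

## Junction calling

A two-copy concatemer of the consensus is mapped with the package's internal
spliced aligner: exact 13-mer anchors against each chromosome and both query
orientations, colinear chaining that admits target gaps up to 50 kb, and an
intron-opening penalty (25) chosen so that a single spurious anchor can
never pay for a fake intron. Chains on the same chromosome that are adjacent
on the query are merged; the back-splice wrap then appears as a negative
target jump between blocks. Terminal blocks shorter than 20 nt are pruned
before boundary refinement, because stray anchors must not drive it. Every
junction boundary is refined exactly: the query split point between adjacent
blocks is chosen to minimize mismatches against both genomic sides. The
aligner is a contract -- query-ordered blocks with target coordinates -- and
is adequate for genomes up to a few megabases; it is not a production
aligner for full mammalian genomes.

Junction correction then snaps each donor/acceptor independently by up to
10 nt to the nearest annotated splice-site pair, else to the nearest
canonical GT-AG (CT-AC on minus); smaller total shifts win and positive
shifts beat negative on ties. Independent per-side shifts matter because a
consensus indel near a junction moves the two alignment boundaries by
different amounts. The circRNA strand is defined by the corrected BSJ motif,
and FSJ correction is constrained to that strand -- without the constraint a
junction can snap to an antisense canonical motif and fabricate a
near-duplicate isoform.

Both template copies must support the same junction set: every FSJ must be
observed twice, except when its twin (one template unit away in the query)
would fall outside the aligned span, and all wrap observations must agree.
A consensus with a high-confidence BSJ is a candidate circRNA; only
candidates whose FSJs are all high-confidence become full-length isoforms.
A BSJ matching a database entry, or with both sites annotated, is
high-confidence when correction succeeded; a BSJ involving a novel site must
additionally show a canonical motif and at least 0.98 alignment identity
within 20 nt of the junction. The 0.98/20 nt and the 10 nt correction
window are declared defaults surfaced as function arguments, as is the
mapping-quality floor (1).

## Catalog and classification

Reads with identical keys (chromosome, strand, BSJ, ordered FSJ chain)
merge into one isoform with per-sample read counts; read count always means
independent supporting reads, never the within-read copy number. BSJ-level
counts over all candidate circRNAs are kept alongside. A BSJ is known if its
exact coordinates appear in any database (correction already normalizes
coordinates, so no fuzzy matching is applied); it is FSM if in a database,
NIC if both sites are annotated, NNC otherwise. The FSJ set is FSM when the
ordered chain is a contiguous sub-chain of some transcript's junction chain
-- contiguous, not merely a subset, because a circRNA's exons are
consecutive in its parent transcript -- NIC when all sites are annotated,
NNC otherwise; single-exon circles are FSM by definition. Gene assignment
ranks strand-consistent genes by shared splice sites, ties assign multiple
genes, zero shared sites falls back to any 1-bp genomic overlap, else NA.
Within a gene, isoforms are named `gene.circRNA.N` by descending median read
count, ties by mean, remaining ties by key, so naming is input-order
invariant.

For alternative-splicing analysis the predominant isoform of each gene is
compared to each other isoform; same-BSJ pairs are decomposed by block-set
comparison into skipped exons, alternative 5'/3' splice sites (boundary
shifts, mirrored by strand) and retained introns (one block contiguously
spanning two blocks of the other isoform plus the intervening intron).

## Statistics

The test kernels are the stock implementations -- `chisq.test` without
continuity correction, two-sided `fisher.test`, `p.adjust("BH")`, `pbinom`
for the one-tailed binomial -- behind the module's functions; the test suite
verifies each against an independent brute-force oracle at 1e-9. Tissue
comparisons follow a two-step design: a gene-level chi-square screen over
isoform read counts (isoforms need at least 2 reads in at least one of the
two tissues; genes need at least two such isoforms), BH-adjusted, with a
gene called differential at FDR <= 0.05 plus an isoform-proportion shift of
at least 0.05; then per-isoform two-sided Fisher tests within flagged genes
at p <= 0.05 and the same 0.05 proportion shift. Tissue-stable isoforms
require a strict within-gene proportion above 0.5 and at least two reads in
every tissue. Tissue-specific calls cover genes detected exclusively in one
tissue, and, for genes failing a cross-tissue homogeneity chi-square at
FDR <= 0.05, isoform-tissue pairs whose proportion beats the overall
proportion by a one-tailed binomial test (BH FDR <= 0.05, proportion
difference >= 0.05, >= 2 reads). The binomial FDR family is global across
selected isoform-tissue pairs by default, with a per-gene option, since the
family is otherwise underdetermined.

Tau is computed directly as `sum(1 - x/max(x))/(n-1)`; zero marks
housekeeping-like uniform expression, one marks single-tissue expression,
and the index is invariant to rescaling. The inverted-Alu classifier reads
element strand as pointing direction: an upstream-flank plus element with a
downstream-flank minus element points toward the circle (convergent),
the mirrored pair points away (divergent), "both" requires at least one
pair of each, within 1000 or 2000 nt windows clipped to chromosome bounds.
Negative-control BSJs pair a downstream 5' site with an upstream 3' site
(same chromosome and strand, back-splice geometry) drawn without replacement
from annotated sites not participating in any observed or known BSJ; the
default is 10,000 pairs.

## The simulator

The simulator is the package's study-condition generator, not a tuning
surface. Defaults: 20 genes of 3-8 exons (60-200 nt exons, 150-400 nt
introns) on one chromosome, 50 isoforms at 10 reads each, a shifted negative
binomial copy number with mean 14.5 truncated at 2 (the distribution shape
is configurable -- nbinom, geometric or fixed -- because only the observed
mean is an established condition), and 8 percent total error split 4/2/2
over substitutions, insertions and deletions, i.i.d. per base. Canonical
dinucleotides are planted on the correct strand at every exon boundary, and
alternative donor/acceptor sites for A5SS/A3SS events are planted 15-45 nt
inside exons -- outside the 10-nt correction window of the true site, so
correction cannot legitimately confuse them. `novel_site_rate` is the
probability that the linear transcript matching a splicing variant is
omitted from the emitted GTF; at zero, every simulated site and pattern is
annotated, which is what makes the all-FSM/FSM invariant testable. Alu-like
300-nt elements are placed in BSJ-flanking windows in configured
orientations, including deliberately non-inverted same-strand pairs that a
correct classifier must ignore.

What the simulator does not emulate: context-dependent nanopore error
profiles (homopolymer bias), chimeric or adapter artifacts, RT overhangs and
ligation chemistry, abundance-dependent coverage, or genomes with repetitive
element sequence. Passing tests therefore demonstrate correctness of the
algorithmic contracts under i.i.d. errors at realistic rates, not
performance on real flow-cell data.

## Numerical choices and degenerate inputs

Sizes were chosen to keep the full test run at desk scale: the end-to-end
recovery test uses 500 reads (about a minute), consensus accuracy strata use
120 reads per copy number for stable medians, kernel oracles use 1000 random
tables each, and the null FDR calibration uses 600 genes. Determinism is
enforced everywhere: fixed seeds, documented tie-breaks (draft base on vote
ties, smaller subread start on score ties, positive shift on correction
ties, lexicographic key order on naming ties). Degenerate inputs have
defined behavior rather than errors where a pipeline must continue: reads
shorter than two minimum periods yield an empty candidate list, unmappable
queries yield no alignment, zero-margin Fisher tables give p = 1, and
similarity of two empty sets and tau of an all-zero vector are errors
because no convention is defensible.

## Known limitations

Very short exons (below about 20 nt) can lose all alignment anchors and
break both-copy concordance for their junctions; affected reads are dropped,
not miscalled. The internal aligner assumes a low-error consensus; raw reads
cannot be mapped directly. BSJ database matching is exact by design, so a
database recorded against a different coordinate normalization must be
lifted before use. The two-copy concordance rule requires the junction set
to be identical between copies; a majority-support variant would rescue a
few more reads at some risk of chimeric calls and is deliberately not
implemented.
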