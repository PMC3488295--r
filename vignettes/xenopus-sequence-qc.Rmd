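---
title: "Auditing expressed-sequence resources: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing expressed-sequence resources: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenqc)
```

## The problem

A model-organism community accumulates gene sequence from three very
different sources: full-insert sequencing of cDNA clones (accurate, and
backed by a physical reagent), consensus sequences from EST contig
assemblies, and gene models computed on an assembled genome. Each source
fails in its own way — clones can be chimeric, frameshifted or truncated;
genome assemblies have gaps that mislead gene-modeling programs into
emitting incomplete or wrong transcripts. Downstream experiments that
depend on exact sequence (morpholino design against the initiator ATG,
promoter work anchored on the 5′ UTR boundary) inherit those errors
silently. `xenqc` implements the audits that make such defects countable:
per-transcript ORF-completeness classification, per-clone QC coding against
reference contigs, assembly gap statistics, and the accounting that turns
clone sets into gene coverage numbers.

## Transcript completeness

### ORF model

`find_longest_orf()` scans the forward strand (gene-model transcripts are
sense-strand; reverse scanning is an explicit flag for raw cDNA input) for
ATG-initiated reading frames. Each candidate extends from its ATG to the
first in-frame stop (TAA/TAG/TGA, included in the reported interval) or,
when no stop is reached, to the last complete codon, with `has_stop =
FALSE`. The longest candidate wins; ties break to the 5′-most start, then
the lowest frame index, so the result is unique and order-independent.
Coordinates are 0-based half-open throughout.

Two deliberate choices:

* **Minimum ORF length, default 90 nt (30 codons).** Random sequence is
  rich in short ATG–stop fragments; without a floor, no transcript would
  ever class as `NO_ORF`. 90 nt is well below almost any real coding
  sequence yet long enough that chance ORFs are rare. It is a parameter,
  not a constant.
* **Ambiguity handling.** A codon containing any non-ACGT character is
  neither a start nor a stop and translates to `X`. Gapped assemblies
  inject N runs into transcripts, and a scanner that refused them would
  fail exactly where the audit is most needed; letting ORFs run through
  ambiguous codons is the conservative option.

### Classification

`classify_completeness()` applies a severity-ordered, mutually exclusive
scheme, so each transcript lands in exactly one category:

1. `HIGH_COPY_REPEAT` — repeat coverage strictly above 0.80 (see below);
   such transcripts are probably not from true protein-coding genes, and
   their ORF structure is irrelevant.
2. `TRUNC_BOTH`, `TRUNC_5`, `TRUNC_3` — a 3′ truncation is an ORF with no
   stop codon (it runs off the transcript end). A 5′ truncation is called
   in one of two modes. In *evidence mode*, a protein-match interval
   starting strictly upstream of the chosen ATG indicates coding sequence
   lost off the 5′ end. When no evidence set is supplied, a *heuristic
   mode* stands in: if the in-frame region upstream of the ATG reaches the
   transcript 5′ end with no in-frame stop and spans at least 30 nt, the
   reading frame plausibly continued upstream of the transcript and the
   call is made, marked `putative`. The 30 nt threshold mirrors the ORF
   floor's reasoning at smaller scale: a shorter open region is
   uninformative because random UTR sequence frequently presents 10–20
   open nucleotides. An in-frame stop upstream positively certifies the
   5′ end as genuinely untranslated and blocks the call.
3. `COMPLETE_*` — which UTRs are present: a 5′ UTR iff the ORF starts
   after position 0, a 3′ UTR iff it ends before the transcript end.
4. `NO_ORF` — no qualifying ORF. The published layout has no such row (its
   inputs all carried ORFs); it is reported as a separate category so
   totals still reconcile.

Whether the repeat rule is applied before or after ORF scanning is not
observable from the tallies alone; the severity ordering here puts repeat
content first, which matches the layout of the published tables and means
a repeat-dominated transcript is never double-reported as truncated.

## Repeat coverage

`repeat_coverage()` defines the contract: local alignments between the
transcript and each library entry, both orientations, keeping hits with
identity ≥ 0.80 over at least 50 nt; overlapping transcript intervals are
merged and coverage is merged bases over transcript length.
`is_high_copy_repeat()` applies the strict `> 0.80` rule — 0.80 exactly is
*not* high-copy.

The aligner is `Biostrings::pairwiseAlignment` (local, affine gaps) under a
substitution matrix over A/C/G/T/N in which N matches nothing, including
itself. A single optimal alignment reports one hit, so tandem or dispersed
repeat copies are recovered by iterated masking: each best hit is replaced
by N (unmatchable) and the pair re-aligned until the best remaining hit
fails the cutoffs. Masking state is kept per library entry, which makes
coverage invariant to library order and to duplicated entries. The identity
and length cutoffs are package defaults surfaced in `repeat_params()`; only
the 80% coverage threshold is part of the published rule.

## Clone QC

`align_to_contig()` produces an optimal local affine-gap alignment (match
+1, mismatch −2, gap open −5, gap extend −1; best orientation kept) with
gapless blocks and indels recovered from the traceback. `classify_clone()`
then applies the code set in fixed precedence:

| code | trigger |
|------|---------|
| `?`    | empty query or more than 50% N — no usable sequence |
| `CHI`  | two mostly disjoint query segments, each ≥ 100 nt at identity ≥ 0.95, aligning best to *different* contigs |
| `FLx`  | best contig non-coding (no annotated ORF, or ORF < 90 nt) |
| `IMM`  | query insertion ≥ 60 nt whose inserted sequence begins `GT` and ends `AG` — a retained intron, detected genome-free from the splice dinucleotides |
| `FS`   | an indel of length ≢ 0 (mod 3) inside the contig ORF |
| `FLsh` | ORF boundaries covered but an in-frame deletion ≥ 60 nt inside the ORF |
| `FLt5` / `FLt3` | the alignment misses the ORF 5′ / 3′ end |
| `FLq`  | ORF fully covered but identity < 0.97 |
| `FL`   | ORF fully covered, identity ≥ 0.97, no defect |

Precedence is total and deterministic (score ties between candidate
contigs break alphabetically), so permuting the candidate list never
changes a call. Each call carries a `rationale` string naming the
triggering evidence, because every threshold above — the 100 nt chimera
segment, the 60 nt intron and deletion floors, the 0.97 full-length
identity band — is an operational default of this package, not a published
constant. `FLq` in particular is operationalised purely as an identity
band. A clone truncated at both ends reports `FLt5`: the code set has no
both-ends code, and 5′ loss is the more damaging defect for
start-codon-anchored applications. Retained-intron detection deliberately
requires no genome: the GT...AG test on the inserted sequence is a proxy
with known false negatives (non-canonical splice sites) that costs nothing
in specificity on this code set.

## Genome gap statistics

Assembly scaffolds encode gaps as N runs between sections of real
sequence. `scaffold_sections()` treats an N run of ≥ 10 nt (configurable)
as a gap and shorter runs as ordinary ambiguous bases, because real
assemblies contain isolated ambiguity calls that are not structural gaps;
with that convention `assembled_bases + gap_bases` always equals the total
residue count, and raising the threshold can only merge sections, never
split them. `mean_intergap_kb()` is the headline arithmetic: assembled
bases over section count, in kb to one decimal. Applied to the packaged
v4.1 assembly totals (≈1.5 Gb in ≈175,000 sections) it gives 8.6 kb —
shorter than a typical multi-exon vertebrate gene locus, which is exactly
why assembly gaps disrupt gene modeling. The statistic is computed from
printed totals, so the N-run convention does not affect it.

## Accounting

`summarize_set()` maps clone accessions to gene ids (many-to-one) and
counts distinct genes with at least one clone; accessions missing from the
map are counted and reported, never dropped. The estimated number of genes
with a full-length cDNA is `distinct_genes × fl_rate`, rounded half away
from zero (4973 × 0.90 = 4475.7 → 4476, matching the published row).
`fl_rate_from_qc()` defines the rate as `FL / (total − ?)`: clones that
never yielded a full-insert sequence are excluded from the denominator
because nothing is known about them. `combine_sets()` sums plates and
wells, deduplicates genes across sets via the shared map, keeps clones
per-set (different physical reagents), and reports the combined
full-length estimate as `NA` — mixing an explicit per-clone analysis with
a sampled rate does not determine a combined value, and publishing one
would imply a precision the inputs lack.

## Submission mining

`parse_flatfile()` is a purpose-built parser for the metadata blocks of
GenBank flatfiles (no installed package exposes REFERENCE/AUTHORS/JOURNAL
structure). The submission date is the `Submitted (DD-MON-YYYY)` date of
the first JOURNAL line carrying one; the last author comes from the first
listed publication reference, falling back to the Direct Submission
reference for records that have never been published — records whose only
reference is the submission itself are still attributable to a lab. Months
are parsed with an explicit table rather than `%b` so results do not
depend on the session locale. Author names are compared exactly after
whitespace trimming: published rankings keep variants like "Destree, O."
and "Destree, O. H." as distinct rows, so folding initials would be
unfaithful to how these tables are actually read. `monthly_counts()`
supports the two published pooling conventions — each record at its own
month, or all records of a cDNA library at the library's earliest month
(EST batches arrive long after the library is made). Conservation holds by
construction: series total + undated count = record count.

## Synthetic data and what the tests show

The generators in `make_transcripts()`, `make_clone_set()`,
`make_scaffolds()` and `make_flatfiles()` produce inputs with exact truth
labels, deterministically per seed (`withr::with_seed`, leaving the
session RNG untouched).

Transcript truth is guaranteed by construction plus rejection sampling:
UTRs are generated ATG-free (occurrences are rewritten without introducing
new ones), complete transcripts carry an in-frame stop in the 5′ UTR so
the open-upstream heuristic cannot fire, and every candidate transcript is
accepted only if a brute-force enumeration of all ATG–stop structures
confirms the designed ORF is the unique longest. The enumerator is a
separate, deliberately naive code path from the production scanner; the
test suite additionally checks the scanner against an independently
written oracle in the test helpers. The transcript-level frameshift defect
is instructive: after a 1 nt deletion the designed frame meets an early
stop, so the mutant presents as a *shorter complete* transcript — a
transcript-level scan cannot see frameshifts, which is precisely why clone
QC aligns against reference contigs instead.

Clone defects are applied at magnitudes strictly beyond the classifier
thresholds (deletions of 90 vs the 60 floor, chimera segments ≥ 150 vs
100, truncations ≥ 30 nt into the ORF). Two generator constraints exist
purely because of alignment realities: indels are placed so both flanking
match runs out-score the affine gap cost (otherwise the optimal local
alignment drops a flank and the clone legitimately presents as truncated),
and retained-intron insertion points avoid G flanks so traceback cannot
slide the gap and strip the GT/AG signature. A `include_boundary` option
emits threshold-exact cases flagged `ambiguous`, exercised but excluded
from recovery scoring.

What passing tests do and do not show: the generators emulate defect
*geometry* (truncation, indel, chimera, repeat content, gap structure),
not sequencing noise, vector contamination, alternative splicing, or
homeolog cross-matches. 100% truth recovery on the unambiguous regime
validates the decision logic and thresholds as internally consistent; on
real data the same thresholds will trade sensitivity against the noise
sources the simulation omits.

Problem sizes in the shipped suite — 1,000 random sequences for the
scanner/oracle equivalence, 216 transcripts and 50 clones for truth
recovery, 100 random assemblies for gap conservation — were chosen as the
smallest sets that exercise every defect class in multiple architectures;
recovery is exact, not statistical, so scale adds little.

## Reports and fixtures

`xen_fixture()` ships the published audit tallies (transcript completeness
for the v4.1 and v7.1 assemblies; clone QC for the Wellcome/Sanger set and
the analysed IMAGE/XGC sample; the clone-set accounting rows; the v4.1
assembly totals). Their internal sums reconcile with the printed totals
(27,653; 43,436; 9,216; 1,920), which the tests assert.
`render_completeness_report()` and `render_qc_report()` emit the published
layouts plus the derived percentages — complete-ORF share (41% for v4.1,
87% for v7.1), failure share (30%), full-length-of-sequenced rate —
rounding to integers for display exactly as those figures are customarily
quoted, while keeping raw fractions in the machine-readable JSON
(`report_json()`), which is the stable interface.

## Known limitations

* The clone QC aligner targets full-insert cDNA vs contig comparisons
  (≤ ~20 kb); it is not a read mapper.
* Chimera detection requires both parent contigs among the candidates and
  mostly disjoint segments; three-way chimeras report the first pair
  found.
* The repeat scanner's iterated masking can, in principle, miss a
  low-identity long hit that overlaps a previously masked better hit;
  with the default cutoffs this did not occur in testing.
* Heuristic 5′-truncation calls are putative by nature — an unusually long
  stop-free 5′ UTR is indistinguishable from truncated coding sequence
  without protein evidence.
* Author-name and accession handling is exact-string; no identity
  disambiguation is attempted.
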