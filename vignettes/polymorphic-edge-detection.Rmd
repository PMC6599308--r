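---
title: "Polymorphic edge detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polymorphic edge detection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

When two homologous sequences are compared base by base, the first
mismatched base is the **polymorphic edge**: for a SNP it is the variant
base itself, for a structural variant (SV) it flanks the breakpoint. `pedr`
implements two callers built on this observation — a reference-free k-mer
comparison of two read sets, and a bidirectional (two-ended) exact-match
alignment against a reference — together with a read-support verification
stage and a planted-mutation simulator that provides ground truth for
end-to-end evaluation.

All heavy set operations (deduplication, counting, table joins, anchor
lookup) are sorted merge-joins, the same primitive as the Unix
`sort`/`uniq`/`join` tool chain. k-mers up to k = 26 are packed two bits
per base into doubles (`4^26 < 2^53`, so the packing is exact), and the
packing preserves lexicographic order, so sorted joins on packed codes are
sorted joins on sequences.

## The sorted unique read set

Every analysis consumes the *sort_uniq* read set
(`sort_unique_reads()`): reads containing any non-ACGT base are dropped
whole, the reverse complement of every surviving read is added, and the
result is deduplicated and sorted byte-lexicographically. Deduplication
suppresses PCR over-amplification (each distinct molecule context counts
once); complement closure makes all downstream counting strand-symmetric,
which is what permits both-strand confirmation of SNP edges. Paired-end
mates are treated as independent single-end reads throughout — no step uses
insert-size or pairing information.

## The k-mer method (reference-free SNP edges)

From each read set, all k-mers (default k = 20) at every read offset are
counted. Each k-mer is split into its (k−1)-mer prefix and last base, giving
the **last-base count table**: per prefix, the counts of following A, C, G
and T — a strand-resolved proxy for allele depth at the base after the
prefix. The target and control tables are joined on the prefix; only
prefixes present in both samples are informative (a prefix containing the
variant itself appears in only one sample and drops out of the join).

Calling, per joined prefix, uses two count thresholds:

* `min_depth` (default 5): a base with at least this count is *present*;
* `max_noise` (default 1): a base with at most this count is *absent*.

A **homozygous** edge requires exactly one present base on each side,
different bases, each absent in the other sample. A **heterozygous** edge
requires one present control base `r`, both `r` and exactly one other base
`a` present in the target, `a` absent in the control, and a target allele
fraction `a/(r+a)` inside the window `[het_low, het_high]` (defaults 0.30
and 0.70, the same window the verification stage uses). Everything else —
ties, several present bases, under-covered controls — yields no call, by
design: ambiguity is left to the verification stage rather than broken by
an arbitrary rule. The defaults suit ~30–100× short-read coverage with
error rates around 0.1–1%; `max_noise` should stay well below the expected
per-k-mer error count ceiling, and `min_depth` well below half the
coverage.

### Both-strand (reciprocal) confirmation

A genuine SNP is seen twice in complement-closed data: once with the left
flank as prefix, and once — on the opposite strand — with the reverse
complement of the *right* flank as prefix. The call object carries only the
left flank, so `reciprocal_confirm()` recovers the right flank by walking
the target last-base table rightward from the call's k-mer, one base at a
time, following the unique present base (up to k steps; the walk stops at
ambiguous prefixes). Two calls are mutual mirrors when one call's
reverse-complemented k-mer occurs inside the other's extension; both are
then flagged `reciprocal`. For an isolated SNP this is exactly the
forward/complementary k-mer pair. For two adjacent substitutions each
strand carries one clean edge (the left edge on the forward strand, the
right edge on the reverse strand) and the walk — which extends through the
*target* allele — still pairs them. Edges whose context is repetitive or
mixed stop the walk early and remain unconfirmed, which is the conservative
outcome.

The k-mer method deliberately reports *edges*, not variant types: an indel
or rearrangement also perturbs last-base patterns, so its junction shows up
as an edge that only the bidirectional method can type and size.

## The bidirectional alignment method

A **reference index** (`build_reference_index()`) holds every k-mer window
of the genome and its reverse complement (recorded at the same
forward-strand start), with any k-mer occurring more than once — across
both strands — removed entirely. Anchoring is therefore exact-match and
unambiguous by construction; there is no mapping-quality model.

For each read, the k-mer starting `margin` bases inside the 5' end and the
k-mer ending `margin` bases before the 3' end are looked up in the index
(default margin 5, because read ends tend to have lower quality; the
margin is configurable). The read is then compared base by base against
the reference *inward from each anchored end*, in the anchor's frame. At
the first mismatch the following 5 bases are compared in register: two or
more further mismatches mark a *gap* edge (the register is broken —
indel/SV territory), at most one marks a *point* mismatch. When the
5-base window is clipped by the read end or a chromosome boundary, at
least two mismatches among the remaining bases are still required for a
gap edge.

Classification follows the anchor geometry:

1. anchors on different chromosomes → translocation (TRL);
2. same chromosome, opposite strands → inversion (INV);
3. same chromosome and strand: let Δ be the reference distance between the
   anchors minus the read distance. Δ > 0 is a deletion of Δ bases,
   Δ < 0 an insertion of |Δ| bases (the inserted sequence is cut from the
   read between the edges); Δ = 0 with point edges yields SNP calls — one
   per directional point edge, so a read spanning two nearby substitutions
   (e.g. the simulator's adjacent pair) contributes to both, and
   coincident edges are emitted once.

Reads with a single anchor (the other end is repetitive, error-struck, or
crosses a junction) contribute SNP edges from the surviving direction
only; they can never support an SV call. Reads whose scan runs outside a
chromosome are dropped.

Coordinate conventions: deletions and insertions are reported at the
reference position of the last matching base on the genome-left side, with
`pos2` the first matching base beyond the junction. With micro-homology at
a junction the first mismatch shifts right by the homology length; the
reported (pos, size) pair still describes the same mutant sequence, so
sizes are exact even when positions slide by a few bases. Inversions and
translocations are reported as the canonicalised pair of edge coordinates
with an orientation code (`>` = the matching block extends left of the
coordinate, `<` = right); canonicalisation makes a read and its reverse
complement produce the identical record, so support counts pool both
orientations.

Identical merged calls are pooled and their support counted in read
*molecules*: a read and the reverse complement that closure added are one
observation, so a single errored molecule cannot manufacture two-read
support from its own mirror image. Calls below `min_support` molecules
(default 2) are dropped before verification.

## Verification

A candidate is confirmed by counting reads that carry its wild-type or
mutant sequence context. For a SNP at position p, every read-length window
covering p is taken from the reference (wild) and with the base substituted
(mutant); the counts are, in control and target, the number of distinct
validation windows found verbatim in the (deduplicated) read set — giving
the quadruple `cw`, `cm`, `tw`, `tm`. Genotypes:

* `M` (homozygous mutation): `cm ≤ 1` and `tw ≤ 1` — at most one
  contaminating context on either side — and at least one mutant-supporting
  target context (`tm ≥ 1`; a call with zero mutant support is vacuous);
* `H` (heterozygous): `cm ≤ 1` and both `tw/(tw+tm)` and `tm/(tw+tm)`
  inside [0.30, 0.70], bounds inclusive;
* `none` otherwise.

When no control sample exists, control reads are sliced from the reference
itself (every odd position, complement-closed), so `cw`/`cm` measure what
the reference alone can explain.

Two implementations of the SNP counting are provided and cross-checked in
the test suite. `method = "join"` materialises every validation window and
joins it against the read set — the literal construction. The default
`method = "mapped"` locates each read once (probing the k-mers at the
read's first and last offsets against the unique-k-mer index, then one full
comparison against the reference): reads equal to a reference window give
the wild counts as interval sums, and reads exactly one substitution away
give the mutant counts as a keyed join. The two routes agree wherever reads
anchor uniquely; in heavily repetitive genomes the mapped route can
undercount (a window whose read matches elsewhere), which is the same
regime where the method's calls are unreliable anyway.

**SV verification** extends the same idea to junctions: mutant windows are
read-length windows over the breakpoint of the reference spliced according
to the call, wild windows are reference windows crossing the 5'-side
breakpoint. Two safeguards matter:

* *Micro-homology:* junction windows whose overlap with one side lies
  within the breakpoint homology are identical to plain reference windows
  — they carry no mutant information and would count wild-type reads as
  mutant support (and, in the control, veto the call via `cm`). Any mutant
  window equal to a breakpoint-side reference window, in either
  orientation, is excluded.
* *Splice refinement:* inversion and translocation edges carry independent
  homology slip on each side, so the two coordinates of one call need not
  describe a consistent splice. Before windows are built, small coordinate
  shifts (up to ±8) are searched for the splice that reproduces the most
  of the call's representative supporting reads.

## The simulator and what passing tests mean

`apply_mutations()` plants, per chromosome: a substitution at every
multiple of `snp_interval` strictly inside the chromosome (10 Mb unscaled),
an adjacent 2 bp substitution pair (recorded as two SNP records), and a
nine-event SV battery — 1/10/100 bp deletions, 1/10/20 bp insertions, a
100 bp inversion, a 100 bp translocation, and a large deletion
(100 kb unscaled) — at nine fixed positions. `scale` divides all positions,
intervals and the large-deletion size, so the identical design runs at
desk scale; the package's end-to-end evaluations use `scale = 100` on
3 × 1.2 Mb random chromosomes. Substituted bases follow a fixed
transversion map (A↔C, G↔T) and inserted bases are the transversion image
of the reference at the insertion point, so the planted genome is
reproducible without a random stream; only read errors consume the seed.

The translocated segment is *cut* from its origin and pasted into the next
chromosome (10 kb before its end). Two consequences are inherent to
cut-and-paste: the origin junction is a genuine deletion signature of the
segment size (the excision scar), and a copy-paste variant would be
undetectable altogether, since the duplicated segment's k-mers would no
longer be genome-unique and the destination junction could not anchor.
The evaluator (`evaluate_calls()`) therefore scores a truth record as
*recovered* only by a correctly-typed call at its breakpoints (sizes exact
for indels, ±5 bp on SV edges), while any call whose breakend falls inside
a planted event's footprint is *attributed* to that event rather than
counted as a false positive: the excision scar, low-support shadow edges
that single-anchored reads emit at junctions, and sequencing errors landing
on or right next to a planted allele all verify as mutations precisely
because the planted event removed the wild-type context there — they are
artifacts of the event, not of the method. Calls away from every planted
footprint count as unmatched, and the error-driven candidates that
sequencing noise creates everywhere else are removed by verification,
because their wild-type context is intact.

Reads are sliced deterministically: 100 bp windows every 2 bp, with the
mate the reverse complement of the window 231 bp downstream, and each base
substituted independently with probability 0.001. This emulates exhaustive,
uniform tiling — real data have stochastic coverage, quality-correlated
errors, indel errors and adapter artifacts, none of which the simulator
models. Passing the end-to-end tests therefore demonstrates the
*algorithmic* claims (exact typing and sizing at unique loci, strand
symmetry, null behaviour, verification logic) but does not calibrate
performance on real libraries. The unique/repetitive stratification uses
exact k-mer occurrence counts over a 200 bp window centred on the mutation
(a surrogate for a single-hit BLAST criterion; boundary cases can differ
from an alignment-based definition).

## Graphical genotype bins

`classify_bins()` reduces two verified homozygous SNP sets to per-bin
labels along the genome (default bin 50,562 bp): a bin is `common` when
shared SNPs exceed 30% of the union, `specific_a`/`specific_b` when SNPs
exist but sharing is at or below the threshold (labelled by the larger
sample, ties to `a`), `empty` otherwise. This is the data behind a
graphical comparison map; plotting is left to the user.

## Known limitations

* Exact-match anchoring cannot place reads whose both end k-mers are
  repetitive or error-struck; detection in repetitive regions is
  accordingly weaker, and SVs with breakpoints inside repeats are missed.
* SVs smaller than the read length but larger than the anchorable flank
  (inversions shorter than ~read length minus two anchor spans, for
  instance) may verify poorly because junction windows cross both
  breakpoints; the simulator's battery avoids this regime only for the
  planted inversion size.
* The k-mer method's scope is one k-mer: clustered polymorphisms closer
  than k interact, and only the edge — not the type or size — of an SV is
  visible.
* A SNP within one read length of a chromosome end has few (possibly zero)
  covering windows with both anchors and may be uncallable.
* Verification counts distinct sequence contexts, not molecules; it is a
  consistency check against the read set, not a genotype likelihood.
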