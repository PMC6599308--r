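# pedr — polymorphic edge detection from short reads

When two homologous DNA sequences are compared base by base, the first
mismatched base is the **polymorphic edge**: for a SNP it is the variant
base itself; for a structural variant it flanks the breakpoint. `pedr`
detects polymorphisms from next-generation sequencing short reads by
locating these edges, for two audiences: reference-free comparison of two
samples (e.g. tumour vs normal, mutant vs wild type), and reference-based
detection of SNPs *and* structural variants (insertions, deletions,
inversions, translocations) from single-end reads — without gapped
alignment, mapping qualities, or paired-end insert models.

## Methods in brief

**k-mer method (reference-free SNPs).** All k-mers (k = 20) of the
deduplicated, reverse-complement-closed, sorted read set ("sort_uniq"
reads) are counted and split into a (k−1)-mer prefix plus last base,
giving per-prefix counts *n*<sub>A</sub>, *n*<sub>C</sub>, *n*<sub>G</sub>,
*n*<sub>T</sub> — a strand-resolved allele-depth proxy for the base
following the prefix. Target and control tables are joined on the prefix;
a homozygous SNP edge shows one present base (count ≥ 5) per sample,
different between samples and absent (count ≤ 1) in the other; a
heterozygous edge shows the control base plus one extra target base at
allele fraction 0.30–0.70. Genuine SNPs are confirmed on both strands
(the forward edge carries the left flank, the complementary edge the
reverse-complemented right flank).

**Bidirectional alignment (SNPs + SVs).** A genome-unique k-mer index
anchors the k-mers sitting `margin` = 5 bases inside each read end; the
read is then compared base by base inward from each end to its two edges.
With reference distance *D*<sub>ref</sub> between anchors and read
distance *D*<sub>read</sub>: Δ = *D*<sub>ref</sub> − *D*<sub>read</sub> > 0
is a deletion of Δ bp, Δ < 0 an insertion; opposite-strand anchors mean an
inversion and different chromosomes a translocation; Δ = 0 with
coinciding point edges is a SNP. A 5-base look-ahead after the first
mismatch separates point mismatches from broken-register (indel) edges.

**Verification.** Every candidate is checked by counting reads that carry
the wild-type vs the mutant sequence context (all read-length windows over
the variant or junction), in target (tw, tm) and control (cw, cm) read
sets; control reads come from a control sample or are sliced from the
reference. Genotype `M` (homozygous) needs cm ≤ 1, tw ≤ 1, tm ≥ 1;
`H` (heterozygous) needs cm ≤ 1 and both target fractions within
0.30–0.70.

**Simulation.** `apply_mutations()` plants a known battery per chromosome
(interval SNPs, an adjacent 2 bp mismatch pair, 1/10/100 bp deletions,
1/10/20 bp insertions, a 100 bp inversion, a 100 bp translocation and a
large deletion), `slice_reads()` tiles 100 bp reads every 2 bp with a
231 bp-offset complementary mate and 0.1% base errors, and
`evaluate_calls()` scores calls against the truth table.

See `vignettes/polymorphic-edge-detection.Rmd` for conventions, parameter
guidance and design notes.

## Worked example

```r
library(pedr)

g   <- random_genome(2, 120000, seed = 202)          # 2 x 120 kb reference
mut <- apply_mutations(g, mutation_scheme(scale = 100))
nrow(mut$truth)                                      # planted events
#> [1] 24

rd   <- slice_reads(mut$genome, read_sim_config(error_rate = 0, seed = 1))
reads <- sort_unique_reads(c(rd$r1, rd$r2))
calls <- call_variants(reads, g)
ver   <- verify_candidates(calls, g, reads)
ver[ver$genotype != "none" & ver$support > 5,
    c("chrom", "pos", "type", "ref", "alt", "size", "support", "tw", "tm", "genotype")]
```

```
     chrom    pos   type    ref                  alt  size support    tw    tm genotype
    <char>  <int> <char> <char>               <char> <int>   <int> <int> <int>   <char>
 1:  chr01  10000    DEL   <NA>                 <NA>     1      52     0    98        M
 2:  chr01  20000    DEL   <NA>                 <NA>    10      51     0    99        M
 3:  chr01  30000    DEL   <NA>                 <NA>   100      51     0    99        M
 4:  chr01  40000    INS   <NA>                    T     1      50     0    98        M
 5:  chr01  50000    INS   <NA>           GGGATAAACG    10      42     1    89        M
 6:  chr01  60000    INS   <NA> CTTTCAAGTCGAGCGTCAAT    20      31     0    79        M
 7:  chr01  70000    INV   <NA>                 <NA>    NA      51     0    99        M
 8:  chr01  70001    INV   <NA>                 <NA>    NA      51     0    99        M
 9:  chr01  80000    DEL   <NA>                 <NA>   100      51     0    99        M
10:  chr01  80001    TRL   <NA>                 <NA>    NA      52     1    98        M
11:  chr01  80100    TRL   <NA>                 <NA>    NA      51     0    99        M
12:  chr01  90000    DEL   <NA>                 <NA>  1000      52     0    98        M
13:  chr01 100000    SNP      T                    G     0     100     0   100        M
14:  chr01 100100    SNP      C                    A     0      79     0     1        M
15:  chr01 100101    SNP      C                    A     0      79     0     1        M
16:  chr02  10000    DEL   <NA>                 <NA>     1      51     0    99        M
 ...
```

Reading the output: each row is one merged, verified call. The planted
deletions and insertions are recovered with their exact sizes (`size`);
`support` is the number of distinct read molecules asserting the call;
`tw`/`tm` count wild-type vs mutant sequence contexts among the target
reads, so a homozygous mutation shows `tw` near 0 and is marked `M`. The
inversion is reported by its two junction-edge records (rows 7-8); the
translocation by its two junctions pairing chr01:80,001/80,100 with the
destination locus on chr02 (rows 10-11), plus its excision scar, the
100 bp deletion at position 80,000 (row 9). Rows 14-15 are the planted
adjacent mismatch pair: each member has exactly one informative mutant
context (`tm = 1`) because every longer window also covers its planted
neighbour. The remaining rows continue through the battery on chr02.

A reference-free comparison of the same reads against a control set:

```r
ctl <- slice_reads(g, read_sim_config(error_rate = 0, seed = 2))
kc  <- kmer_call_snps(reads, sort_unique_reads(c(ctl$r1, ctl$r2)))
table(kc$zygosity, kc$reciprocal)
```

```
      FALSE TRUE
  hom     8   48
```

The 48 reciprocal (both-strand confirmed) homozygous edges are the planted
SNPs plus clean SV junction edges: the k-mer method signals that a
structural variant exists, but only the bidirectional method types and
sizes it.

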