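---
title: "Detecting gene traffic between an amoebal genome and giant viruses"
author: "amoebahgt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene traffic between an amoebal genome and giant viruses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amoebahgt)
```

## The problem

*Acanthamoeba* are free-living phagocytic amoebae that host a menagerie of
amoeba-resisting microorganisms, among them the giant DNA viruses
(pandoraviruses, mimiviruses, marseilleviruses, pithoviruses, Mollivirus).
Long co-residence of viruses and host in the same cytoplasm is suspected to
promote lateral nucleotide-sequence transfer in both directions. Detecting
such transfer from a draft genome is a cascade of mundane but
threshold-laden steps — similarity search, best-hit taxonomy, context
filters, gene trees — and each threshold choice changes the candidate set.
`amoebahgt` packages that cascade as tested, seeded, reusable code, and
pairs it with a synthetic-data generator so that every stage can be
validated against machine-readable truth rather than against an external
database snapshot.

## The candidate cascade

A gene is an HGT candidate when, in order:

1. its best database hit is a giant-virus protein (single-best-hit
   labeling; genes with no passing hit are ORFans);
2. its protein is longer than 100 amino acids;
3. it sits on a scaffold where non-viral ORFs hold a *strict* majority
   (ORFans count as non-viral, ties fail — the conservative reading, since
   the tie case is otherwise undefined);
4. a merged database of its significant hits (e-value < 1e-4, alignment
   length strictly > 100 aa) from an nr-like reference set and from other
   amoebal proteomes is re-searched, and the candidate is classed
   `viral_majority`, `amoebal_majority` or `mixed` by whether > 50% of
   passing re-search hits are viral or amoebal;
5. where homolog sets permit, a gene tree is built and a transfer
   direction inferred (below).

Default similarity thresholds are amino-acid identity >= 30%, e-value
<= 1e-2 and query coverage >= 30%. Coverage is computed on the query
(aligned query span / query length), the common convention when
"coverage of aligned sequences" is otherwise ambiguous; subject coverage is
carried in every hit record for transparency.

## Alignment model

Pairwise search is exact Smith-Waterman with affine gaps (BLOSUM62, gap
open 11, extend 1 — a gap of length *k* costs 11 + *k*), implemented in
C++ with a deterministic traceback (highest-scoring cell at the smallest
row-major position; match preferred over gap states). No heuristic seeding
is used: at desk scale the full dynamic program is fast enough, and
exactness is what lets the test suite pin the aligner to a brute-force
oracle. E-values use the Karlin-Altschul formula `E = K m n exp(-lambda S)`
with the published gapped-BLOSUM62 constants (lambda = 0.267, K = 0.041)
held fixed rather than re-estimated per query: deterministic, adequate for
threshold logic, and linear in database length by construction. Best-hit
ties are broken totally (e-value, then raw score, then subject id) so all
outputs are reproducible. `X` never counts as an identity.

The genome-wide viral-homolog scan emulates a tBLASTn search by aligning
viral proteins against all six frame translations of each scaffold and
reporting the best local alignment per (gene, scaffold, strand, frame) with
plus-strand nucleotide coordinates; there is no frameshift-aware alignment
and no enumeration of secondary alignments within one frame.

## What the synthetic data emulates — and what it does not

`generate_host_genome()` builds multi-scaffold genomes of intron-free,
ATG-initiated, stop-terminated ORFs separated by intergenic spacers drawn
uniformly from 30-300 nt, at a host background GC of 0.583, the amoebal
host value (pandoraviruses sit close by at about 60.6%, which is why GC
alone cannot rule transfers in or out). `implant_transfers()`
plants viral genes by mutating a panel protein at a chosen per-site rate
(uniform replacement by a different residue — filters downstream depend
only on identity fraction, not substitution biology), reverse-translating
with uniform codon choice, and inserting at an intergenic position without
disrupting any existing ORF. Implant GC is deliberately *not* re-tuned, so
a compositional signal survives for `gc_profile()` to see. Every emitted
gene appears in exactly one truth row, with GFF3 1-based inclusive
coordinates shared between annotation and truth table.

Two generator properties are worth stating plainly:

* A stop codon is placed in-frame immediately upstream of every gene (and
  downstream of minus-strand genes), so the deterministic
  longest-ORF-per-stop caller provably recovers every truth ORF at exact
  coordinates. Real genomes give no such guarantee; this is what makes
  implant-recovery a sharp test rather than a fuzzy one.
* The start methionine is protected from mutation so implants stay callable
  ORFs; at divergence *d* the realised substitution rate is therefore
  `d (L-1)/L`, negligible at the simulated lengths.

The generator does **not** emulate introns, codon-usage bias, sequencing or
assembly error, paralogous families, or genuinely ancient transfers.
Passing the recovery suite therefore shows the cascade's logic and
thresholds behave as designed; it does not show that a real draft genome's
headline counts would be reproduced — those depend on database snapshots
and are explicitly out of scope.

For taxonomy tests an amoebozoa reference panel is derived from a subset of
host ORFs at a configurable divergence (`make_amoeba_references()`),
playing the role a related amoeba's proteome plays in a real analysis.
Truth `host` genes are counted as correctly labeled when the pipeline says
`amoebozoa` *or* `ORFan` — a host gene without a surviving relative in the
reference panel is an ORFan by definition.

## Rhizome mosaicism

`fenestrate()` slices a protein into 40-aa windows at 20-aa steps
(`floor((L-40)/20) + 1` fragments); each fragment is classified by the
domain-level category of its best hit (virus / eukaryote / bacteria /
archaea), with the coverage threshold waived because the fragments are
already short (the waiver is recorded in the output attributes). Trailing
residues past the last full window get no extra anchored window — variable
or anchored tail windows would make fragment statistics incomparable
across genes — and proteins shorter than one window yield a single
whole-length fragment. The mosaicism index is distinct classified origins
over classified fragments; it is undefined (NA) when nothing classifies.

## Trees and transfer direction

Distances are Poisson-corrected (`d = -ln(1-p)` on the mismatch fraction
over ungapped column pairs, with `p` clamped at 0.95 to keep saturated
pairs finite). The module consumes pre-aligned, equal-length sequences;
multiple-alignment construction is delegated to external tools because the
synthetic families are generated ungapped and realigning them is not what
this package contributes. Neighbor joining is the classical Q-criterion
agglomeration with two determinism guarantees the usual library routines do
not make: taxa are processed in label order (first minimal Q pair wins) and
negative branch lengths are clamped to zero with the deficit moved to the
sister edge, conserving the joined path length. The standard library
implementation serves as an independent cross-check in the tests, never as
the implementation.

"Most parsimonious transfer scenario" is operationalised as explicit
nesting rules, printed with every call: root at an `other_cellular`
outgroup leaf if present, else at the midpoint; call `virus_to_amoeba` iff
the amoebal leaves (query included) form a clade whose sister is
exclusively viral while the viral leaves are paraphyletic; call
`amoeba_to_virus` for the mirror configuration; everything else —
including reciprocally monophyletic groups, intermixed leaves, or a
missing viral side — is `inconclusive`. The rules are mutually exclusive
by construction. Ancestral sequences use per-column Fitch parsimony with
alphabetical root tie-breaks and gaps treated as missing.

## Synteny

Scaffolds carrying at least 3 viral-best-hit genes seed synteny blocks.
Presence in a target genome uses reciprocal best hits (one-way hits
inflate counts through paralogs); the order score is the longest common
subsequence of block order versus partner order along a single target
scaffold, divided by block size, with a fully reversed run accepted as
collinear because draft scaffolds have arbitrary orientation. Partners
scattered across target scaffolds count toward presence but cap the order
score — mirroring the separate "present" versus "in synteny" questions.
The genome tree shown beside the conservation matrix uses
1 - Jaccard of ortholog-group membership as the distance; this stands in
for whole-genome alignment, which is out of scope.

## Numerical and reporting conventions

* Report percentages are printed as integers at >= 1% and at one decimal
  below 1% for family shares and COG shares, and at one decimal for the
  ratio statements (ORFan share, sharing fraction, overlap share, scan
  share); `share_pct()` centralises this, using R's round-half-even.
* Strict inequalities follow the stated rules everywhere they matter:
  contig size classes ("< 1,000 bp"), re-screen alignment length
  ("> 100 aa"), scaffold-context majority.
* N50 is the contig length at which the descending cumulative sum first
  reaches half the assembly.
* Ambiguous codons translate to `X`; `X` never scores as an identity.

## Problem sizes

The shipped tests and the acceptance script run the full cascade on
genomes of 20 scaffolds x 10 host ORFs (80-250 aa) with 12 implants
against 3 viral panels of 10 proteins plus 4 cellular decoy panels — sizes
chosen so that implant recovery, false-positive rates and threshold
monotonicity are measured on hundreds of genes per replicate while a full
multi-seed sweep stays a desk-scale computation. The aligner oracle uses
500 random pairs of up to 30 residues; neighbor joining is checked on
random 5-8 taxon additive trees.

## A worked example

```{r example, eval = FALSE}
panels <- generate_reference_panels(3, 10, c(200, 40), seed = 1)
genome <- generate_host_genome(20, 10, gc_target = 0.583, seed = 2)
genome <- implant_transfers(genome, panels, n_transfers = 12,
                            divergence = 0.1, seed = 3)
res <- hgt_scan(genome$orfs, panels$proteins, panels$taxonomy)
table(res$labels$category)
#>
#> ORFan virus
#>   200    12
```

All twelve implants surface as viral best hits at divergence 0.1 and no
host-background gene does; the candidate table then carries the length and
scaffold-context flags for the downstream stages.

## Known limitations

Single-best-hit labeling is a documented simplification of
lowest-common-ancestor taxonomy binning; every report header states it.
The Karlin-Altschul constants are fixed, so absolute e-values at real
database scale differ from a heuristic search engine's, and absolute candidate counts from real
draft genomes — which depend on database snapshots and search heuristics —
are not reproduction targets. The ORF
caller is ATG-only and intron-blind by design, honest for the synthetic
genomes it is paired with but not a replacement for a eukaryotic gene
finder on real scaffolds.
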