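---
title: "Methods: how gRNAdesign scores and ranks CRISPR/Cas9 guide candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how gRNAdesign scores and ranks CRISPR/Cas9 guide candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gRNAdesign)
```

## The design model

A Cas9 target is a 23-bp genomic site N20-NGG: a 20-nt protospacer followed
by an NGG PAM. The guide RNA carries the protospacer sequence and directs
cleavage; the pipeline's job is to enumerate every such site in a query
sequence and attach the evidence needed to choose between them. Four factors
are scored, in the order they enter the ranking:

1. **Mapping uniqueness.** The literal 23-mer (PAM included) is mapped to
   the reference genome on both strands allowing at most one mismatch. A
   candidate with exactly one placement is *unique*; additional placements
   are potential off-target sites. Mismatch counting is ungapped Hamming
   distance over all 23 positions, with no special treatment of the PAM at
   the off-target locus — this mirrors mapping the extracted 23-bp sequence
   directly with a mismatch-tolerant short-read aligner, which is the
   behaviour this engine reimplements.
2. **Known variants.** Each candidate's own locus is intersected with a
   user-supplied VCF. A SNP or indel inside the target region means the
   guide may mismatch the allele actually present. Both SNPs and indels
   count toward the total (the `kind` column lets users filter); variants at
   off-target placements are listed per hit but never scored.
3. **Structure sequestration.** The 20-nt guide must base-pair with target
   DNA; guide bases engaged in intramolecular pairs of the gRNA's own
   secondary structure are unavailable for that. The full gRNA
   (guide + scaffold) is folded and the number of *paired* guide positions
   ("sequestered") is the ranking penalty; the complementary unpaired
   ("free") count is reported alongside. The literature describes the
   hazard both as guide bases "in loops" and as bases locked in stems, which
   point in opposite directions; both counts are therefore exposed, and
   ranking uses the sequestered count because pairing is what physically
   blocks DNA hybridization.
4. **AT content.** `at_content()` returns 100·(A+T)/20. High GC (low AT) in
   the guide correlates with stronger off-target hybridization, so among
   otherwise equal candidates the higher-AT one ranks first. No cutoff is
   imposed — the evidence does not support a hard threshold, so AT% is a
   tie-breaking consideration, not a filter.

## Coordinate and strand conventions

All user-facing coordinates are 1-based inclusive on the forward genome
axis, rendered `chrom:start-end(strand)`; a full target region always has
`end − start + 1 = 23`. Strand never changes coordinates — it only selects
whether `fetch()` returns the forward substring or its reverse complement.
Minus-strand candidates discovered as CC-leading windows on the forward
strand are reported in guide orientation (5'→3' of the guide).

IUPAC ambiguity codes are coerced to N at FASTA load time (with a logged
count). N never matches any base: candidate windows containing N are dropped
(they cannot be synthesized), and an N in the genome counts as a mismatch at
verification, so a window with one N and an otherwise exact match is still a
1-mismatch hit at the default budget.

## The off-target search engine

`build_index()` splits the 23-mer into `max_mismatches + 1` contiguous
near-equal parts (12 + 11 at the default budget of 1) and hashes all
overlapping genome k-mers at those part lengths. By pigeonhole, any
placement within the mismatch budget matches at least one part exactly, so
looking up each part's exact occurrences and verifying the full 23-bp window
by Hamming distance is fully sensitive — the nominal 16-bp seed-length
parameter is retained for interface compatibility but sensitivity never
depends on it. Hits are ordered deterministically by (mismatches,
chromosome record order, start, then + before −) and truncated after
`max_hits` (default 10) with an explicit flag; `unique` means exactly one
reported hit with no truncation. Indels at off-target placements are not
modelled (the search is ungapped by design). The self-hit of a
genome-derived candidate is counted, so a perfectly unique guide reports
one place matched.

## Variant distances

The 3'-distance convention: the 3'-terminal base of the 23-bp PAM-inclusive
region is at distance 0 (so on "+" regions `dist = end − pos`, on "−"
regions `dist = pos − start`); for a multi-base reference span the
intersecting base nearest the 3' end is used. A SNP inside a region
therefore has distance in [0, 22], and the "+" and "−" readings of the same
site sum to 22. This is a documented package convention: published reports
print such distances without defining whether the 23-mer or the 20-mer end
is meant, so the PAM-inclusive, 0-counted definition was chosen for being
self-consistent and testable, and is asserted only against this package's
own outputs.

## Folding engine

`fold()` maximizes the number of allowed base pairs (Watson-Crick plus G-U
wobble by default) subject to a minimum hairpin loop of `min_loop = 3`
unpaired bases and no pseudoknots. Among co-optimal structures the traceback
prefers, in order, leaving the left index unpaired, then the pairing partner
with the smallest position — this makes output deterministic and test-stable.
The engine is validated against exhaustive structure enumeration for all
sequences up to length 12; for the 96-nt guide+scaffold fold the DP's pair
list is checked for structural validity instead (enumeration is infeasible
there, which is exactly why the DP exists).

Base-pair maximization is not a thermodynamic model: it over-pairs relative
to an MFE predictor and its loop counts are not comparable to
energy-model outputs. It was chosen to keep the package dependency-free and
fully reproducible; users who need energy-based structures can run any
external folder and hand the dot-bracket string to `import_structure()`,
which validates balance and the loop constraint (errors) and pairing
complementarity (warnings only, since thermodynamic engines may report
non-canonical pairs). The bundled scaffold is the 76-nt S. pyogenes
tracrRNA-fusion sequence in `inst/extdata/sgrna_scaffold.txt`; it is an
editable data file, and `scaffold = ""` folds the bare guide.

## Ranking

`rank_candidates()` applies a stable radix sort over (hits ↑ with unmapped
last, variants ↑, sequestered ↑, AT% ↓, query_start ↑). The first two keys
are the classic sort; the rest are this package's extensions and can be
dropped (`rank_keys = c("hits", "snps")`). Unmapped candidates (possible
when the query is not drawn from the chosen genome) sort after all mapped
ones. With multiple query records the pipeline ranks within each record, so
a batch report has one section per gene with ranks 1..N each.

## What the synthetic fixtures emulate

`make_genome()` draws an i.i.d. background at a configurable GC fraction
(default fixture: 50 kb at GC 0.45, roughly mammalian-like) and implants
chosen 23-mers as exact, 1-mismatch and 2-mismatch copies at non-overlapping
forward-strand positions; it then verifies by brute force (Hamming distance
at every window, via Biostrings) that no accidental placements within one
mismatch exist, regenerating the background otherwise. `make_vcf()` places
SNPs/indels at planned offsets with REF alleles read from the generated
genome. Everything is deterministic given the seed.

The default fixture encodes the three situations that matter for ranking:
a unique target carrying one SNP 2 bp from its 3' end, a target with an
extra 1-mismatch copy (two places matched), and a target whose second copy
differs at two positions and must stay outside the 1-mismatch budget. The
implanted sequences are published human guides (PVALB, AAVS1, VEGFA) with
PAMs appended, so fixture results are directly comparable to the bundled
reference set (`load_reference_set()`, 8 guides whose printed AT% the
package reproduces 8/8).

What i.i.d. backgrounds do **not** emulate: repeat families, segmental
duplications and low-complexity tracts, which dominate real off-target
counts; realistic variant density and linkage; chromosome-scale genome
sizes. Passing fixture tests therefore demonstrates correctness of the
search/annotation/ranking logic, not genome-scale performance
characteristics or realistic off-target rates.

## Numerical and degenerate-input choices

Problem sizes used by the validation suite: the search engine is compared
with a brute-force Hamming scan on 1000 seeded random genomes (mostly 60 bp
to 2 kb, with a tail to 50 kb, both mismatch budgets, including the
reporting-cap contract); the folder on 500 random RNAs of length ≤ 12
against exhaustive enumeration; variant overlap on 1000 randomized
region/variant sets against a naive interval oracle. Degenerate inputs:
queries shorter than 23 bp yield an empty candidate set with a warning (not
an error); an empty VCF body annotates nothing; an empty candidate list
renders a header-only TSV; a pipeline run with zero candidates exits
successfully with a warning. Chromosome names are matched exactly between
genome and VCF unless `normalize_chr = TRUE` strips the "chr" prefix —
silent renaming is never attempted.

## Known limitations

Hamming-only off-target search (no bulges), NGG-only PAM scanning,
non-thermodynamic folding, and no scoring of off-target severity
(position-weighted mismatch models postdate this design and are out of
scope). The per-candidate variant count attributes variants to the
candidate's own locus only; users wanting off-target-locus variants can read
them from the per-hit listing.
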