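# gRNAdesign

Design guide RNAs for the CRISPR/Cas9 system from query gene sequences, with
the annotations a bench scientist needs to choose between candidates:
genome-wide mapping uniqueness, overlapping SNPs/indels, guide bases
sequestered by the gRNA's own secondary structure, and AT content.

## The problem and who this is for

Cas9 is directed to a genomic site by a 20-nt guide sequence (the
protospacer) that must sit immediately 5' of an NGG protospacer-adjacent
motif (PAM); the 23-bp site is written N20-NGG. Many 23-bp windows in a gene
satisfy the pattern, but not all make good guides:

* a guide whose 23-mer maps to more than one genomic place (within one
  mismatch) risks off-target cleavage;
* a known SNP or indel inside the target region means the guide may not
  match the chromosome actually present in the cells;
* guide bases locked into the gRNA's own secondary structure are unavailable
  for DNA pairing, lowering binding efficiency;
* an extremely low AT content (high GC) is associated with stronger
  off-target behaviour, so higher AT is preferred, all else equal.

`gRNAdesign` scans query sequences for all N20-NGG sites on both strands,
maps every candidate 23-mer back to a reference genome allowing at most one
mismatch (a pigeonhole k-mer index with full-window Hamming verification —
the 23-mer is split so that any placement within the budget matches one part
exactly), intersects each candidate's locus with a VCF of known variants
(reporting each variant's distance to the 3', PAM-proximal end of the
23-bp region), folds guide + tracrRNA-fusion scaffold by base-pair
maximization (Nussinov dynamic programming, minimum hairpin loop 3, G-U
wobble allowed) to count paired ("sequestered") and unpaired ("free") guide
bases, computes AT% = 100·(A+T)/20, and ranks candidates by
(mapping hits ↑, overlapping variants ↑, sequestered guide bases ↑, AT% ↓
preferred high, query position) with the classic two-key
(hits, SNPs) ordering available via `rank_keys = c("hits", "snps")`.

## Worked example

Generate a seeded 50-kb toy genome carrying a known unique target with a
SNP 2 bp from its 3' end, then design guides for the gene region around it:

```r
library(gRNAdesign)

spec <- default_fixture_spec(101)
fx   <- make_genome(spec)                      # genome + ground truth
write_fasta(fx$genome, "toy_genome.fa")
writeLines(make_vcf(spec, fx)$vcf_text, "toy_variants.vcf", sep = "")
q <- fixture_queries(fx)
writeLines(c(">my_gene", q$per_implant[["implant1"]]), "my_gene.fa")

res <- run_pipeline("my_gene.fa", "toy_genome.fa",
                    vcf    = "toy_variants.vcf",
                    anchor = q$anchors[["implant1"]],
                    out    = "report.tsv")
```

The top and bottom of the written `report.tsv` (10 candidates):

```
rank query_id query_start strand guide                pam genomic_region      n_hits n_variants variant_details             loop_sequestered loop_free at_percent
1    my_gene  23          +      TCCAGATGATTGGGTGTTCA GGG chr1:47977-47999(+) 1      0                                      13               7         55
2    my_gene  3           -      GGACCACGCGTGTAGTACGT TGG chr1:47957-47979(-) 1      0                                      13               7         40
...
10   my_gene  31          +      ATTGGGTGTTCAGGGCAGAG TGG chr1:47985-48007(+) 1      1          rsFIXPVALB(2 bp to 3' end)  16               4         45
```

Reading row 10: this guide maps to exactly one genomic place (`n_hits` 1 —
unique), but a known SNP sits 2 bp from the 3' end of its 23-bp target
region, 16 of its 20 guide bases are paired inside the predicted gRNA
structure, and its AT content is 45%. SNP-free candidates with fewer
sequestered bases outrank it.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/grna-design.R --query my_gene.fa --genome toy_genome.fa \
    --vcf toy_variants.vcf --anchor chr1:47955-48037 --format html --out report.html
```

Useful pieces individually:

```r
at_content("GGGGCCACTAGGGACAGGAT")   # 35 — a published AAVS1 guide
fold("GGGAAACCC")                    # (((...)))  (3 pairs)
load_reference_set()                 # 8 published human guides w/ metadata
```

## Limitations

The folding engine maximizes base-pair count; it is not a thermodynamic
(Turner-parameter) MFE predictor — import an external dot-bracket structure
with `import_structure()` when energy-based loop counts are required.
Off-target search is ungapped (Hamming) and PAM-agnostic over the literal
23-mer, and alternative PAMs (NAG, ...) are not scanned. The 3'-distance
convention (3'-terminal base of the PAM-inclusive 23-mer at distance 0) is
documented in the methods vignette.
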