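# apescan

Genome scanning for **A-form DNA promoter elements**: promoters where a
transcription factor reads DNA *structure* (indirect read-out) alongside an
ordinary sequence motif (direct read-out). The motivating case is the
*Xenopus* CBTF/ilf3 complex, which activates transcription only where an
A-form element sits near a CCAAT box.

## What it computes

For each base $i$ of a sequence, the **A-DNA propensity energy** (APE,
kcal/mol) is scored from the trinucleotide centred there, summed over both
strands:

    APE(i) = T(b[i-1] b[i] b[i+1]) + T(revcomp(b[i-1] b[i] b[i+1]))

with negative values favouring the A-form helix. Fourteen trinucleotides
carry no energy; positions depending on them are *undetermined* and score
nothing. From the profile, the scanner derives:

* **APS** (A-form promoter sequence): a maximal run of ≥ `apelen`
  consecutive determined, strictly negative APE values, reported with its
  two flanking bases;
* **motif hits**: exact occurrences of each configured motif or its reverse
  complement, overlaps allowed;
* **CPS** (combined promoter sequence): an APS followed by a motif with at
  most `motifgap` bases between the APS span and the motif start, spanning
  APS start to motif end.

Scans run over the `genegap` bases strictly upstream of each gene's TSS
(from FASTA + GFF3), oriented in gene sense, and a seeded Monte-Carlo null
(i.i.d. windows at fixed base composition) estimates how many windows would
contain such elements by compositional chance, giving observed/expected
enrichment. Defaults: `motif = CCAAT`, `apelen = 10`, `motifgap = 20`,
`genegap = 500`.

The packaged trinucleotide table is a clearly-labelled *synthetic
reconstruction* of the qualitative A-philicity structure (G/C blocks
negative, T-substituted C-block starts negative, ATGC repeats weakly
negative, 14 undetermined triplets); real energy tables can be supplied as
a two-column TSV via `load_ape_table()`. See
`vignettes/apescan-methods.Rmd` for the model, conventions and caveats.

## Worked example

Generate a small synthetic genome with one planted CPS upstream of each of
two genes (one per strand), scan it, and compare against a compositional
null:

```r
library(apescan)

spec <- plant_spec(n_genes = 2, directives = "cps",
                   motif = c("CCAAT", "GGGCGG"), gap = c(5L, 3L), seed = 7)
fix  <- make_synthetic_genome(spec)   # writes FASTA + GFF3 + truth table

scan <- scan_genes(fix$genome, fix$genes,
                   table  = make_test_ape_table("gc_negative"),
                   config = scan_config(motifs = c("CCAAT", "GGGCGG")))
scan$results[, c("gene_id", "strand", "tss", "aps_start", "aps_end",
                 "run_length", "motif_start", "matched_text", "gap",
                 "cps_start", "cps_end")]
#>   gene_id strand tss aps_start aps_end run_length motif_start matched_text gap cps_start cps_end
#> 1    g001      + 551        84      97         12         103        CCAAT   5        84     107
#> 2    g002      - 800       964     977         12         955       GGGCGG   3       955     977
```

Each row is one CPS: the APS span (run of 12 negative APE values plus two
flanks, genomic 1-based), the motif it couples to, the gap between them,
and the combined span. For gene `g002` (minus strand) the coordinates are
reflected into genome space; the motif text still reads in gene sense.

```r
res <- run_null(scan_config(motifs = c("CCAAT", "GGGCGG", "AGATA", "TGATA")),
                make_test_ape_table("gc_negative"),
                n_sequences = 20000, n_genes = 2, seed = 42,
                observed_cps_genes = 2)
res
#> Monte-Carlo null: 20000 windows of 500 bp (seed 42)
#>   windows with APS: 615  -> expected 0.061 gene-equivalents
#>   windows with CPS: 81  -> expected 0.008 gene-equivalents
#>   CPS enrichment (observed/expected): 246.9
```

Both planted genes carry a CPS while random composition would explain
roughly 0.008 of them — the planted genome is strongly enriched.

Results export as a tab-separated table (`write_results_tsv()`), GFF3
(`write_gff()`), BED tracks for APS/motif/APE-sign (`write_bed()`), and a
fixedStep WIG of APE scores (`write_wig()`). A command-line front end wraps
the same functions:

```sh
Rscript inst/exec/apescan scan --genome genome.fa --gff3 genes.gff3 \
    --motif CCAAT,GGGCGG --out-prefix out --bed --wig --gff
Rscript inst/exec/apescan null --n 1000000 --seed 1
```

(After installation the launcher lives at
`system.file("exec", "apescan", package = "apescan")`.)

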