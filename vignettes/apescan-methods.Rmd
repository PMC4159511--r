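---
title: "Predicting A-form DNA promoter elements with apescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting A-form DNA promoter elements with apescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

Most transcription factors recognise a base sequence (direct read-out), but
some recognise the three-dimensional structure the DNA adopts (indirect
read-out). A-form DNA — a right-handed duplex with 2.6 Å base rise and about
20° base tilt, against B-form's 3.4 Å and 6° — is one such recognisable
structure: in *Xenopus*, the CBTF complex (containing the double-stranded
RNA-binding protein ilf3) activates the *gata2* promoter only when an A-form
element sits near a CCAAT box. Promoters of this architecture combine a
structural element with an ordinary motif, so finding more of them requires
scanning for both parts jointly. `apescan` implements that scan.

## The scoring model

**APE.** The A-DNA propensity energy of the base at position $i$ depends on
the trinucleotide $b_{i-1} b_i b_{i+1}$. A table $T$ assigns each
trinucleotide a single-strand energy in kcal/mol (negative = A-philic), and
the per-base score sums both strands:

$$\mathrm{APE}(i) \;=\; T(b_{i-1} b_i b_{i+1}) \;+\; T(\mathrm{revcomp}(b_{i-1} b_i b_{i+1}))$$

Summing the forward triplet and its reverse complement makes the profile
strand-symmetric: the profile of $\mathrm{revcomp}(s)$ is the reversal of
the profile of $s$. This is tested exhaustively over the 64 trinucleotides
and on random sequences.

Not every trinucleotide has an energy. Fourteen of the 64 are
*undetermined*: positions whose score depends on one (on either strand)
carry no value at all. The same applies to the first and last position of
any sequence (no complete window) and to any window containing a non-ACGT
base. An undetermined position is `NA`, never silently 0 — this matters
because zeros would otherwise join negative runs.

**APS.** An A-form promoter sequence is a maximal run of consecutive
*determined, strictly negative* APE values of length at least `apelen`,
reported together with the two flanking bases its outermost scores depend
on, so the reported span is `apelen + 2` or longer. Three boundary rules are
deliberate and strict:

* an APE value of exactly 0 terminates a run ("negative" is read literally);
* an undetermined position terminates a run (it contributes nothing);
* only maximal runs are reported — a 15-long run with `apelen = 10` is one
  APS, not six nested ones, matching how whole-genome element counts are
  tallied.

**CPS.** A combined promoter sequence is an APS followed by an occurrence of
a promoter motif (or its reverse complement), with at most `motifgap` bases
strictly between the APS span end and the motif start, the motif lying
strictly downstream of the span. The gap is measured from the span end
(i.e. after the 3′ flanking base) because the flanked APS and the motif are
depicted as disjoint elements; motif/APS overlap semantics are undefined in
the source model, so overlapping placements are not called. Every
qualifying (APS, motif) pair is a distinct CPS, spanning APS span start to
motif end.

## Parameters

| parameter  | default | units | meaning |
|------------|---------|-------|---------|
| `motif`    | CCAAT   | —     | promoter motif(s); each searched with its reverse complement, overlaps allowed |
| `apelen`   | 10      | positions | minimum run of negative APE values; the 12-bp APS span (10 + 2 flanks) is the shortest length for which the A-form structure has been observed reliably |
| `motifgap` | 20      | bp    | maximum APS–motif separation, set by the footprint of the CCAAT-binding complex |
| `genegap`  | 500     | bp    | window strictly 5′ of the TSS that is searched |

All defaults are overridable everywhere (library, CLI). The genome-wide
motif set used for combined scans and for the null model is
{CCAAT, GGGCGG, AGATA, TGATA}.

## The energy table

The engine is value-agnostic: any table in the two-column TSV dialect
(`TRIPLET<TAB>value-or-X`) can be loaded, and all algorithmic guarantees are
tested on synthetic tables. The packaged default
(`extdata/ape_triplet_table_synthetic.tsv`) is a **synthetic
reconstruction**, not the published experimental energies, which this
package does not redistribute. It reproduces the qualitative structure the
published scans imply:

* G/C blocks are A-philic (GGG/CCC strongest, GGC/GCC and CCG/CGG weaker);
* a C-block tolerates a T at its first or second position (TCC/GGA,
  CTC/GAG negative);
* repeated ATGC blocks are weakly A-philic (ATG/CAT, TGC/GCA);
* A/T-rich trinucleotides are B-philic (positive);
* 14 trinucleotides are undetermined: all eight containing a TpA step and
  three reverse-complement pairs containing a CpG step (GCG/CGC, ACG/CGT,
  TCG/CGA).

Because absolute magnitudes and the exact negative set differ from the
original energies, *quantitative* genome-wide or null-model counts obtained
with the packaged table are indicative only; analyses that depend on the
real energies should load them via `load_ape_table()`. Everything that does
not depend on the numeric values — run detection, coupling, coordinates,
track output, enrichment machinery — is unaffected.

## Genome scanning

Genes come from GFF3 (`type == "gene"`, configurable), the TSS is
approximated by the feature's 5′ end, and the searched window is
`[TSS - genegap, TSS - 1]` — strictly 5′, excluding the TSS base, clipped
at contig edges. Transcript-isoform-aware TSS selection is out of scope.
The window is extracted in the gene's 5′→3′ sense; since APE is
strand-symmetric and motifs are searched with their reverse complements,
scanning the oriented strand changes no CPS calls, only the orientation
labels, which are therefore defined relative to the gene sense (a
`forward` CCAAT lies on the coding strand of the downstream gene).
Neighbouring genes' windows are scanned independently even when they
overlap. Hits are mapped back to 1-based genomic coordinates, with
minus-strand coordinates reflected so `start <= end` always holds.

One hit is reported per (position, source motif, orientation); a
palindromic motif is reported once per position, as `forward`.

## The Monte-Carlo null

To ask whether upstream windows carry more elements than their base
composition explains, `run_null()` simulates i.i.d. windows at fixed
A/C/G/T frequencies (for *X. tropicalis*: 0.299733, 0.200318, 0.200317,
0.299632), scans each exactly as a real window, and counts **windows
containing at least one** APS or CPS. The fraction is scaled to the genome's
gene count (18,442) to give expected gene-equivalents, and enrichment is
observed/expected. Windows-with-element counting (rather than total
occurrences) is chosen because the published observed/expected ratios
(~100× for APS, ~50× for CPS) are consistent with per-gene tallies, which
count a gene once however many elements its window holds.

Sequence generation stays in R's seeded RNG (one uniform draw per base, in
window order), so a run is exactly reproducible and a batch of windows is
bit-identical to the same number of successive `random_sequence()` calls.
The per-window scan runs in compiled code for throughput; a test asserts
count-equality of the compiled path against the one-by-one R pipeline on
identically seeded windows, so the fast path never silently diverges from
the reference implementation. The test-suite exercises the null at
10^5 windows and the acceptance script at 10^6; at 10^6 windows the
binomial standard error on an expectation of a few gene-equivalents is
about 0.3.

The null is i.i.d. by design; dinucleotide-preserving shuffles are a
non-goal.

## The synthetic genome generator

`plant_spec()` + `make_synthetic_genome()` build FASTA + GFF3 + an exact
truth table: genes alternate strands along one contig, each upstream window
is background sequence at specified base frequencies, optionally carrying a
planted element — a G-run on the gene-sense strand (so minus-strand genes
exercise reverse-complement placement), for CPS plants followed by an A/T
gap and a motif in either orientation. Backgrounds are rejection-sampled:
a window is regenerated until it contains no unplanned G/C run of `apelen`
or more and no unplanned occurrence of any scan motif within coupling
distance of a qualifying run. This makes the truth table exact under the
`gc_negative` test table (central G or C ⇒ −1, else +1), which is the
reference table for recovery tests because its negative set is exactly the
G/C-centred positions.

What passing recovery tests show: the full pipeline (file I/O, TSS
derivation, orientation, coordinate mapping, run detection, coupling)
returns planted elements at exact genomic coordinates with no spurious
calls in the protected windows. What they do not show: behaviour on real
chromatin-shaped sequence composition (CpG islands, repeats), which the
i.i.d. background does not emulate, nor correctness of any particular
energy table.

## Numerical and degenerate-input choices

* Sequences are case-normalised; all IUPAC codes other than ACGT trigger
  undetermined windows.
* Empty sequences, windows at contig edges, and zero-gene annotations all
  produce empty (not failing) results.
* Ordering is fully deterministic: hits by position then orientation then
  source motif; result rows by seqid, TSS, CPS start. Writers are
  byte-deterministic given identical inputs.
* BED output is 0-based half-open, GFF3 and WIG 1-based; for every interval
  `BED_start = GFF_start - 1` and `BED_end = GFF_end`. WIG uses fixedStep
  blocks broken at undetermined positions rather than sentinel scores,
  which would corrupt browser autoscaling. In the APE-sign BED track a
  value of exactly 0 is labelled `pos`, since APS detection uses strict
  negativity and only `neg` segments matter downstream.
* The oracle-equivalence tests run 500 random sequences (20–300 bp) against
  brute-force interval/sliding-window enumerations; planted-element
  recovery runs 50 random plant specifications. These sizes are the
  package's validation scale and complete in a couple of minutes.

## Known limitations

* The packaged energy table is a qualitative reconstruction (above); its
  absolute null-model expectations inherit that approximation.
* TSS = gene-feature 5′ end; no transcript evidence is used.
* Exact-string motifs only — no position-weight matrices, by design.
* Single-threaded; genome-scale scans stream gene-by-gene but the null
  model is the only compiled hot path.
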