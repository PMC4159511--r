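# Synthetic single-strand trinucleotide A-DNA propensity energies (kcal/mol).
# This is a reconstruction, NOT the published experimental table: the original
# energies are in the literature this scoring scheme derives from and are not
# redistributed here. Sign structure encodes the qualitative behaviour of
# A-philic sequence: G/C blocks strongly A-philic; C-blocks tolerating a T at
# the first or second position; repeated ATGC blocks weakly A-philic; A/T-rich
# sequence B-philic. 14 triplets (all TpA-step triplets and three CpG-step
# complement pairs) carry no value ("X") and are treated as undetermined.
# Per-base APE is the sum over forward and reverse strands: the value for the
# triplet centred on a base plus the value for its reverse complement.
AAA	1.00
AAC	0.55
AAG	0.50
AAT	0.90
ACA	0.60
ACC	0.30
ACG	X
ACT	0.55
AGA	0.45
AGC	0.25
AGG	0.30
AGT	0.55
ATA	X
ATC	0.40
ATG	-0.30
ATT	0.90
CAA	0.65
CAC	0.35
CAG	0.40
CAT	-0.30
CCA	0.35
CCC	-1.00
CCG	-0.60
CCT	0.30
CGA	X
CGC	X
CGG	-0.60
CGT	X
CTA	X
CTC	-0.20
CTG	0.40
CTT	0.50
GAA	0.60
GAC	0.35
GAG	-0.20
GAT	0.40
GCA	-0.35
GCC	-0.80
GCG	X
GCT	0.25
GGA	-0.25
GGC	-0.80
GGG	-1.00
GGT	0.30
GTA	X
GTC	0.35
GTG	0.35
GTT	0.55
TAA	X
TAC	X
TAG	X
TAT	X
TCA	0.50
TCC	-0.25
TCG	X
TCT	0.45
TGA	0.50
TGC	-0.35
TGG	0.35
TGT	0.60
TTA	X
TTC	0.50
TTG	0.65
TTT	1.00
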