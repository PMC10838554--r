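# map_version: 1
# Normalisation map from common GenBank spellings to canonical lower-case
# mitochondrial gene labels. Control regions are mapped to the generic label
# CR and numbered CR1/CR2 by order of appearance when the annotation is built.
alias	canonical	type
ND1	nad1	PCG
ND2	nad2	PCG
ND3	nad3	PCG
ND4	nad4	PCG
ND4L	nad4l	PCG
ND5	nad5	PCG
ND6	nad6	PCG
NAD1	nad1	PCG
NAD2	nad2	PCG
NAD3	nad3	PCG
NAD4	nad4	PCG
NAD4L	nad4l	PCG
NAD5	nad5	PCG
NAD6	nad6	PCG
COX1	cox1	PCG
COX2	cox2	PCG
COX3	cox3	PCG
COI	cox1	PCG
COII	cox2	PCG
COIII	cox3	PCG
CO1	cox1	PCG
CO2	cox2	PCG
CO3	cox3	PCG
ATP6	atp6	PCG
ATP8	atp8	PCG
ATPASE6	atp6	PCG
ATPASE8	atp8	PCG
CYTB	cob	PCG
COB	cob	PCG
CYB	cob	PCG
12S	12S	rRNA
16S	16S	rRNA
RRNS	12S	rRNA
RRNL	16S	rRNA
12S RIBOSOMAL RNA	12S	rRNA
16S RIBOSOMAL RNA	16S	rRNA
S-RRNA	12S	rRNA
L-RRNA	16S	rRNA
D-LOOP	CR	CR
CONTROL REGION	CR	CR
CR	CR	CR
TRNF	trnF	tRNA
TRNV	trnV	tRNA
TRNL1	trnL1	tRNA
TRNL2	trnL2	tRNA
TRNI	trnI	tRNA
TRNQ	trnQ	tRNA
TRNM	trnM	tRNA
TRNW	trnW	tRNA
TRNA	trnA	tRNA
TRNN	trnN	tRNA
TRNC	trnC	tRNA
TRNY	trnY	tRNA
TRNS1	trnS1	tRNA
TRNS2	trnS2	tRNA
TRND	trnD	tRNA
TRNK	trnK	tRNA
TRNG	trnG	tRNA
TRNR	trnR	tRNA
TRNH	trnH	tRNA
TRNT	trnT	tRNA
TRNP	trnP	tRNA
TRNE	trnE	tRNA
TRN-PHE	trnF	tRNA
TRN-VAL	trnV	tRNA
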