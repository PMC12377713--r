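# Synthetic CRAPome-style frequent-flyer contaminant list.
# Constructed, representative default: keratins, serum/media carry-over,
# proteases and other proteins that co-purify in most affinity purifications.
# Replace with a study-specific curated list where available.
# One identifier per line; accessions and gene symbols both match.
KRT1
KRT2
KRT3
KRT4
KRT5
KRT6A
KRT6B
KRT7
KRT8
KRT9
KRT10
KRT12
KRT13
KRT14
KRT15
KRT16
KRT17
KRT18
KRT19
KRT20
KRT23
KRT24
KRT25
KRT27
KRT28
KRT31
KRT32
KRT33A
KRT33B
KRT34
KRT35
KRT36
KRT71
KRT72
KRT73
KRT74
KRT75
KRT76
KRT77
KRT78
KRT79
KRT80
KRT81
KRT82
KRT83
KRT84
KRT85
KRT86
KRTAP1-1
ALB
TF
TTR
A2M
SERPINA1
APOA1
APOB
FGA
FGB
FGG
HBA1
HBB
IGHG1
IGHG2
IGHM
IGKC
TRY1
PRSS1
CTRB1
CELA1
PLEC
DSP
DCD
LYZ
LTF
CSN1S1
CSN2
P04264
P35908
P13645
P35527
P02768
P00761
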