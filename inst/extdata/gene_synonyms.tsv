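synonym	token
# protein-coding genes
cox1	COX1
coxi	COX1
coi	COX1
co1	COX1
cox-1	COX1
cytochromecoxidasesubuniti	COX1
cytochromecoxidasesubunit1	COX1
cox2	COX2
coxii	COX2
coii	COX2
co2	COX2
cox-2	COX2
cytochromecoxidasesubunitii	COX2
cytochromecoxidasesubunit2	COX2
cox3	COX3
coxiii	COX3
coiii	COX3
co3	COX3
cox-3	COX3
cytochromecoxidasesubunitiii	COX3
cytochromecoxidasesubunit3	COX3
nd1	ND1
nad1	ND1
nadh1	ND1
nadhdehydrogenasesubunit1	ND1
nd2	ND2
nad2	ND2
nadh2	ND2
nadhdehydrogenasesubunit2	ND2
nd3	ND3
nad3	ND3
nadh3	ND3
nadhdehydrogenasesubunit3	ND3
nd4	ND4
nad4	ND4
nadh4	ND4
nadhdehydrogenasesubunit4	ND4
nd4l	ND4L
nad4l	ND4L
nadh4l	ND4L
nadhdehydrogenasesubunit4l	ND4L
nd5	ND5
nad5	ND5
nadh5	ND5
nadhdehydrogenasesubunit5	ND5
nd6	ND6
nad6	ND6
nadh6	ND6
nadhdehydrogenasesubunit6	ND6
atp6	ATP6
atpase6	ATP6
atp-6	ATP6
atpsynthasef0subunit6	ATP6
atpsynthasesubunit6	ATP6
atp8	ATP8
atpase8	ATP8
atp-8	ATP8
atpsynthasef0subunit8	ATP8
atpsynthasesubunit8	ATP8
cytb	CYTB
cob	CYTB
cyb	CYTB
cytochromeb	CYTB
# rRNAs
rrnl	rrnL
l-rrna	rrnL
lrrna	rrnL
16s	rrnL
16srrna	rrnL
16sribosomalrna	rrnL
rrn16	rrnL
largesubunitribosomalrna	rrnL
rrns	rrnS
s-rrna	rrnS
srrna	rrnS
12s	rrnS
12srrna	rrnS
12sribosomalrna	rrnS
rrn12	rrnS
smallsubunitribosomalrna	rrnS
# control region
cr	CR
d-loop	CR
dloop	CR
controlregion	CR
putativecontrolregion	CR
at-richregion	CR
a+t-richregion	CR
atrichregion	CR
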