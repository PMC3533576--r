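# Synonym table for canonical_name(). One row per known spelling; labels are
# matched after lower-casing and stripping all non-alphanumeric characters.
# AMBIG_LEU / AMBIG_SER mark labels that need an anticodon to resolve.
label	gene
coi	cox1
co1	cox1
coxi	cox1
cox1	cox1
mtco1	cox1
cytochromecoxidasesubuniti	cox1
cytochromecoxidasesubunit1	cox1
cytochromeoxidasesubuniti	cox1
coii	cox2
co2	cox2
coxii	cox2
cox2	cox2
mtco2	cox2
cytochromecoxidasesubunitii	cox2
cytochromecoxidasesubunit2	cox2
coiii	cox3
co3	cox3
coxiii	cox3
cox3	cox3
mtco3	cox3
cytochromecoxidasesubunitiii	cox3
cytochromecoxidasesubunit3	cox3
cob	cob
cytb	cob
cyb	cob
mtcyb	cob
cytochromeb	cob
atp6	atp6
atpase6	atp6
atpsynthasef0subunit6	atp6
atpasesubunit6	atp6
atp8	atp8
atpase8	atp8
atpsynthasef0subunit8	atp8
atpasesubunit8	atp8
nd1	nad1
nad1	nad1
nadhdehydrogenasesubunit1	nad1
nd2	nad2
nad2	nad2
nadhdehydrogenasesubunit2	nad2
nd3	nad3
nad3	nad3
nadhdehydrogenasesubunit3	nad3
nd4	nad4
nad4	nad4
nadhdehydrogenasesubunit4	nad4
nd4l	nad4L
nad4l	nad4L
nadhdehydrogenasesubunit4l	nad4L
nd5	nad5
nad5	nad5
nadhdehydrogenasesubunit5	nad5
nd6	nad6
nad6	nad6
nadhdehydrogenasesubunit6	nad6
rrnl	rrnL
16s	rrnL
16srrna	rrnL
16sribosomalrna	rrnL
lrrna	rrnL
largesubunitribosomalrna	rrnL
lsurrna	rrnL
rrn16	rrnL
rrns	rrnS
12s	rrnS
12srrna	rrnS
12sribosomalrna	rrnS
srrna	rrnS
smallsubunitribosomalrna	rrnS
ssurrna	rrnS
rrn12	rrnS
cr	CR
dloop	CR
controlregion	CR
putativecontrolregion	CR
atrichregion	CR
atrichr	CR
trnaala	trnA
trnaarg	trnR
trnaasn	trnN
trnaasp	trnD
trnacys	trnC
trnagln	trnQ
trnaglu	trnE
trnagly	trnG
trnahis	trnH
trnaile	trnI
trnalys	trnK
trnamet	trnM
trnaphe	trnF
trnapro	trnP
trnathr	trnT
trnatrp	trnW
trnatyr	trnY
trnaval	trnV
trnaleu	AMBIG_LEU
trnaser	AMBIG_SER
trnaleucun	trnL1
trnaleuuur	trnL2
trnaseragn	trnS1
trnaserucn	trnS2
trnaleutag	trnL1
trnaleuuag	trnL1
trnaleutaa	trnL2
trnaleuuaa	trnL2
trnasertct	trnS1
trnaserucu	trnS1
trnasergct	trnS1
trnasergcu	trnS1
trnasertga	trnS2
trnaseruga	trnS2
l1	trnL1
l2	trnL2
s1	trnS1
s2	trnS2
trnl1	trnL1
trnl2	trnL2
trns1	trnS1
trns2	trnS2
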