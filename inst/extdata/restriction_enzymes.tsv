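name	recognition_site
EcoRI	GAATTC
BamHI	GGATCC
HindIII	AAGCTT
XbaI	TCTAGA
SalI	GTCGAC
PstI	CTGCAG
SphI	GCATGC
KpnI	GGTACC
SacI	GAGCTC
SmaI	CCCGGG
XhoI	CTCGAG
NcoI	CCATGG
NdeI	CATATG
NheI	GCTAGC
SpeI	ACTAGT
BglII	AGATCT
EcoRV	GATATC
ClaI	ATCGAT
MluI	ACGCGT
ApaI	GGGCCC
DraI	TTTAAA
ScaI	AGTACT
StuI	AGGCCT
PvuII	CAGCTG
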