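element	signal	site_id	annotation
CAATBOX1	CAAT	S000028	Seed
ARR1AT	NGATT	S000454	Response regulator
WRKY71OS	TGAC	S000447	GAABAPR proteinsplant defenses
DOFCOREZM	AAAG	S000265	Leafshootcarbon metabolism
WBOXNTERF3	TGACY	S000457	Wound
NODCON2GM	CTCTT	S000462	Nodule
GATABOX	GATA	S000039	Leafshootlightmolecular light switches
IBOXCORE	GATAA	S000199	Leafshootlight regulation
POLLEN1LELAT52	AGAAA	S000245	Pollen
CACTFTPPCA1	YACT	S000449	C4 plantmesophyll
TAAAGSTKST1	TAAAG	S000387	Guard cellK+ influx channel
GT1CONSENSUS	GRWAAW	S000198	LeafshootlightSA
GTGANTG10	GTGA	S000378	Pollen
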