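# Food items detected by trnL metabarcoding in feces of greater white-fronted
# goose (GWFG) and bean goose (BG): assigned read counts and the percentage of
# each group's assigned reads (Fs). Detected items only (n_reads > 0).
group	taxon	rank	n_reads	fs_percent
GWFG	Poaceae spp. (except Poa annua)	family	51705	47.98
GWFG	Poa annua	species	23554	21.86
GWFG	Carex heterolepis	species	18867	17.51
GWFG	Carex spp. (except Carex heterolepis)	genus	9706	9.01
GWFG	Alopecurus aequalis	species	3458	3.21
GWFG	Potentilla chinensis	species	184	0.17
GWFG	Cynodon dactylon	species	155	0.14
GWFG	Polygonum spp.	genus	56	0.05
GWFG	Stellaria media	species	26	0.02
GWFG	Ranunculus chinensis	species	14	0.02
GWFG	Lapsana apogonoides	species	11	0.02
GWFG	Asteraceae sp.	genus	16	0.01
BG	Carex heterolepis	species	81457	99.49
BG	Carex spp. (except Carex heterolepis)	genus	191	0.23
BG	Poa annua	species	167	0.20
BG	Potentilla chinensis	species	65	0.08
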