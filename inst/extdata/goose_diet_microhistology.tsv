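# Food items identified by microhistologic examination of the same fecal
# samples: percentage of identifiable epidermis fragments (Fm) per bird group.
group	taxon	rank	fm_percent
GWFG	Poaceae spp. (except Poa annua)	family	45.68
GWFG	Alopecurus	genus	30.93
GWFG	Carex heterolepis	species	16.39
GWFG	Asteraceae sp.	genus	2.33
GWFG	Carex spp. (except Carex heterolepis)	genus	2.31
GWFG	Potentilla chinensis	species	1.18
GWFG	Fabaceae sp.	genus	0.64
GWFG	Carex thunbergii	species	0.54
BG	Carex heterolepis	species	62.85
BG	Asteraceae sp.	genus	14.55
BG	Alopecurus	genus	13.18
BG	Carex spp. (except Carex heterolepis)	genus	3.49
BG	Carex thunbergii	species	2.79
BG	Potentilla chinensis	species	2.06
BG	Fabaceae sp.	genus	1.08
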