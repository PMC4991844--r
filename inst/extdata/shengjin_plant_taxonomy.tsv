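# Reference taxonomy of the 70 plant morpho-species collected at Shengjin Lake
# for the local trnL barcode library (25 families, 53 genera).
seq_id	family	genus	species
Curculigo_orchioides	Hypoxidaceae	Curculigo	Curculigo orchioides
Artemisia_capillaris	Asteraceae	Artemisia	Artemisia capillaris
Artemisia_selengensis	Asteraceae	Artemisia	Artemisia selengensis
Aster_subulatus	Asteraceae	Aster	Aster subulatus
Bidens_frondosa	Asteraceae	Bidens	Bidens frondosa
Erigeron_annuus	Asteraceae	Erigeron	Erigeron annuus
Gnaphalium_affine	Asteraceae	Gnaphalium	Gnaphalium affine
Hemistepta_lyrata	Asteraceae	Hemistepta	Hemistepta lyrata
Kalimeris_incisa	Asteraceae	Kalimeris	Kalimeris incisa
Bothriospermum_kusnezowii	Boraginaceae	Bothriospermum	Bothriospermum kusnezowii
Lobelia_chinensis	Campanulaceae	Lobelia	Lobelia chinensis
Sagina_japonica	Caryophyllaceae	Sagina	Sagina japonica
Stellaria_media	Caryophyllaceae	Stellaria	Stellaria media
Calystegia_hederacea	Convolvulaceae	Calystegia	Calystegia hederacea
Cardamine_lyrata	Brassicaceae	Cardamine	Cardamine lyrata
Carex_heterolepis	Cyperaceae	Carex	Carex heterolepis
Carex_capricornis	Cyperaceae	Carex	Carex capricornis
Carex_paxii	Cyperaceae	Carex	Carex paxii
Carex_remotiuscula	Cyperaceae	Carex	Carex remotiuscula
Fimbristylis_dichotoma	Cyperaceae	Fimbristylis	Fimbristylis dichotoma
Eleocharis_migoana	Cyperaceae	Eleocharis	Eleocharis migoana
Scripus_karuizawensis	Cyperaceae	Scripus	Scripus karuizawensis
Nymphoides_peltatum	Menyanthaceae	Nymphoides	Nymphoides peltatum
Myriophyllum_spicatum	Haloragaceae	Myriophyllum	Myriophyllum spicatum
Hydrilla_verticillta	Hydrocharitaceae	Hydrilla	Hydrilla verticillta
Hydrocharis_dubia	Hydrocharitaceae	Hydrocharis	Hydrocharis dubia
Vallisineria_spiralis	Hydrocharitaceae	Vallisneria	Vallisneria spiralis
Vallisneria_spinulosa	Hydrocharitaceae	Vallisneria	Vallisneria spinulosa
Juncus_effusus	Juncaceae	Juncus	Juncus effusus
Juncus_gracillimus	Juncaceae	Juncus	Juncus gracillimus
Leonurus_japonicus	Lamiaceae	Leonurus	Leonurus japonicus
Salvia_plebeia	Lamiaceae	Salvia	Salvia plebeia
Glycine_soja	Fabaceae	Glycine	Glycine soja
Vicia_sativa	Fabaceae	Vicia	Vicia sativa
Euryale_ferox	Nymphaeaceae	Euryale	Euryale ferox
Trapella_sinensis	Pedaliaceae	Trapella	Trapella sinensis
Plantago_asiatica	Plantaginaceae	Plantago	Plantago asiatica
Alopecurus_aequalis	Poaceae	Alopecurus	Alopecurus aequalis
Beckmannia_syzigachne	Poaceae	Beckmannia	Beckmannia syzigachne
Bromus_japonicus	Poaceae	Bromus	Bromus japonicus
Cynodon_dactylon	Poaceae	Cynodon	Cynodon dactylon
Phalaris_arundinacea	Poaceae	Phalaris	Phalaris arundinacea
Phragmites_australis	Poaceae	Phragmites	Phragmites australis
Poa_annua	Poaceae	Poa	Poa annua
Polypogon_fugax	Poaceae	Polypogon	Polypogon fugax
Roegneria_kamoji	Poaceae	Roegneria	Roegneria kamoji
Zizania_latifolia	Poaceae	Zizania	Zizania latifolia
Polygonum_lapathifolium	Polygonaceae	Polygonum	Polygonum lapathifolium
Polygonum_orientale	Polygonaceae	Polygonum	Polygonum orientale
Polygonum_perfoliatum	Polygonaceae	Polygonum	Polygonum perfoliatum
Polygonum_persicaria	Polygonaceae	Polygonum	Polygonum persicaria
Rumex_trisetiferus	Polygonaceae	Rumex	Rumex trisetiferus
Potamogeton_crispus	Potamogetonaceae	Potamogeton	Potamogeton crispus
Potamogeton_maackianus	Potamogetonaceae	Potamogeton	Potamogeton maackianus
Potamogeton_malaianus	Potamogetonaceae	Potamogeton	Potamogeton malaianus
Potamogeton_natans	Potamogetonaceae	Potamogeton	Potamogeton natans
Potamogeton_pectinatus	Potamogetonaceae	Potamogeton	Potamogeton pectinatus
Clematis_florida	Ranunculaceae	Clematis	Clematis florida
Ranunculus_chinensis	Ranunculaceae	Ranunculus	Ranunculus chinensis
Ranunculus_sceleratus	Ranunculaceae	Ranunculus	Ranunculus sceleratus
Potentilla_freyniana	Rosaceae	Potentilla	Potentilla freyniana
Gratiola_japonica	Scrophulariaceae	Gratiola	Gratiola japonica
Mazus_miquelii	Scrophulariaceae	Mazus	Mazus miquelii
Veronica_undulata	Scrophulariaceae	Veronica	Veronica undulata
Trapa_bispinosa	Trapaceae	Trapa	Trapa bispinosa
Trapa_maximowiczii	Trapaceae	Trapa	Trapa maximowiczii
Trapa_pseudoincisa	Trapaceae	Trapa	Trapa pseudoincisa
Trapa_quadrispinosa	Trapaceae	Trapa	Trapa quadrispinosa
Hydrocotyle_sibthorpioides	Umbelliferae	Hydrocotyle	Hydrocotyle sibthorpioides
Torilis_japonica	Umbelliferae	Torilis	Torilis japonica
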