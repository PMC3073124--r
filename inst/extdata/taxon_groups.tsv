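taxon	group
Berthella_canariensis	outgroup_root
Actinocyclus_verrucosus	doridina
Bathydoris_hodgsoni	doridina
Calycidoris_guentheri	doridina
Diaphorodoris_luteocincta	doridina
Marionia_echinomuriceae	tritoniidae
Tritonia_bollandi	tritoniidae
Tritonia_hombergi	tritoniidae
Dirona_picta	arminina_other
Hero_formosa	arminina_other
Heterodoris_antipodes	arminina_other
Heterodoris_robusta	arminina_other
Madrella_sanguinea	arminina_other
Pinufius_rebus	arminina_other
Bonisa_nakaza	proctonotidae
Caldukia_affinis	proctonotidae
Caldukia_albolineata	proctonotidae
Caldukia_rubiginosa	proctonotidae
Galeojanolus_ionnae	proctonotidae
Janolus_australis	proctonotidae
Janolus_capensis	proctonotidae
Janolus_hyalinus	proctonotidae
Janolus_longidentatus	proctonotidae
Armina_aoteana	armina
Armina_bayeri	armina
Armina_californica	armina
Armina_comta	armina
Armina_cordellensis	armina
Armina_elongata	armina
Armina_gilchristi	armina
Armina_joia	armina
Armina_juliana	armina
Armina_loveni	armina
Armina_maculata	armina
Armina_magna	armina
Armina_mulleri	armina
Armina_neapolitana	armina
Armina_papillata	armina
Armina_paucifoliata	armina
Armina_punctulata	armina
Armina_variolosa	armina
Armina_xandra	armina
Dermatobranchus_albopunctulatus	dermatobranchus
Dermatobranchus_albus	dermatobranchus
Dermatobranchus_fortunatus	dermatobranchus
Dermatobranchus_gonatophorus	dermatobranchus
Dermatobranchus_marginlatus	dermatobranchus
Dermatobranchus_multistriatus	dermatobranchus
Dermatobranchus_nigropunctatus	dermatobranchus
Dermatobranchus_ornatus	dermatobranchus
Dermatobranchus_otome	dermatobranchus
Dermatobranchus_pulcherrimus	dermatobranchus
Dermatobranchus_pustulosus	dermatobranchus
Dermatobranchus_rubidus	dermatobranchus
Dermatobranchus_semistriatus	dermatobranchus
Dermatobranchus_striatus	dermatobranchus
Dermatobranchus_tongashanensis	dermatobranchus
Dermatobranchus_albineus	dermatobranchus
Dermatobranchus_arminus	dermatobranchus
Dermatobranchus_caeruleomaculatus	dermatobranchus
Dermatobranchus_caesitius	dermatobranchus
Dermatobranchus_cymatilis	dermatobranchus
Dermatobranchus_dendronephthyphagus	dermatobranchus
Dermatobranchus_diagonalis	dermatobranchus
Dermatobranchus_earlei	dermatobranchus
Dermatobranchus_fasciatus	dermatobranchus
Dermatobranchus_funiculus	dermatobranchus
Dermatobranchus_kalyptos	dermatobranchus
Dermatobranchus_kokonas	dermatobranchus
Dermatobranchus_leoni	dermatobranchus
Dermatobranchus_microphallus	dermatobranchus
Dermatobranchus_oculus	dermatobranchus
Dermatobranchus_phyllodes	dermatobranchus
Dermatobranchus_piperoides	dermatobranchus
Dermatobranchus_semilunus	dermatobranchus
Dermatobranchus_rodmani	dermatobranchus
Dermatobranchus_tuberculatus	dermatobranchus
Histiomena_marginata	histiomena
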