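species_code	species_name	family	shape	size_category	aperture_min	aperture_max	source
AC	Abies concolor	Pinaceae	saccate	large	1	1	Bonapol
AG	Alnus glutinosa	Betulaceae	oblate	medium	5	5	Bonapol
BN	Brassica napus	Brassicaceae	prolate	medium	3	3	Bonapol
CA	Chenopodium album	Amaranthaceae	spheroidal	medium	25	NA	Bonapol
CS	Cupressus sempervirens	Cupressaceae	spheroidal	medium	0	0	Bonapol
DG	Dactylis glomerata	Poaceae	spheroidal	medium	1	1	Hand collected, Giessen, Germany
Pic	Picea sp.	Pinaceae	saccate	large	1	1	Hand collected, Giessen, Germany
PL	Plantago lanceolata	Plantaginaceae	spheroidal	small	9	15	Hand collected, Aschaffenburg, Germany
Pop	Populus sp.	Salicaceae	spheroidal	medium	0	0	Hand collected, Aschaffenburg, Germany
RA	Rumex acetosella	Polygonaceae	spheroidal	small	3	3	Bonapol
SC	Salix caprea	Salicaceae	spheroidal	small	3	3	Bonapol
TB	Taxus baccata	Taxaceae	elliptic	small	0	0	Hand collected, Rhodes, Greece
TP	Tilia platyphyllos	Tiliaceae	oblate	small	3	3	Bonapol
UG	Ulmus glabra	Ulmaceae	spheroidal	medium	5	6	Bonapol
ZM	Zea mays	Poaceae	spheroidal	large	1	1	Bonapol
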