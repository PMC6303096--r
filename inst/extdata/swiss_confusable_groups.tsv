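channel	species	shares_barcode	note
barcode	Pyrgus malvae;Pyrgus malvoides	FALSE	para/polyphyletic, haplotypes species-specific
barcode	Adscita statices;Adscita alpina	FALSE	para/polyphyletic, haplotypes species-specific
barcode	Plebejus argyrognomon;Plebejus idas	FALSE	para/polyphyletic, haplotypes species-specific
barcode	Erebia manto;Erebia bubastis	FALSE	para/polyphyletic, haplotypes species-specific
barcode	Erebia tyndarus;Erebia arvernensis;Erebia nivalis	TRUE	shared barcodes within complex
barcode	Erebia ligea;Erebia euryale	TRUE	shared barcodes
barcode	Coenonympha darwiniana;Coenonympha gardetta	TRUE	shared barcodes
barcode	Zygaena minos;Zygaena purpuralis	TRUE	shared barcodes
barcode	Pyrgus warrenensis;Pyrgus alveus;Pyrgus accreta	TRUE	shared barcodes within complex
barcode	Cupido osiris;Cupido minimus	TRUE	shared barcodes
male_morphology	Aricia artaxerxes;Aricia agestis	NA	cannot always be separated with certainty
male_morphology	Boloria napaea;Boloria pales	NA	cannot be separated with certainty in males
male_morphology	Pieris bryoniae;Pieris napi	NA	cannot be separated with certainty in males
male_morphology	Pyrgus accreta;Pyrgus alveus	NA	wing morphology indistinguishable; genitalia differences disputed
male_morphology	Zygaena romeo;Zygaena osterodensis	NA	genitalia examination needed; some specimens remain difficult
male_morphology	Coenonympha gardetta;Coenonympha darwiniana	NA	intermediates in contact zones
male_morphology	Colias hyale;Colias alfacariensis	NA	some males difficult
male_morphology	Melitaea athalia;Melitaea nevadensis	NA	genitalia intermediate in contact-zone populations
female_morphology	Aricia artaxerxes;Aricia agestis	NA	cannot always be separated with certainty
female_morphology	Colias alfacariensis;Colias hyale	NA	cannot be separated with certainty in females
female_morphology	Erebia tyndarus;Erebia arvernensis;Erebia nivalis	NA	cannot be separated with certainty in females
female_morphology	Hipparchia fagi;Hipparchia genava	NA	cannot be separated with certainty in females
female_morphology	Melitaea athalia;Melitaea nevadensis	NA	no morphological criteria for females
female_morphology	Pyrgus accreta;Pyrgus alveus;Pyrgus warrenensis	NA	wing morphology indistinguishable
female_morphology	Zygaena romeo;Zygaena osterodensis	NA	genitalia examination needed; some specimens remain difficult
female_morphology	Coenonympha gardetta;Coenonympha darwiniana	NA	intermediates in contact zones
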