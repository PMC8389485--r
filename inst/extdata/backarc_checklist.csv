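class,group,family,species
Anthozoa,Actinaria,Kadosactinidae,Marianactis bythios
Anthozoa,Zoantharia,Epizoanthidae,Epizoanthus aff. sp. nov.
Aplacophora,Solenogastres,Simrothiellidae,Helicoradomenia sp. nov.
Bivalvia,Mytilida,Mytilidae,Bathymodiolus septemdierum
Gastropoda,Abyssochrysoidea,Provannidae,Alviniconcha hessleri
Gastropoda,Abyssochrysoidea,Provannidae,Provanna nassariaeformis
Gastropoda,Abyssochrysoidea,Provannidae,Desbruyeresia marianaensis
Gastropoda,Abyssochrysoidea,Provannidae,Desbruyeresia chamorrensis
Gastropoda,Lepetellida,Lepetodrilidae,Lepetodrilus aff. schrolli MT
Gastropoda,Lepetellida,Lepetodrilidae,Pseudorimula marianae
Gastropoda,Lottoidea,Pectinodontidae,Bathyacmaea sp.
Gastropoda,Cycloneritida,Phenacolepadidae,Shinkailepas sp. nov.
Gastropoda,Neomphaloidea,Neomphalidae,Symmetromphalus regularis
Gastropoda,Neogastropoda,Raphitomidae,Phymorhynchus wareni
Hexanauplia,Cirripedia,Neoverrucidae,Neoverruca brachylepadoformis
Hexanauplia,Cirripedia,Eolepadidae,Vulcanolepas verenae
Malacostraca,Decapoda,Alvinocarididae,Rimicaris vandoverae
Malacostraca,Decapoda,Alvinocarididae,Rimicaris cf. variabilis
Malacostraca,Decapoda,Alvinocarididae,Rimicaris falkorae
Malacostraca,Decapoda,Bythograeidae,Austinograea williamsi
Pycnogonida,Pantapoda,Ammotheidae,Sericosura cochleifovea
Polychaeta,Errantia,Polynoidae,Levensteiniella raisae
Polychaeta,Errantia,Polynoidae,Lepidonotopodium minutum
Polychaeta,Errantia,Polynoidae,Branchinotogluma marianus
Polychaeta,Errantia,Hesionidae,Sirsoe hessleri
Polychaeta,Sedentaria,Spionidae,Laonice sp. nov.
Polychaeta,Sedentaria,Alvinellidae,Paralvinella hessleri
Polychaeta,Sedentaria,Ampharetidae,Amphisamytha sp. nov.
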