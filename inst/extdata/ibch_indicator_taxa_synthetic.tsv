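name	rank	phylum	higher_group	gi_value	gi_min_abundance
Baetidae	family	Arthropoda	Ephemeroptera	2	10
Heptageniidae	family	Arthropoda	Ephemeroptera	5	3
Leptophlebiidae	family	Arthropoda	Ephemeroptera	7	3
Ephemerellidae	family	Arthropoda	Ephemeroptera	3	3
Ephemeridae	family	Arthropoda	Ephemeroptera	6	3
Caenidae	family	Arthropoda	Ephemeroptera	2	10
Oligoneuriidae	family	Arthropoda	Ephemeroptera		3
Polymitarcyidae	family	Arthropoda	Ephemeroptera	5	3
Potamanthidae	family	Arthropoda	Ephemeroptera	5	3
Siphlonuridae	family	Arthropoda	Ephemeroptera		3
Ameletidae	family	Arthropoda	Ephemeroptera		3
Perlidae	family	Arthropoda	Plecoptera	9	3
Perlodidae	family	Arthropoda	Plecoptera	9	3
Chloroperlidae	family	Arthropoda	Plecoptera	9	3
Nemouridae	family	Arthropoda	Plecoptera	6	3
Leuctridae	family	Arthropoda	Plecoptera	7	3
Capniidae	family	Arthropoda	Plecoptera	8	3
Taeniopterygidae	family	Arthropoda	Plecoptera	9	3
Hydropsychidae	family	Arthropoda	Trichoptera	3	3
Rhyacophilidae	family	Arthropoda	Trichoptera	4	3
Glossosomatidae	family	Arthropoda	Trichoptera	7	3
Hydroptilidae	family	Arthropoda	Trichoptera	5	3
Philopotamidae	family	Arthropoda	Trichoptera	8	3
Polycentropodidae	family	Arthropoda	Trichoptera	4	3
Psychomyiidae	family	Arthropoda	Trichoptera	4	3
Ecnomidae	family	Arthropoda	Trichoptera		3
Limnephilidae	family	Arthropoda	Trichoptera	3	3
Goeridae	family	Arthropoda	Trichoptera	7	3
Lepidostomatidae	family	Arthropoda	Trichoptera	6	3
Leptoceridae	family	Arthropoda	Trichoptera	4	3
Sericostomatidae	family	Arthropoda	Trichoptera	6	3
Brachycentridae	family	Arthropoda	Trichoptera	8	3
Beraeidae	family	Arthropoda	Trichoptera	7	3
Odontoceridae	family	Arthropoda	Trichoptera	8	3
Molannidae	family	Arthropoda	Trichoptera		3
Phryganeidae	family	Arthropoda	Trichoptera		3
Thremmatidae	family	Arthropoda	Trichoptera		3
Apataniidae	family	Arthropoda	Trichoptera		3
Helicopsychidae	family	Arthropoda	Trichoptera		3
Uenoidae	family	Arthropoda	Trichoptera		3
Elmidae	family	Arthropoda	Coleoptera	2	10
Dryopidae	family	Arthropoda	Coleoptera		3
Gyrinidae	family	Arthropoda	Coleoptera		3
Haliplidae	family	Arthropoda	Coleoptera		3
Dytiscidae	family	Arthropoda	Coleoptera		3
Hydrophilidae	family	Arthropoda	Coleoptera		3
Hydraenidae	family	Arthropoda	Coleoptera		3
Helophoridae	family	Arthropoda	Coleoptera		3
Scirtidae	family	Arthropoda	Coleoptera		3
Psephenidae	family	Arthropoda	Coleoptera		3
Curculionidae	family	Arthropoda	Coleoptera		3
Chrysomelidae	family	Arthropoda	Coleoptera		3
Chironomidae	family	Arthropoda	Diptera	1	10
Simuliidae	family	Arthropoda	Diptera		3
Ceratopogonidae	family	Arthropoda	Diptera		3
Limoniidae	family	Arthropoda	Diptera		3
Tipulidae	family	Arthropoda	Diptera		3
Pediciidae	family	Arthropoda	Diptera		3
Psychodidae	family	Arthropoda	Diptera		3
Blephariceridae	family	Arthropoda	Diptera		3
Athericidae	family	Arthropoda	Diptera		3
Tabanidae	family	Arthropoda	Diptera		3
Stratiomyidae	family	Arthropoda	Diptera		3
Empididae	family	Arthropoda	Diptera		3
Dolichopodidae	family	Arthropoda	Diptera		3
Ephydridae	family	Arthropoda	Diptera		3
Muscidae	family	Arthropoda	Diptera		3
Anthomyiidae	family	Arthropoda	Diptera		3
Sciomyzidae	family	Arthropoda	Diptera		3
Syrphidae	family	Arthropoda	Diptera		3
Culicidae	family	Arthropoda	Diptera		3
Dixidae	family	Arthropoda	Diptera		3
Thaumaleidae	family	Arthropoda	Diptera		3
Ptychopteridae	family	Arthropoda	Diptera		3
Rhagionidae	family	Arthropoda	Diptera		3
Chaoboridae	family	Arthropoda	Diptera		3
Corixidae	family	Arthropoda	Heteroptera		3
Notonectidae	family	Arthropoda	Heteroptera		3
Naucoridae	family	Arthropoda	Heteroptera		3
Nepidae	family	Arthropoda	Heteroptera		3
Aphelocheiridae	family	Arthropoda	Heteroptera	3	3
Pleidae	family	Arthropoda	Heteroptera		3
Gerridae	family	Arthropoda	Heteroptera		3
Veliidae	family	Arthropoda	Heteroptera		3
Hydrometridae	family	Arthropoda	Heteroptera		3
Mesoveliidae	family	Arthropoda	Heteroptera		3
Calopterygidae	family	Arthropoda	Odonata		3
Lestidae	family	Arthropoda	Odonata		3
Coenagrionidae	family	Arthropoda	Odonata		3
Platycnemididae	family	Arthropoda	Odonata		3
Aeshnidae	family	Arthropoda	Odonata		3
Gomphidae	family	Arthropoda	Odonata		3
Cordulegastridae	family	Arthropoda	Odonata		3
Corduliidae	family	Arthropoda	Odonata		3
Libellulidae	family	Arthropoda	Odonata		3
Sialidae	family	Arthropoda	Megaloptera		3
Osmylidae	family	Arthropoda	Neuroptera		3
Sisyridae	family	Arthropoda	Neuroptera		3
Crambidae	family	Arthropoda	Lepidoptera		3
Gammaridae	family	Arthropoda	Crustacea	2	10
Asellidae	family	Arthropoda	Crustacea	1	10
Astacidae	family	Arthropoda	Crustacea		3
Cambaridae	family	Arthropoda	Crustacea		3
Atyidae	family	Arthropoda	Crustacea		3
Niphargidae	family	Arthropoda	Crustacea		3
Corophiidae	family	Arthropoda	Crustacea		3
Mysidae	family	Arthropoda	Crustacea		3
Crangonyctidae	family	Arthropoda	Crustacea		3
Hydrachnidae	family	Arthropoda	Hydracarina		3
Limnesiidae	family	Arthropoda	Hydracarina		3
Hygrobatidae	family	Arthropoda	Hydracarina		3
Sperchontidae	family	Arthropoda	Hydracarina		3
Torrenticolidae	family	Arthropoda	Hydracarina		3
Lymnaeidae	family	Mollusca	Gastropoda	2	10
Physidae	family	Mollusca	Gastropoda	2	10
Planorbidae	family	Mollusca	Gastropoda	2	10
Ancylidae	family	Mollusca	Gastropoda	2	10
Hydrobiidae	family	Mollusca	Gastropoda	2	10
Bithyniidae	family	Mollusca	Gastropoda		3
Valvatidae	family	Mollusca	Gastropoda		3
Viviparidae	family	Mollusca	Gastropoda		3
Neritidae	family	Mollusca	Gastropoda		3
Acroloxidae	family	Mollusca	Gastropoda		3
Sphaeriidae	family	Mollusca	Bivalvia	2	10
Unionidae	family	Mollusca	Bivalvia		3
Dreissenidae	family	Mollusca	Bivalvia		3
Corbiculidae	family	Mollusca	Bivalvia		3
Glossiphoniidae	family	Annelida	Hirudinea	1	10
Hirudinidae	family	Annelida	Hirudinea		3
Erpobdellidae	family	Annelida	Hirudinea	1	10
Piscicolidae	family	Annelida	Hirudinea		3
Tubificidae	family	Annelida	Oligochaeta	1	10
Naididae	family	Annelida	Oligochaeta	1	10
Lumbricidae	family	Annelida	Oligochaeta		3
Lumbriculidae	family	Annelida	Oligochaeta		3
Enchytraeidae	family	Annelida	Oligochaeta		3
Haplotaxidae	family	Annelida	Oligochaeta		3
Planariidae	family	Platyhelminthes	Tricladida		3
Dugesiidae	family	Platyhelminthes	Tricladida		3
Dendrocoelidae	family	Platyhelminthes	Tricladida		3
Gordiidae	family	Nematomorpha	Nematomorpha		3
Tetrastemmatidae	family	Nemertea	Nemertea		3
Porifera	phylum	Porifera	Porifera		3
Bryozoa	phylum	Bryozoa	Bryozoa		3
Cnidaria	phylum	Cnidaria	Cnidaria		3
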