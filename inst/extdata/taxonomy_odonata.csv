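species,genus,family,suborder
Calopteryx splendens,Calopteryx,Calopterygidae,Zygoptera
Calopteryx virgo,Calopteryx,Calopterygidae,Zygoptera
Lestes sponsa,Lestes,Lestidae,Zygoptera
Lestes dryas,Lestes,Lestidae,Zygoptera
Platycnemis pennipes,Platycnemis,Platycnemididae,Zygoptera
Ceriagrion tenellum,Ceriagrion,Coenagrionidae,Zygoptera
Coenagrion hastulatum,Coenagrion,Coenagrionidae,Zygoptera
Coenagrion mercuriale,Coenagrion,Coenagrionidae,Zygoptera
Coenagrion puella,Coenagrion,Coenagrionidae,Zygoptera
Coenagrion pulchellum,Coenagrion,Coenagrionidae,Zygoptera
Enallagma cyathigerum,Enallagma,Coenagrionidae,Zygoptera
Erythromma najas,Erythromma,Coenagrionidae,Zygoptera
Erythromma viridulum,Erythromma,Coenagrionidae,Zygoptera
Ischnura elegans,Ischnura,Coenagrionidae,Zygoptera
Ischnura pumilio,Ischnura,Coenagrionidae,Zygoptera
Pyrrhosoma nymphula,Pyrrhosoma,Coenagrionidae,Zygoptera
Aeshna caerulea,Aeshna,Aeshnidae,Anisoptera
Aeshna cyanea,Aeshna,Aeshnidae,Anisoptera
Aeshna grandis,Aeshna,Aeshnidae,Anisoptera
Aeshna juncea,Aeshna,Aeshnidae,Anisoptera
Aeshna mixta,Aeshna,Aeshnidae,Anisoptera
Anax imperator,Anax,Aeshnidae,Anisoptera
Brachytron pratense,Brachytron,Aeshnidae,Anisoptera
Gomphus vulgatissimus,Gomphus,Gomphidae,Anisoptera
Cordulegaster boltonii,Cordulegaster,Cordulegastridae,Anisoptera
Cordulia aenea,Cordulia,Corduliidae,Anisoptera
Somatochlora arctica,Somatochlora,Corduliidae,Anisoptera
Somatochlora metallica,Somatochlora,Corduliidae,Anisoptera
Libellula depressa,Libellula,Libellulidae,Anisoptera
Libellula fulva,Libellula,Libellulidae,Anisoptera
Libellula quadrimaculata,Libellula,Libellulidae,Anisoptera
Orthetrum cancellatum,Orthetrum,Libellulidae,Anisoptera
Orthetrum coerulescens,Orthetrum,Libellulidae,Anisoptera
Sympetrum danae,Sympetrum,Libellulidae,Anisoptera
Sympetrum sanguineum,Sympetrum,Libellulidae,Anisoptera
Sympetrum striolatum,Sympetrum,Libellulidae,Anisoptera
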