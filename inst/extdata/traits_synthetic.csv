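species,status,region,thorax_length,flight_period,habitat_breadth,breeding_habitat,overwintering
Calopteryx splendens,widespread,widespread,15.4,7,3,lentic,eggs
Calopteryx virgo,very rare,southern,23.1,5,3,lentic,eggs
Lestes sponsa,very rare,southern,15.2,4,4,lotic,both
Lestes dryas,very widespread,southern,21.2,5,2,lotic,eggs
Platycnemis pennipes,widespread,widespread,16.7,3,2,both,larvae
Ceriagrion tenellum,scarce,southern,25.7,6,4,lotic,eggs
Coenagrion hastulatum,local,southern,22.8,3,6,lotic,larvae
Coenagrion mercuriale,local,southern,18.4,2,3,lentic,eggs
Coenagrion puella,widespread,northern,23.2,4,6,lotic,larvae
Coenagrion pulchellum,local,southern,21.7,5,4,lotic,larvae
Enallagma cyathigerum,rare,widespread,15.3,4,5,lotic,eggs
Erythromma najas,rare,oceanic,19.2,3,6,lotic,eggs
Erythromma viridulum,scarce,oceanic,16.3,5,1,both,both
Ischnura elegans,widespread,widespread,21.8,7,5,lotic,larvae
Ischnura pumilio,very widespread,northern,17.4,2,6,lentic,larvae
Pyrrhosoma nymphula,very rare,northern,19.1,6,4,lentic,both
Aeshna caerulea,local,southern,15.1,3,6,both,larvae
Aeshna cyanea,rare,southern,16.2,5,6,lotic,eggs
Aeshna grandis,very widespread,oceanic,20.5,2,5,lentic,eggs
Aeshna juncea,rare,southern,16,4,6,both,eggs
Aeshna mixta,very widespread,widespread,19.4,3,2,lotic,larvae
Anax imperator,rare,widespread,20.7,3,2,both,eggs
Brachytron pratense,widespread,oceanic,19.2,3,6,lotic,larvae
Gomphus vulgatissimus,widespread,southern,18.8,4,6,lotic,eggs
Cordulegaster boltonii,local,widespread,13.1,5,2,lotic,eggs
Cordulia aenea,widespread,southern,18.9,3,1,lotic,both
Somatochlora arctica,scarce,oceanic,12.8,4,1,lentic,larvae
Somatochlora metallica,local,oceanic,24.6,3,3,lentic,eggs
Libellula depressa,scarce,southern,16,5,2,lotic,larvae
Libellula fulva,scarce,southern,20.6,5,5,lotic,larvae
Libellula quadrimaculata,rare,oceanic,22.1,2,1,lotic,larvae
Orthetrum cancellatum,widespread,southern,20,6,2,lentic,eggs
Orthetrum coerulescens,local,oceanic,25.4,3,1,both,larvae
Sympetrum danae,rare,widespread,16.6,3,5,lentic,larvae
Sympetrum sanguineum,rare,southern,21.8,2,5,lotic,larvae
Sympetrum striolatum,widespread,northern,16.1,3,4,lentic,larvae
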