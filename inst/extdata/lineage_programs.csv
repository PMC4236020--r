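taxon,lineage1,lineage2,lineage3,lineage4,lineage5,lineage6,lineage7
Human,0,20,40,10,10,10,10
Gorilla,0,20,40,10,10,10,10
Orangutan,0,20,40,10,10,10,10
Baboon,0,20,40,10,10,10,10
Macaque,0,20,40,10,10,10,10
Capuchin,0,20,40,10,10,10,10
Owl monkey,0,50,50,0,0,0,0
Callimico,0,50,50,0,0,0,0
Marmoset,0,60,40,0,0,0,0
Galago,0,75,25,0,0,0,0
Tupaia,10,75,15,0,0,0,0
Rabbit,10,75,15,0,0,0,0
Agouti,10,75,15,0,0,0,0
Capybara,10,75,15,0,0,0,0
Rat,10,80,10,0,0,0,0
Mouse,10,80,10,0,0,0,0
Opossum,80,10,10,0,0,0,0
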