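species,gestation_days,neurogenic_days,observed_neurons,founder_pool,cell_cycle_hours,gi_group
Human,270,112,1.63E+10,3.10E+07,45,high
Gorilla,257,103,9.10E+09,1.59E+07,45,high
Orangutan,260,104,8.90E+09,1.16E+07,45,high
Macaque,166,60,1.71E+09,4.41E+06,45,high
Baboon,180,72,2.88E+09,6.37E+06,45,high
Capuchin,158,59,1.14E+09,2.97E+06,45,high
Owl monkey,138,55,4.42E+08,1.05E+06,30,low
Callimico,153,60,3.57E+08,6.92E+05,30,low
Marmoset,146,58,2.45E+08,6.71E+05,30,low
Galago,134,54,2.26E+08,1.01E+06,30,low
Tupaia,46,19,6.04E+07,5.68E+05,18.5,low
Rabbit,30,13,7.15E+07,8.08E+05,18.5,low
Agouti,112,45,1.10E+08,9.80E+05,18.5,low
Capybara,137,55,3.10E+08,1.78E+06,18.5,low
Rat,21,10,3.10E+07,5.40E+05,18.5,low
Mouse,19,9,1.37E+07,3.99E+05,18.5,low
Opossum,NA,10,0.88E+06,2.50E+04,18.5,low
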