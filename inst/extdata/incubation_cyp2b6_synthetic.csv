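"enzyme_source","pathway","concentration_uM","velocity","velocity_units","replicate"
"CYP2B6_synthetic",1,0.05,2.16426161348856,"pmol/min/pmolCYP",1
"CYP2B6_synthetic",1,0.05,1.98318339635323,"pmol/min/pmolCYP",2
"CYP2B6_synthetic",1,0.1,3.53506302009217,"pmol/min/pmolCYP",1
"CYP2B6_synthetic",1,0.1,3.02504358176128,"pmol/min/pmolCYP",2
"CYP2B6_synthetic",1,0.25,4.86458841561172,"pmol/min/pmolCYP",1
"CYP2B6_synthetic",1,0.25,5.11797597200577,"pmol/min/pmolCYP",2
"CYP2B6_synthetic",1,0.5,5.24736768293767,"pmol/min/pmolCYP",1
"CYP2B6_synthetic",1,0.5,5.80487719105315,"pmol/min/pmolCYP",2
"CYP2B6_synthetic",1,1,6.65177240574036,"pmol/min/pmolCYP",1
"CYP2B6_synthetic",1,1,6.62065536951831,"pmol/min/pmolCYP",2
"CYP2B6_synthetic",1,5,7.54104696495626,"pmol/min/pmolCYP",1
"CYP2B6_synthetic",1,5,7.49212709884889,"pmol/min/pmolCYP",2
"CYP2B6_synthetic",1,10,7.41639206013439,"pmol/min/pmolCYP",1
"CYP2B6_synthetic",1,10,8.17596846859266,"pmol/min/pmolCYP",2
"CYP2B6_synthetic",1,25,7.15189892480809,"pmol/min/pmolCYP",1
"CYP2B6_synthetic",1,25,7.54994451025964,"pmol/min/pmolCYP",2
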