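sex,compartment,organ,mass_g,s_bm_gy_per_mbq_h
male,high,liver,1800,1.60e-07
male,high,spleen,180,1.20e-07
male,high,kidneys,310,1.80e-07
male,high,tumour,250,1.40e-07
male,low,muscle,28000,4.0e-08
male,low,adipose_remainder,25000,3.0e-08
male,low,lungs,1000,9.0e-08
male,low,gi_tract,1200,1.20e-07
male,low,heart_blood,1500,8.0e-08
male,low,skeleton,10000,1.50e-07
female,high,liver,1400,1.84e-07
female,high,spleen,150,1.38e-07
female,high,kidneys,275,2.07e-07
female,high,tumour,250,1.61e-07
female,low,muscle,23800,4.6e-08
female,low,adipose_remainder,21250,3.5e-08
female,low,lungs,850,1.04e-07
female,low,gi_tract,1020,1.38e-07
female,low,heart_blood,1275,9.2e-08
female,low,skeleton,8500,1.73e-07
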