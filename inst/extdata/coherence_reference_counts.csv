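thresholds,site,system_class,ncc,nww,ncw,nwc
constant_lake,Greifensee,lake,18,25,9,0
constant_lake,Bautzen,lake,46,17,15,2
constant_lake,Scharmuetzelsee,lake,29,30,9,0
constant_lake,Stechlinsee,lake,19,17,3,1
constant_lake,Erken,lake,43,15,11,3
constant_lake,Oder Bank,baltic,18,10,2,7
constant_lake,Kiel Bight,baltic,53,29,6,8
constant_lake,Fehmarn Belt,baltic,27,12,4,7
constant_lake,Darss Sill,baltic,31,15,1,11
constant_lake,Arkona Basin,baltic,14,6,1,7
constant_lake,Ems,north_sea,26,20,18,11
constant_lake,German Bight,north_sea,27,17,17,11
constant_lake,North Sea Buoy,north_sea,16,13,7,6
site_specific,Oder Bank,baltic,15,14,5,3
site_specific,Kiel Bight,baltic,46,34,13,3
site_specific,Fehmarn Belt,baltic,24,18,6,0
site_specific,Darss Sill,baltic,31,20,1,6
site_specific,Arkona Basin,baltic,14,10,1,3
site_specific,Ems,north_sea,29,28,15,3
site_specific,German Bight,north_sea,35,25,9,2
site_specific,North Sea Buoy,north_sea,19,17,4,2
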