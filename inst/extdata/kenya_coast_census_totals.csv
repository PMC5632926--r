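year,finest_level,level_name,n_units,population
1979,5,Sub-location,191,1014567
1989,5,Sub-location,212,1444296
1999,6,Enumeration area,2457,1949264
2009,5,Sub-location,279,2679478
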