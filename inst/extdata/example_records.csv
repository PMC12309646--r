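species_tag,cell_id,lon,lat,date
focal,1,,,2020-06-03
focal,,0.4,1.6,2020-07-15
nonfocal,2,,,2020-06-20
nonfocal,2,,,2020-06-21
nonfocal,,1.2,0.3,2020-08-01
nonfocal,3,,,not-a-date
focal,,,,2020-06-10
nonfocal,4,,,2020-09-29
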