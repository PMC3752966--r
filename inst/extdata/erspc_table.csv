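stratum,start,end,cases,rate_per_1000,unit
control,0,12,1067,5.26,person_years
screen,,,1078,54,persons
interval,0,1,17,0.90,person_years
interval,1,2,10,0.54,person_years
interval,2,3,24,1.31,person_years
interval,3,4,24,1.34,person_years
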