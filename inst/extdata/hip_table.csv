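stratum,start,end,cases,rate_per_1000,unit
control,0,5,285,1.87,person_years
screen,,,55,2.73,persons
interval,0,1,13,0.61,person_years
interval,1,2,7,1.03,person_years
interval,2,3,1,0.31,person_years
interval,3,4,3,1.16,person_years
interval,4,5,5,2.25,person_years
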