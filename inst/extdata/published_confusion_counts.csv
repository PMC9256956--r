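threshold_c,tp,fp,tn,fn,accuracy_pct,sensitivity_pct,specificity_pct
37.00,4466,336,106,117,91,97,24
37.25,3767,370,616,272,87,93,62
37.50,3231,495,1110,189,86,94,69
37.75,2654,643,1623,105,85,96,72
38.00,2035,742,2172,76,84,96,75
38.25,1411,707,2824,83,84,94,80
38.50,878,546,3485,116,87,88,86
38.75,456,313,4090,166,90,73,93
39.00,163,141,4542,179,94,48,97
39.25,22,39,4810,154,96,13,99
39.50,3,12,4937,73,98,4,100
39.75,0,5,4989,31,99,0,100
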