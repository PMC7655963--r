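age_min,age_max,count,male,female,acer_total_mean,acer_total_sd
20,29,39,25,14,96.5,1.89
30,39,21,10,11,97.9,2.49
40,49,19,11,8,96.4,3.13
50,59,34,12,22,97.4,1.54
60,69,35,14,21,96.1,2.41
70,79,26,13,13,94.8,3.06
80,89,1,0,1,91.0,NA
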