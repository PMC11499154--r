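donor,cell_line,condition,pct
Donor1,SK-MEL-5,LV,68.46
Donor2,SK-MEL-5,LV,71.02
Donor3,SK-MEL-5,LV,65.48
Donor4,SK-MEL-5,LV,62.43
Donor5,SK-MEL-5,LV,74.02
Donor6,SK-MEL-5,LV,85.48
Donor7,SK-MEL-5,LV,81.67
Donor1,SK-MEL-5,Veh,51.72
Donor2,SK-MEL-5,Veh,38.04
Donor3,SK-MEL-5,Veh,18.80
Donor4,SK-MEL-5,Veh,36.11
Donor5,SK-MEL-5,Veh,16.05
Donor6,SK-MEL-5,Veh,29.26
Donor7,SK-MEL-5,Veh,33.56
Donor1,HCT-116,LV,33.75
Donor2,HCT-116,LV,44.16
Donor3,HCT-116,LV,44.52
Donor4,HCT-116,LV,29.52
Donor5,HCT-116,LV,29.92
Donor6,HCT-116,LV,57.69
Donor7,HCT-116,LV,50.50
Donor1,HCT-116,Veh,33.75
Donor2,HCT-116,Veh,44.52
Donor3,HCT-116,Veh,29.92
Donor4,HCT-116,Veh,50.50
Donor5,HCT-116,Veh,18.93
Donor6,HCT-116,Veh,33.62
Donor7,HCT-116,Veh,39.55
Donor1,MDA-MB-231,LV,42.33
Donor2,MDA-MB-231,LV,42.50
Donor3,MDA-MB-231,LV,40.06
Donor4,MDA-MB-231,LV,15.97
Donor5,MDA-MB-231,LV,8.18
Donor6,MDA-MB-231,LV,16.93
Donor7,MDA-MB-231,LV,28.48
Donor1,MDA-MB-231,Veh,36.45
Donor2,MDA-MB-231,Veh,20.65
Donor3,MDA-MB-231,Veh,6.16
Donor4,MDA-MB-231,Veh,15.75
Donor5,MDA-MB-231,Veh,21.13
Donor6,MDA-MB-231,Veh,17.29
Donor7,MDA-MB-231,Veh,17.96
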