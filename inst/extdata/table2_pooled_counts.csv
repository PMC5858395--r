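group,n_studies,case_tt,case_ct,case_cc,case_total,ctrl_tt,ctrl_ct,ctrl_cc,ctrl_total
Overall,71,1087,3142,3835,8064,1410,5166,6656,13232
Caucasian,27,425,1564,1659,3648,700,3001,3437,7138
Hispanic,7,215,360,190,765,325,524,266,1115
SouthAmerican,4,62,173,143,378,66,258,231,555
EastAsian,17,296,548,411,1255,240,828,962,2030
SouthAsian,4,15,94,452,561,31,199,761,991
MiddleEast,7,54,267,423,744,46,206,376,628
African,5,20,136,557,713,2,150,623,775
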