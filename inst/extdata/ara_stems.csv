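vial_id,dosed,ethylene_per_g
Undosed 1,FALSE,4.84
Undosed 2,FALSE,3.38
Undosed 3,FALSE,4.50
Undosed 7,FALSE,4.52
Undosed 8,FALSE,5.01
Undosed 9,FALSE,3.52
Undosed 13,FALSE,4.42
Undosed 14,FALSE,7.34
Undosed 15,FALSE,8.46
Dosed 21,TRUE,20.63
Dosed 22,TRUE,61.42
Dosed 23,TRUE,6.19
Dosed 27,TRUE,8.52
Dosed 28,TRUE,5.76
Dosed 29,TRUE,9.05
Dosed 33,TRUE,5.69
Dosed 34,TRUE,4.24
Dosed 35,TRUE,106.9
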