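trait,date_index,band1_nm,band2_nm
dw,1,676,664
dw,2,774,748
dw,3,826,746
dw,4,1030,740
nc,1,1018,978
nc,2,1110,1108
nc,3,1130,546
nc,4,1030,986
nup,1,792,736
nup,2,1068,544
nup,3,758,754
nup,4,1018,994
cc,1,584,582
cc,2,1134,580
cc,3,556,552
cc,4,1108,726
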