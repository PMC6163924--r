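trait,best_mean_r2,cv_at_best,band1_nm,band2_nm
dw,0.67,0.26,794,736
nc,0.22,0.70,996,924
nup,0.63,0.23,792,736
cc,0.55,0.22,584,582
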