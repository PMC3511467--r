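subject_id,amount_ss,amount_ll,delay_days,choice
s01,20,25.5,0.25,LL
s01,20,42,30,SS
s02,20,31.25,7,LL
s02,20,65,180,SS
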