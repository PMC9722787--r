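station_id,season,d,reciprocal
UE,dry,0.17,5.80
ME,dry,0.13,7.46
LE,dry,0.16,6.01
HI,dry,0.37,2.67
CK,dry,0.14,6.98
UE,wet,0.18,5.63
ME,wet,0.13,7.75
LE,wet,0.28,3.53
HI,wet,0.19,5.21
CK,wet,0.20,5.12
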