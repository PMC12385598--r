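sample,new_scale,existing_scale,consumer
YJ,6.61,6.20,7.43
HR,5.80,5.03,5.97
BW,5.75,5.63,6.47
QD,3.98,6.40,4.83
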