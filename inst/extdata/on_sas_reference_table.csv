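dataset,segment,quantity,measured,no_microstructure
dataset1,bulbar,on_length_mm,0.75,0.75
dataset1,bulbar,csf_volume_mm3,2.61,4.11
dataset1,bulbar,interface_area_mm2,114.89,23.65
dataset2,intraorbital,on_length_mm,0.73,0.73
dataset2,intraorbital,csf_volume_mm3,1.68,2.64
dataset2,intraorbital,interface_area_mm2,68.20,21.03
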