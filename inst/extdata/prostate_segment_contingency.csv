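observer,tp,fp,fn,tn
Radiologist expert gray,64,19,116,217
Radiologist 1 color,35,20,145,216
Radiologist 2 color,47,24,133,212
Radiologist 4 color,27,12,153,224
Radiologist 5 color,30,10,150,226
Radiologists color mean,37,12,143,224
Radiologist expert color,64,21,116,215
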