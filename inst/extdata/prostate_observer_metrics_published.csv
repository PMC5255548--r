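observer,sensitivity,specificity,ppv,npv
Radiologist expert gray,0.36,0.92,0.77,0.65
Radiologist 1 color,0.19,0.92,0.64,0.60
Radiologist 2 color,0.26,0.90,0.66,0.61
Radiologist 4 color,0.15,0.95,0.69,0.59
Radiologist 5 color,0.17,0.96,0.75,0.60
Radiologists color mean,0.21,0.95,0.76,0.61
Radiologist expert color,0.36,0.91,0.75,0.65
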