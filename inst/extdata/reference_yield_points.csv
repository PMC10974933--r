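formulation,rheometer_Pa,printhead_kPa
F1,607,366
F2,1064,305
F3,198,417
F4,1064,363
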