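id,label,weight
D1,Endangered category,0.3938
D2,Artificial planting,0.0438
D3,Conservation status,0.0127
D4,Threat persistence,0.0410
D5,Domestic and international population impacts,0.0029
D6,Species trade impacts,0.0059
D7,Community status,0.0041
D8,Organism type,0.0289
D9,Endemic species,0.0545
D10,Species status,0.0060
D11,Relict species status,0.0140
D12,Economic values,0.0655
D13,Hereditary value,0.3270
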