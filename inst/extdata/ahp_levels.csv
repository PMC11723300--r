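criterion,label,points
D1,Extinct,9
D1,Critically endangered,7
D1,Endangered,5
D1,Vulnerable or near threatened,3
D1,Least concern,1
D2,Unable to artificially breed,5
D2,Artificial populations cannot form under natural conditions,3
D2,Artificial populations can form under natural conditions,1
D3,Not conserved,7
D3,Not effectively regulated,5
D3,Conserved in situ or translocated or isolated,3
D3,Restoration of populations,1
D4,Persistence of threatening factors,5
D4,Transient threatening factors,3
D4,Non-threatening factors,1
D5,Breeding from abroad,5
D5,No effect within domestic and foreign populations,3
D5,No population decline at home or abroad,1
D6,Over-utilization,3
D6,No over-utilization,1
D7,Dominant species,7
D7,Subdominant species,5
D7,Companion species,3
D7,No effect on other species in the community,1
D8,Tree,7
D8,Shrub,5
D8,Perennial herb,3
D8,Annual herb,1
D9,Provincial endemic species,7
D9,Regional endemic species,5
D9,Chinese endemic species,3
D9,Non-Chinese endemic species,1
D10,Monotypic family,9
D10,Oligocene species,7
D10,Monotypic genus,5
D10,Oligotypic genus,3
D10,Polyphyletic genus,1
D11,Glacial relict plants,3
D11,Non-glacial relict plants,1
D12,Valuable for development and utilization,3
D12,No development or utilization value,1
D13,Unique utilization value,5
D13,Certain utilization value,3
D13,No utilization value,1
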