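group,category,count
iucn,EN,1
iucn,NT,5
iucn,DD,2
iucn,LC,81
iucn,NII,12
growth_form,perennial_herb,72
growth_form,annual_herb,9
growth_form,shrub,12
growth_form,vine,2
growth_form,tree,6
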