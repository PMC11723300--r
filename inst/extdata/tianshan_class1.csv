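species,red_list,family,ahp_value,endemic_local,ecological_type
Gagea serotina,,Liliaceae,0.60,N,Perennial Herb
Primula algida,LC,Primulaceae,0.60,Y,Perennial Herb
Leonurus turkestanicus,LC,Lamiaceae,0.60,Y,Perennial Herb
Lathyrus tuberosus,LC,Fabaceae,0.60,Y,Perennial Herb
Inula racemosa,LC,Asteraceae,0.60,Y,Perennial Herb
Ligularia heterophylla,LC,Asteraceae,0.60,Y,Perennial Herb
Rheum wittrockii,LC,Polygonaceae,0.60,Y,Perennial Herb
Aquilegia atrovinosa,LC,Ranunculaceae,0.60,Y,Perennial Herb
Cynoglossum officinale,,Boraginaceae,0.60,Y,Biennial Herb
Doronicum altaicum,LC,Asteraceae,0.60,Y,Perennial Herb
Arctium tomentosum,LC,Asteraceae,0.60,Y,Biennial Herb
Conium maculatum,LC,Apiaceae,0.61,Y,Biennial Herb
Oxytropis ochroleuca,LC,Fabaceae,0.61,Y,Perennial Herb
Roemeria refracta,LC,Papaveraceae,0.61,Y,Annual Herb
Thymus marschallianus,LC,Lamiaceae,0.61,Y,Semishrubs
Thymus proximus,LC,Lamiaceae,0.61,Y,Perennial Semishrubs
Rosa laxa,LC,Rosaceae,0.62,Y,Shrubs
Prunus armeniaca,NT,Rosaceae,0.63,N,Deciduous Tree
Betula tianschanica,LC,Betulaceae,0.63,N,Perennial Tree
Glycyrrhiza uralensis,NT,Fabaceae,0.65,N,Perennial Herb
Rhodiola quadrifida,NT,Crassulaceae,0.65,N,Perennial Herb
Pseudolysimachion alatavicum,NT,Plantaginaceae,0.69,Y,Perennial Herb
Aconitum nemorum,NT,Ranunculaceae,0.69,Y,Perennial Herb
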