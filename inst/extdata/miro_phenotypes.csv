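# Continuous phenotype summaries: pollen-tube length (um, 17 h growth) and
# silique length (cm, matched inflorescence positions).
cross_id,group,mean,sd,n
pollen_tube_um,miro1_het,436.2,136.0,133
pollen_tube_um,miro1_het_miro2_hom,178.3,84.8,209
silique_cm,wild_type,1.33,0.056,10
silique_cm,miro1_het_miro2_hom,1.11,0.04,10
silique_cm,miro1_het,1.22,0.038,10
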