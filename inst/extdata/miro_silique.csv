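# Ovule-fate composition of siliques per parental genotype.
# viable = total embryos minus unfertilized ovules and aborted seeds.
cross_id,class,count
wild_type,unfertilized_ovule,11
wild_type,aborted_seed,5
wild_type,viable,626
miro2_hom,unfertilized_ovule,16
miro2_hom,aborted_seed,6
miro2_hom,viable,1113
miro1_het,unfertilized_ovule,98
miro1_het,aborted_seed,226
miro1_het,viable,994
miro1_het_miro2_hom,unfertilized_ovule,402
miro1_het_miro2_hom,aborted_seed,40
miro1_het_miro2_hom,viable,723
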