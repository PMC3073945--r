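# Progeny counts from selfings and reciprocal crosses of miro T-DNA lines.
# dhet_self: miro1 (+/-) miro2-2 (+/-) selfed, scored on BASTA + kanamycin
# dhet_m2hom_self: miro1 (+/-) miro2-2 (-/-) selfed, dual selection
# miro1_self: miro1 (+/-) selfed, BASTA only
# genotyped_subset: PCR-genotyped dual-resistant plants; target =
#   miro1 (+/-) miro2-2 (-/-)
# te_male: WT female x miro1 (+/-) miro2-2 (-/-) male; te_female: reciprocal.
#   te/karyogamy counts RECONSTRUCTED from published percentages and totals
#   (round(p*n)), not observed directly.
# karyogamy_*: ovules with polar-nucleus fusion defect (target) vs normal.
cross_id,class,count
dhet_self,resistant,140
dhet_self,sensitive,328
dhet_m2hom_self,resistant,163
dhet_m2hom_self,sensitive,805
miro1_self,resistant,315
miro1_self,sensitive,237
genotyped_subset,target,17
genotyped_subset,other,63
te_male,resistant,1
te_male,sensitive,795
te_female,resistant,161
te_female,sensitive,464
karyogamy_miro1,target,62
karyogamy_miro1,other,265
karyogamy_dhet,target,180
karyogamy_dhet,other,238
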