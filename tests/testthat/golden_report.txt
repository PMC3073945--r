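Gametophytic transmission analysis report
=========================================

Segregation analysis
--------------------
dhet_self: 140 resistant / 328 sensitive (n = 468), 29.9% resistant; hypothesis 3:5 (all zygotes, naive): X2 = 11.489, p = 0.0007
dhet_m2hom_self: 163 resistant / 805 sensitive (n = 968), 16.8% resistant
miro1_self: 315 resistant / 237 sensitive (n = 552), 57.1% resistant

Genotyped subset
----------------
genotyped_subset: 17 of 80 plants (21.3%) carry the target genotype; hypothesis 2:1 (conditional): X2 = 5.256, p = 0.0219

Co-transmission efficiency (TE = R/S)
-------------------------------------
te_male: TE = 0.0013 (0.1% of total seedlings, n = 796), 95% CI [0.0002, 0.0071]
te_female: TE = 0.3470 (25.8% of total seedlings, n = 625), 95% CI [0.2901, 0.4150]

Silique composition
-------------------
wild_type: n = 642 ovule positions; 1.7% unfertilized, 0.8% aborted, total lethality 2.5%
miro2_hom: n = 1135 ovule positions; 1.4% unfertilized, 0.5% aborted, total lethality 1.9%
miro1_het: n = 1318 ovule positions; 7.4% unfertilized, 17.1% aborted, total lethality 24.6%
miro1_het_miro2_hom: n = 1165 ovule positions; 34.5% unfertilized, 3.4% aborted, total lethality 37.9%

Phenotype comparisons (Welch t)
-------------------------------
pollen_tube_um: miro1_het vs miro1_het_miro2_hom: t = 19.581, df = 197.7, p = <0.0001
silique_cm: wild_type vs miro1_het_miro2_hom: t = 10.109, df = 16.3, p = <0.0001
silique_cm: wild_type vs miro1_het: t = 5.140, df = 15.8, p = 0.0001
silique_cm: miro1_het_miro2_hom vs miro1_het: t = -6.305, df = 18.0, p = <0.0001

Two-proportion comparisons
--------------------------
karyogamy_miro1 (19.0%) vs karyogamy_dhet (43.1%): z = -6.971, p = <0.0001
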