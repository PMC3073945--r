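# Two-locus gametophytic transmission model for the miro1 / miro2-2
# T-DNA alleles. Loci are on separate chromosomes: strictly unlinked.
loci:
  - name: MIRO1
    wild_allele: MIRO1
    tdna_allele: miro1
    marker: BASTA
  - name: MIRO2
    wild_allele: MIRO2
    tdna_allele: miro2-2
    marker: kanamycin
params:
  # relative transmission efficiencies of the double-mutant gamete,
  # as estimated from reciprocal outcrosses to wild type
  tau_male:
    "miro1:miro2-2": 0.0012
  tau_female:
    "miro1:miro2-2": 0.347
  # incompletely penetrant female gametophyte failure of the double-mutant
  # embryo sac, scored as unfertilized ovules
  sac_failure:
    "miro1:miro2-2": 0.45
  # homozygous miro1 zygotes abort during embryo development
  lethal:
    - locus: MIRO1
      state: hom_tdna
crosses:
  - id: dhet_self
    mother: "+/- +/-"
  - id: dhet_m2hom_self
    mother: "+/- -/-"
  - id: te_male
    mother: "+/+ +/+"
    father: "+/- -/-"
  - id: te_female
    mother: "+/- -/-"
    father: "+/+ +/+"
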