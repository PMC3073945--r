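Package: gametrans
Title: Gametophytic Transmission Genetics of T-DNA Insertion Alleles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-locus gametophytic-selection model for segregation analysis
    of T-DNA insertion alleles in plants. Enumerates Mendelian gametes,
    applies sex-specific relative transmission efficiencies, female
    embryo-sac failure and zygotic lethality to derive exact progeny-class
    distributions for selfings and reciprocal crosses; fits transmission
    parameters to observed progeny-class counts by maximum likelihood;
    provides segregation chi-square tests, transmission-efficiency
    estimates with Wilson intervals, Welch t-tests from summary statistics
    and two-proportion comparisons; includes a forward simulator for
    progeny counts, per-silique ovule-fate compositions and continuous
    pollen-tube or silique-length phenotypes, plus delimited-text and
    config readers and a reproduction-report generator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
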