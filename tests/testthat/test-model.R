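test_that("gamete enumeration follows Mendelian independence", {
  loci <- two_loci()

  dhet <- enumerate_gametes(genotype(loci, "+/- +/-"))
  expect_equal(nrow(dhet), 4L)
  expect_equal(dhet$freq, rep(0.25, 4))
  expect_setequal(dhet$label, c("MIRO1:MIRO2", "miro1:MIRO2",
                                "MIRO1:miro2-2", "miro1:miro2-2"))

  het_hom <- enumerate_gametes(genotype(loci, "+/- -/-"))
  expect_equal(nrow(het_hom), 2L)
  expect_equal(het_hom$freq, rep(0.5, 2))
  expect_setequal(het_hom$label, c("MIRO1:miro2-2", "miro1:miro2-2"))

  wt <- enumerate_gametes(genotype(loci, "+/+ +/+"))
  expect_equal(nrow(wt), 1L)
  expect_equal(wt$freq, 1)

  # 2^h gametes for h heterozygous loci, frequencies always sum to 1
  for (d1 in 0:2) for (d2 in 0:2) {
    g <- enumerate_gametes(genotype(loci, c(d1, d2)))
    expect_equal(nrow(g), 2^sum(c(d1, d2) == 1L))
    expect_equal(sum(g$freq), 1)
  }
})

test_that("invalid genotypes are rejected", {
  loci <- two_loci()
  expect_error(genotype(loci, c(3, 0)), "dosage")
  expect_error(genotype(loci, c(-1, 0)), "dosage")
  expect_error(genotype(loci, "+/-"), "one '\\+/-' token per locus")
  expect_error(genotype(loci, "x/y +/-"), "tokens")
  expect_error(genotype(loci, c(MIRO1 = 1, OTHER = 0)), "locus names")
})

test_that("factorized gametes match brute-force homolog enumeration on all
          nine two-locus genotypes", {
  loci <- two_loci()
  for (d1 in 0:2) for (d2 in 0:2) {
    dos <- c(MIRO1 = d1, MIRO2 = d2)
    fact <- enumerate_gametes(genotype(loci, dos))
    fact_freq <- tapply(fact$freq, fact$label, sum)
    brute <- brute_selected(dos, loci)
    expect_equal(fact_freq[sort(names(fact_freq))],
                 brute[sort(names(brute))],
                 tolerance = 1e-12)
  }
})

test_that("gametophytic selection reweights and renormalizes", {
  loci <- two_loci()
  g <- enumerate_gametes(genotype(loci, "+/- -/-"))

  neutral <- transmission_params(loci)
  expect_equal(select_gametes(g, "male", neutral)$freq, g$freq)

  complete <- transmission_params(loci,
                                  tau_male = c("miro1:miro2-2" = 0))
  sel <- select_gametes(g, "male", complete)
  expect_equal(sel$freq[sel$label == "MIRO1:miro2-2"], 1)
  expect_equal(sel$freq[sel$label == "miro1:miro2-2"], 0)

  # female co-transmission at TE = 0.347: 0.347/1.347 of gametes mutant
  fem <- transmission_params(loci,
                             tau_female = c("miro1:miro2-2" = 0.347))
  self <- select_gametes(g, "female", fem)
  expect_equal(self$freq[self$label == "miro1:miro2-2"], 0.347 / 1.347,
               tolerance = 1e-12)
  expect_equal(self$freq[self$label == "MIRO1:miro2-2"], 1 / 1.347,
               tolerance = 1e-12)

  # all-zero selection is a degenerate cross
  dead <- transmission_params(loci,
                              tau_male = c("miro1:miro2-2" = 0,
                                           "MIRO1:miro2-2" = 0))
  expect_error(select_gametes(g, "male", dead), "degenerate")
})

test_that("progeny distribution reproduces the textbook Punnett table in the
          neutral limit", {
  loci <- two_loci()
  dhet <- cross_spec(genotype(loci, "+/- +/-"))

  # no selection, no lethality: 9:3:3:1 over marker patterns
  neutral <- transmission_params(loci)
  d0 <- progeny_distribution(dhet, neutral)
  expect_equal(d0[["viable:BASTA+kanamycin"]], 9 / 16)
  expect_equal(d0[["viable:BASTA"]], 3 / 16)
  expect_equal(d0[["viable:kanamycin"]], 3 / 16)
  expect_equal(d0[["viable:none"]], 1 / 16)

  # first-locus homozygous lethality: the explicit 16-cell table
  lethal <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
  d1 <- progeny_distribution(dhet, lethal)
  expect_equal(as.numeric(d1[names(punnett_dhet_lethal)]),
               as.numeric(punnett_dhet_lethal))
  expect_equal(d1[["aborted_seed"]], 0.25)

  # total embryo-sac failure
  sf <- transmission_params(loci,
                            sac_failure = c("MIRO1:MIRO2" = 1,
                                            "miro1:MIRO2" = 1,
                                            "MIRO1:miro2-2" = 1,
                                            "miro1:miro2-2" = 1))
  d2 <- progeny_distribution(dhet, sf)
  expect_equal(d2[["unfertilized_ovule"]], 1)
})

test_that("progeny distributions sum to 1 for random valid parameters", {
  loci <- two_loci()
  set.seed(42)
  for (rep in 1:50) {
    prm <- random_params(loci)
    mother <- genotype(loci, sample(0:2, 2, replace = TRUE))
    father <- genotype(loci, sample(0:2, 2, replace = TRUE))
    d <- try(progeny_distribution(cross_spec(mother, father), prm),
             silent = TRUE)
    if (inherits(d, "try-error")) next  # degenerate cross, valid outcome
    expect_true(all(d >= 0))
    expect_equal(sum(d), 1, tolerance = 1e-12)
  }
})

test_that("factorized distribution equals brute-force enumeration on every
          two-locus cross, with and without selection", {
  loci <- two_loci()
  tau_m <- c("miro1:miro2-2" = 0.1, "miro1:MIRO2" = 0.4)
  tau_f <- c("miro1:miro2-2" = 0.35)
  sacf <- c("miro1:miro2-2" = 0.45)
  prm <- transmission_params(loci, tau_male = tau_m, tau_female = tau_f,
                             sac_failure = sacf,
                             lethal = list(hom_tdna("MIRO1")))
  for (m1 in 0:2) for (m2 in 0:2) for (f1 in 0:2) for (f2 in 0:2) {
    mdos <- c(MIRO1 = m1, MIRO2 = m2)
    fdos <- c(MIRO1 = f1, MIRO2 = f2)
    d <- progeny_distribution(
      cross_spec(genotype(loci, mdos), genotype(loci, fdos)), prm)
    oracle <- brute_progeny(mdos, fdos, loci, tau_male = tau_m,
                            tau_female = tau_f, sac_failure = sacf,
                            lethal_hom = "MIRO1")
    expect_equal(as.numeric(d[sort(names(d))]),
                 as.numeric(oracle[sort(names(oracle))]),
                 tolerance = 1e-12)
  }
})

test_that("raising a mutant gamete's male tau never lowers the dual-resistant
          viable fraction", {
  loci <- two_loci()
  dhet <- cross_spec(genotype(loci, "+/- +/-"))
  taus <- c(0, 0.1, 0.25, 0.5, 1, 2, 5)
  frac <- vapply(taus, function(tau) {
    prm <- transmission_params(loci,
                               tau_male = c("miro1:miro2-2" = tau),
                               lethal = list(hom_tdna("MIRO1")))
    d <- progeny_distribution(dhet, prm)
    d[["viable:BASTA+kanamycin"]] / sum(d[grepl("^viable", names(d))])
  }, numeric(1))
  expect_true(all(diff(frac) >= -1e-12))
})

test_that("mother/father swap with swapped tau maps is symmetric when no
          embryo sac fails", {
  loci <- two_loci()
  a <- genotype(loci, "+/- -/-")
  b <- genotype(loci, "+/- +/-")
  tm <- c("miro1:miro2-2" = 0.1, "miro1:MIRO2" = 0.6)
  tf <- c("miro1:miro2-2" = 0.8, "MIRO1:miro2-2" = 0.3)
  d1 <- progeny_distribution(
    cross_spec(a, b),
    transmission_params(loci, tau_male = tm, tau_female = tf,
                        lethal = list(hom_tdna("MIRO1"))))
  d2 <- progeny_distribution(
    cross_spec(b, a),
    transmission_params(loci, tau_male = tf, tau_female = tm,
                        lethal = list(hom_tdna("MIRO1"))))
  expect_equal(as.numeric(d1[sort(names(d1))]),
               as.numeric(d2[sort(names(d2))]), tolerance = 1e-12)
})

test_that("expected resistant fractions reproduce the named segregation
          hypotheses", {
  loci <- two_loci()
  prm <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
  dhet <- cross_spec(genotype(loci, "+/- +/-"))

  # the 10:6 convention counts embryo-lethal zygotes in the denominator
  expect_identical(expected_resistant_fraction(dhet, prm,
                                               mode = "all_zygotes_naive"),
                   6 / 16)
  # conditioning on germinable seedlings instead
  expect_identical(expected_resistant_fraction(dhet, prm,
                                               mode = "viable_seedlings"),
                   6 / 12)

  # single-locus selfing, 2/3 of survivors carry the insertion
  l1 <- one_locus()
  p1 <- transmission_params(l1, lethal = list(hom_tdna("MIRO1")))
  expect_equal(expected_resistant_fraction(cross_spec(genotype(l1, "+/-")),
                                           p1, markers = "BASTA",
                                           mode = "viable_seedlings"),
               2 / 3, tolerance = 1e-12)

  expect_error(expected_resistant_fraction(dhet, prm, mode = "bogus"),
               "unknown conditioning mode")
})

test_that("conditional genotype fractions behave as conditional
          probabilities", {
  loci <- two_loci()
  prm <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
  dhet <- cross_spec(genotype(loci, "+/- +/-"))
  dual <- resistant_to(c("BASTA", "kanamycin"))

  # second-locus homozygotes among dual-resistant seedlings: 2:1, i.e. 1/3
  expect_equal(conditional_genotype_fraction(dhet, prm,
                                             target = hom_tdna("MIRO2"),
                                             condition = dual),
               1 / 3, tolerance = 1e-12)

  # trivial conditioning identities
  uncond <- conditional_genotype_fraction(dhet, prm, target = dual)
  d <- progeny_distribution(dhet, prm)
  expect_equal(uncond,
               d[["viable:BASTA+kanamycin"]] /
                 sum(d[grepl("^viable", names(d))]),
               tolerance = 1e-12)
  expect_equal(conditional_genotype_fraction(dhet, prm, target = dual,
                                             condition = dual), 1)

  # impossible condition: miro1 homozygotes are lethal
  expect_error(conditional_genotype_fraction(dhet, prm,
                                             target = dual,
                                             condition = hom_tdna("MIRO1")),
               "zero probability")
})

test_that("parameter validation enforces the model's domains", {
  loci <- two_loci()
  expect_error(transmission_params(loci, tau_male = c("miro1:MIRO2" = -1)),
               ">= 0")
  expect_error(transmission_params(loci, tau_male = c("bogus:label" = 1)),
               "unknown gamete")
  expect_error(transmission_params(loci,
                                   sac_failure = c("miro1:MIRO2" = 1.5)),
               "\\[0, 1\\]")
  expect_error(transmission_params(loci,
                                   tau_male = c("MIRO1:MIRO2" = 2)),
               "reference")
  expect_error(locus_set("A", "x", "x", "M"), "must differ")
  expect_error(locus_set(c("A", "B"), c("a", "b"), c("a2", "b2"),
                         c("M", "M")), "unique")
})
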