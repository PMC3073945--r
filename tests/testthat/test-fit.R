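# wild-type mother x double-mutant father: the classical reciprocal cross
# whose single-tau MLE has the closed form R/S
te_cross <- function(loci) {
  cross_spec(genotype(loci, "+/+ +/+"), genotype(loci, "+/- -/-"))
}

test_that("single-tau MLE on a reciprocal cross equals the closed-form R/S", {
  loci <- two_loci()
  for (rs in list(c(161, 464), c(50, 450), c(7, 3))) {
    fit <- fit_transmission(
      te_cross(loci),
      observed = c("viable:BASTA+kanamycin" = rs[1],
                   "viable:kanamycin" = rs[2]),
      free = "tau_male[miro1:miro2-2]")
    expect_true(fit$convergence)
    expect_equal(unname(coef(fit)), rs[1] / rs[2], tolerance = 1e-5)
    # and matches the transmission-efficiency estimator
    expect_equal(unname(coef(fit)),
                 transmission_efficiency(rs[1], rs[2])$te,
                 tolerance = 1e-5)
  }
})

test_that("boundary data give a boundary estimate with a one-sided profile
          interval", {
  loci <- two_loci()
  fit <- fit_transmission(
    te_cross(loci),
    observed = c("viable:BASTA+kanamycin" = 0, "viable:kanamycin" = 200),
    free = "tau_male[miro1:miro2-2]")
  expect_equal(unname(coef(fit)), 0, tolerance = 1e-7)
  expect_true(any(fit$at_boundary))
  ci <- confint(fit)
  expect_equal(ci[1, "lower"], 0)
  expect_gt(ci[1, "upper"], 0)
  expect_lt(ci[1, "upper"], 0.05)
})

test_that("simulated data at tau = 0.3 are recovered within sampling error", {
  loci <- two_loci()
  truth <- 0.3
  prm <- transmission_params(loci, tau_male = c("miro1:miro2-2" = truth))
  n <- 5000
  counts <- simulate_progeny(te_cross(loci), prm, n = n, seed = 2024)
  obs <- counts[c("viable:BASTA+kanamycin", "viable:kanamycin")]
  fit <- fit_transmission(te_cross(loci), observed = obs,
                          free = "tau_male[miro1:miro2-2]")
  # binomial SE mapped to the tau scale via the delta method
  p <- truth / (1 + truth)
  se_tau <- sqrt(p * (1 - p) / n) / (1 - p)^2
  expect_lt(abs(coef(fit) - truth), 3 * se_tau)
  # profile and Wald intervals agree at this n and both cover
  prof <- confint(fit, method = "profile")
  wald <- confint(fit, method = "wald")
  expect_equal(prof[1, ], wald[1, ], tolerance = 0.05)
  expect_true(prof[1, "lower"] < truth && truth < prof[1, "upper"])
})

test_that("two free parameters are jointly recovered from rich class data", {
  loci <- two_loci()
  truth <- c(0.2, 0.5)
  prm <- transmission_params(loci,
                             tau_male = c("miro1:miro2-2" = truth[1]),
                             sac_failure = c("miro1:miro2-2" = truth[2]),
                             lethal = list(hom_tdna("MIRO1")))
  cross <- cross_spec(genotype(loci, "+/- -/-"))
  counts <- simulate_progeny(cross, prm, n = 20000, seed = 99)
  fit <- fit_transmission(cross, observed = counts,
                          free = c("tau_male[miro1:miro2-2]",
                                   "sac_failure[miro1:miro2-2]"),
                          params = transmission_params(
                            loci, lethal = list(hom_tdna("MIRO1"))))
  expect_true(fit$convergence)
  expect_equal(unname(coef(fit)), truth, tolerance = 0.1)
  ci <- confint(fit)
  expect_true(all(ci[, "lower"] < truth & truth < ci[, "upper"]))
})

test_that("non-identifiable parameters raise a warning rather than passing
          silently", {
  loci <- two_loci()
  # mother "+/+ -/-" never produces a miro1-bearing egg, so its female tau
  # cannot move the likelihood
  cross <- cross_spec(genotype(loci, "+/+ -/-"), genotype(loci, "+/- -/-"))
  counts <- simulate_progeny(cross, transmission_params(loci), n = 500,
                             seed = 5)
  expect_warning(
    fit_transmission(cross, observed = counts,
                     free = "tau_female[miro1:MIRO2]"),
    "non-identifiable")
})

test_that("fit interface rejects ill-posed problems", {
  loci <- two_loci()
  obs2 <- c("viable:BASTA+kanamycin" = 10, "viable:kanamycin" = 20)
  expect_error(fit_transmission(te_cross(loci), obs2,
                                free = c("tau_male[miro1:miro2-2]",
                                         "tau_male[miro1:MIRO2]")),
               "degrees of freedom")
  expect_error(fit_transmission(te_cross(loci),
                                c("viable:BASTA" = 5,
                                  "viable:kanamycin" = 5),
                                free = "tau_male[miro1:miro2-2]"),
               "not produced by this cross")
  expect_error(fit_transmission(te_cross(loci), obs2, free = "tau_male"),
               "malformed")
  expect_error(fit_transmission(te_cross(loci), obs2,
                                free = "tau_male[MIRO1:MIRO2]"),
               "reference")
})

test_that("transfit methods are mutually consistent", {
  loci <- two_loci()
  obs <- c("viable:BASTA+kanamycin" = 161, "viable:kanamycin" = 464)
  fit <- fit_transmission(te_cross(loci), obs,
                          free = "tau_male[miro1:miro2-2]")
  expect_s3_class(fit, "transfit")
  expect_equal(nobs(fit), 625)
  expect_equal(sum(fitted(fit)), 1, tolerance = 1e-12)
  expect_equal(sum(predict(fit, type = "counts")), 625, tolerance = 1e-9)
  # at a saturated binomial fit the Pearson residuals vanish
  expect_lt(max(abs(residuals(fit))), 1e-3)
  # full-distribution prediction includes the unscored classes
  full <- predict(fit, conditioned = FALSE)
  expect_equal(sum(full), 1, tolerance = 1e-12)
  expect_true(all(names(obs) %in% names(full)))
  # simulate is reproducible and totals n
  s1 <- simulate(fit, nsim = 3, seed = 1)
  s2 <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(s1, s2)
  expect_equal(colSums(s1), rep(625, 3))
  expect_equal(as.numeric(stats::logLik(fit)),
               stats::dmultinom(obs, prob = fitted(fit), log = TRUE))
  out <- utils::capture.output(print(summary(fit)))
  expect_true(any(grepl("tau_male", out)))
})
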