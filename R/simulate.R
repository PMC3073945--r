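# deterministic sub-seed per operation label, so adding one simulation to a
# pipeline never shifts the draws of another; plain polynomial string hash,
# kept below 2^31
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

#' Simulate progeny-class counts from a cross
#'
#' Draws `n` progeny classes from the exact [progeny_distribution()] of the
#' cross (one multinomial draw). `n` is interpreted as the number of ovules
#' entering the accounting; restrict to seedling classes downstream if only
#' plate counts are wanted.
#'
#' @param cross a [cross_spec()].
#' @param params a [transmission_params()].
#' @param n number of progeny units to draw.
#' @param seed optional base seed; the draw is reproducible given the seed.
#' @return Named integer counts over the progeny classes.
#' @examples
#' loci <- miro_loci()
#' prm <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
#' simulate_progeny(cross_spec(genotype(loci, "+/- +/-")), prm,
#'                  n = 500, seed = 1)
#' @export
simulate_progeny <- function(cross, params, n, seed = NULL) {
  stopifnot(n > 0, n == round(n))
  dist <- progeny_distribution(cross, params)
  if (!is.null(seed)) set.seed(derive_seed(seed, "simulate_progeny"))
  counts <- as.integer(stats::rmultinom(1, size = n, prob = as.numeric(dist)))
  stats::setNames(counts, names(dist))
}

#' Simulate per-silique ovule-fate compositions
#'
#' Each silique holds a fixed number of ovule positions (wild-type seed set
#' is about 57 per silique); every position is an independent draw from the
#' cross's progeny-class distribution, so fates are randomly dispersed along
#' the silique. An optional Dirichlet-multinomial overdispersion knob
#' (`rho > 0`) lets class probabilities vary between siliques; it defaults
#' off, i.e. plain multinomial sampling.
#'
#' @param cross a [cross_spec()].
#' @param params a [transmission_params()].
#' @param n_siliques number of siliques.
#' @param ovules_per_silique ovule positions per silique (default 57).
#' @param rho between-silique overdispersion in `[0, 1)`; 0 = none.
#' @param seed optional base seed.
#' @return Integer matrix, one row per silique, one column per class.
#' @export
simulate_siliques <- function(cross, params, n_siliques,
                              ovules_per_silique = 57, rho = 0,
                              seed = NULL) {
  stopifnot(n_siliques > 0, ovules_per_silique > 0, rho >= 0, rho < 1)
  dist <- progeny_distribution(cross, params)
  p <- as.numeric(dist)
  if (!is.null(seed)) set.seed(derive_seed(seed, "simulate_siliques"))
  out <- matrix(0L, n_siliques, length(p),
                dimnames = list(NULL, names(dist)))
  for (s in seq_len(n_siliques)) {
    ps <- p
    if (rho > 0) {
      conc <- p * (1 - rho) / rho
      g <- stats::rgamma(length(p), shape = pmax(conc, 1e-12))
      ps <- g / sum(g)
    }
    out[s, ] <- as.integer(stats::rmultinom(1, ovules_per_silique, ps))
  }
  out
}

#' Simulate continuous length phenotypes
#'
#' Normal draws truncated at zero (by inverse-CDF sampling), for pollen-tube
#' or silique lengths specified by mean and SD. At the parameter regimes
#' reported for these phenotypes (mean at least two SDs above zero) the
#' truncation is negligible and sample moments converge to the
#' specification.
#'
#' @param mean,sd distribution parameters (same units, e.g. um or cm).
#' @param n number of draws.
#' @param seed optional base seed.
#' @return Numeric vector of non-negative lengths.
#' @examples
#' x <- simulate_lengths(436.2, 136.0, n = 1000, seed = 1)
#' @export
simulate_lengths <- function(mean, sd, n, seed = NULL) {
  stopifnot(sd >= 0, n > 0, n == round(n), mean >= 0)
  if (!is.null(seed)) set.seed(derive_seed(seed, "simulate_lengths"))
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(0, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Write a synthetic demo dataset
#'
#' Generates a complete synthetic input set in the delimited formats the
#' readers consume — a segregation count table, a silique composition
#' table and a summary-statistics table — by simulating from the two-locus
#' MIRO model at plausible transmission parameters. Useful as an end-to-end
#' fixture; all values are simulated, none copied from published tables.
#'
#' @param dir output directory (created if needed).
#' @param seed base seed; recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_demo_dataset <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  loci <- miro_loci()
  prm <- transmission_params(
    loci,
    tau_male    = c("miro1:miro2-2" = 0.0012, "miro1:MIRO2" = 0.13),
    tau_female  = c("miro1:miro2-2" = 0.35, "miro1:MIRO2" = 0.75),
    sac_failure = c("miro1:miro2-2" = 0.45),
    lethal      = list(hom_tdna("MIRO1")))
  dhet <- cross_spec(genotype(loci, "+/- +/-"))
  dh_m2 <- cross_spec(genotype(loci, "+/- -/-"))

  seg <- function(cross, id, n, op) {
    cnt <- simulate_progeny(cross, prm, n, seed = derive_seed(seed, op))
    viable <- grepl("^viable:", names(cnt))
    res <- sum(cnt[names(cnt) == "viable:BASTA+kanamycin"])
    data.frame(cross_id = id, class = c("resistant", "sensitive"),
               count = c(res, sum(cnt[viable]) - res))
  }
  counts <- rbind(seg(dhet, "dhet_self", 600, "a"),
                  seg(dh_m2, "dhet_m2hom_self", 1100, "b"))
  write_counts(counts, file.path(dir, "segregation_counts.csv"))

  sil <- simulate_siliques(dh_m2, prm, n_siliques = 20,
                           ovules_per_silique = 57,
                           seed = derive_seed(seed, "sil"))
  agg <- colSums(sil)
  viable <- grepl("^viable:", names(agg))
  sil_df <- data.frame(
    cross_id = "dhet_m2hom_self",
    class = c("unfertilized_ovule", "aborted_seed", "viable"),
    count = c(agg[["unfertilized_ovule"]],
              if ("aborted_seed" %in% names(agg)) agg[["aborted_seed"]] else 0L,
              sum(agg[viable])))
  write_counts(sil_df, file.path(dir, "silique_counts.csv"))

  tube <- rbind(
    data.frame(cross_id = "pollen_tube_um", group = "miro1_het",
               stringsAsFactors = FALSE,
               t(summarize_lengths(simulate_lengths(436.2, 136, 150,
                                                    derive_seed(seed, "t1"))))),
    data.frame(cross_id = "pollen_tube_um", group = "miro1_het_miro2_hom",
               stringsAsFactors = FALSE,
               t(summarize_lengths(simulate_lengths(178.3, 84.8, 200,
                                                    derive_seed(seed, "t2"))))))
  write_summary_stats(tube, file.path(dir, "summary_stats.csv"))

  paths <- file.path(dir, c("segregation_counts.csv", "silique_counts.csv",
                            "summary_stats.csv"))
  manifest <- run_manifest(inputs = paths, seed = seed)
  write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(c(paths, file.path(dir, "manifest.json")))
}

summarize_lengths <- function(x) {
  c(mean = mean(x), sd = stats::sd(x), n = length(x))
}
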