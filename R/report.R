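#' Segregation summary with model-derived hypotheses
#'
#' Tabulates resistant/sensitive counts per cross and, where a hypothesis
#' is supplied, the chi-square goodness of fit against it. Hypotheses are
#' expected resistant proportions (ratio strings such as "3:5" are
#' presentation only).
#'
#' @param counts count table (see [read_counts()]) with `resistant` /
#'   `sensitive` classes.
#' @param hypotheses named list, one entry per tested cross_id:
#'   `list(p = expected resistant proportion, label = "3:5")`.
#' @return Data frame: cross_id, R, S, n, pct_resistant, hypothesis,
#'   chi2, p.value.
#' @export
segregation_summary <- function(counts, hypotheses = list()) {
  ids <- unique(counts$cross_id[counts$class %in%
                                  c("resistant", "sensitive")])
  rows <- lapply(ids, function(id) {
    cd <- count_data(counts, id)
    n <- cd$R + cd$S
    hyp <- hypotheses[[id]]
    if (!is.null(hyp)) {
      gof <- chisq_gof(c(cd$R, cd$S), c(hyp$p, 1 - hyp$p))
      data.frame(cross_id = id, R = cd$R, S = cd$S, n = n,
                 pct_resistant = 100 * cd$R / n,
                 hypothesis = hyp$label, chi2 = gof$statistic,
                 p.value = gof$p.value, stringsAsFactors = FALSE)
    } else {
      data.frame(cross_id = id, R = cd$R, S = cd$S, n = n,
                 pct_resistant = 100 * cd$R / n,
                 hypothesis = NA_character_, chi2 = NA_real_,
                 p.value = NA_real_, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Silique-composition summary
#'
#' Per-cross ovule-fate accounting from a count table with classes
#' `unfertilized_ovule`, `aborted_seed` and `viable` (or `viable:*`):
#' percentages of each fate and total lethality (unfertilized + aborted).
#'
#' @param counts count table (see [read_counts()]).
#' @return Data frame: cross_id, n, unfertilized, aborted, viable counts,
#'   pct_unfertilized, pct_aborted, pct_total_lethality.
#' @export
silique_summary <- function(counts) {
  ids <- unique(counts$cross_id)
  rows <- lapply(ids, function(id) {
    sub <- counts[counts$cross_id == id, ]
    unf <- sum(sub$count[sub$class == "unfertilized_ovule"])
    ab <- sum(sub$count[sub$class == "aborted_seed"])
    vi <- sum(sub$count[sub$class == "viable" |
                          grepl("^viable:", sub$class)])
    n <- unf + ab + vi
    data.frame(cross_id = id, n = n, unfertilized = unf, aborted = ab,
               viable = vi,
               pct_unfertilized = 100 * unf / n,
               pct_aborted = 100 * ab / n,
               pct_total_lethality = 100 * (unf + ab) / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise t-tests from a summary-statistics table
#'
#' Within each `cross_id` (one measured phenotype), compares every pair of
#' groups with [welch_t_summary()].
#'
#' @param stats data frame from [read_summary_stats()].
#' @param pooled use the pooled-variance form.
#' @return Data frame: cross_id, group1, group2, t, df, p.value.
#' @export
summary_ttests <- function(stats, pooled = FALSE) {
  rows <- list()
  for (id in unique(stats$cross_id)) {
    sub <- stats[stats$cross_id == id, ]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in seq(i + 1L, nrow(sub))) {
        tt <- welch_t_summary(sub$mean[i], sub$sd[i], sub$n[i],
                              sub$mean[j], sub$sd[j], sub$n[j],
                              pooled = pooled)
        rows[[length(rows) + 1L]] <-
          data.frame(cross_id = id, group1 = sub$group[i],
                     group2 = sub$group[j], t = tt$t, df = tt$df,
                     p.value = tt$p.value, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Reproduction report
#'
#' Chains the full analysis over a set of input tables: segregation
#' chi-squares against model-derived hypotheses, a genotyped-subset test,
#' transmission efficiencies from reciprocal crosses, silique-composition
#' accounting, summary-statistic t-tests and two-proportion comparisons.
#' Every number in the report is recomputed from the inputs and the model
#' at call time.
#'
#' @param counts segregation/TE count table (see [read_counts()]); crosses
#'   with classes `target`/`other` feed the genotyped-subset and proportion
#'   sections.
#' @param silique_counts optional silique-composition count table.
#' @param summary_stats optional summary-statistics table.
#' @param model model list as returned by [load_model_config()] /
#'   [miro_model()]; used to derive the expected proportions.
#' @param hypotheses named list of segregation hypotheses (see
#'   [segregation_summary()]).
#' @param genotyped optional `list(cross_id =, p =, label =)` for a
#'   genotype-within-resistant subset tested against expected proportion
#'   `p`.
#' @param te_crosses cross_ids whose counts are reported as transmission
#'   efficiencies.
#' @param compare_proportions list of cross_id pairs (each with
#'   `target`/`other` classes) compared by [two_proportion_test()].
#' @param out optional path; the text report is written there.
#' @return A `gametrans_report`: list of section tables plus the rendered
#'   text lines; printing shows the text.
#' @export
reproduction_report <- function(counts,
                                silique_counts = NULL,
                                summary_stats = NULL,
                                model = NULL,
                                hypotheses = list(),
                                genotyped = NULL,
                                te_crosses = character(),
                                compare_proportions = list(),
                                out = NULL) {
  sections <- list()
  lines <- c("Gametophytic transmission analysis report",
             "=========================================")

  seg_ids <- setdiff(unique(counts$cross_id[counts$class %in%
                                              c("resistant", "sensitive")]),
                     te_crosses)
  if (length(seg_ids)) {
    seg <- segregation_summary(counts[counts$cross_id %in% seg_ids, ],
                               hypotheses)
    sections$segregation <- seg
    lines <- c(lines, "", "Segregation analysis", "--------------------")
    for (i in seq_len(nrow(seg))) {
      ln <- sprintf("%s: %d resistant / %d sensitive (n = %d), %s%% resistant",
                    seg$cross_id[i], seg$R[i], seg$S[i], seg$n[i],
                    format_pct(seg$pct_resistant[i] / 100))
      if (!is.na(seg$chi2[i])) {
        ln <- sprintf("%s; hypothesis %s: X2 = %.3f, p = %s",
                      ln, seg$hypothesis[i], seg$chi2[i],
                      format_pval(seg$p.value[i]))
      }
      lines <- c(lines, ln)
    }
  }

  if (!is.null(genotyped)) {
    cd <- counts[counts$cross_id == genotyped$cross_id, ]
    x <- sum(cd$count[cd$class == "target"])
    n <- sum(cd$count)
    gof <- chisq_gof(c(x, n - x), c(genotyped$p, 1 - genotyped$p))
    sections$genotyped <- data.frame(cross_id = genotyped$cross_id,
                                     x = x, n = n, pct = 100 * x / n,
                                     chi2 = gof$statistic,
                                     p.value = gof$p.value)
    lines <- c(lines, "", "Genotyped subset", "----------------",
               sprintf(paste0("%s: %d of %d plants (%s%%) carry the target",
                              " genotype; hypothesis %s: X2 = %.3f, p = %s"),
                       genotyped$cross_id, x, n, format_pct(x / n),
                       genotyped$label, gof$statistic,
                       format_pval(gof$p.value)))
  }

  if (length(te_crosses)) {
    te_rows <- lapply(te_crosses, function(id) {
      cd <- count_data(counts, id)
      te <- transmission_efficiency(cd$R, cd$S)
      data.frame(cross_id = id, R = cd$R, S = cd$S, te = te$te,
                 pct_of_total = te$pct_of_total,
                 ci_lower = te$ci[["lower"]], ci_upper = te$ci[["upper"]],
                 stringsAsFactors = FALSE)
    })
    te_tab <- do.call(rbind, te_rows)
    sections$transmission_efficiency <- te_tab
    lines <- c(lines, "", "Co-transmission efficiency (TE = R/S)",
               "-------------------------------------")
    for (i in seq_len(nrow(te_tab))) {
      lines <- c(lines, sprintf(
        "%s: TE = %.4f (%s%% of total seedlings, n = %d), 95%% CI [%.4f, %s]",
        te_tab$cross_id[i], te_tab$te[i],
        format_pct(te_tab$pct_of_total[i] / 100),
        te_tab$R[i] + te_tab$S[i], te_tab$ci_lower[i],
        if (is.finite(te_tab$ci_upper[i]))
          sprintf("%.4f", te_tab$ci_upper[i]) else "Inf"))
    }
  }

  if (!is.null(silique_counts) && nrow(silique_counts)) {
    sil <- silique_summary(silique_counts)
    sections$silique <- sil
    lines <- c(lines, "", "Silique composition", "-------------------")
    for (i in seq_len(nrow(sil))) {
      lines <- c(lines, sprintf(
        paste0("%s: n = %d ovule positions; %s%% unfertilized, ",
               "%s%% aborted, total lethality %s%%"),
        sil$cross_id[i], sil$n[i],
        format_pct(sil$pct_unfertilized[i] / 100),
        format_pct(sil$pct_aborted[i] / 100),
        format_pct(sil$pct_total_lethality[i] / 100)))
    }
  } else if (!is.null(silique_counts)) {
    lines <- c(lines, "", "Silique composition", "-------------------",
               "no data")
  }

  if (!is.null(summary_stats) && nrow(summary_stats)) {
    tt <- summary_ttests(summary_stats)
    sections$ttests <- tt
    lines <- c(lines, "", "Phenotype comparisons (Welch t)",
               "-------------------------------")
    for (i in seq_len(nrow(tt))) {
      lines <- c(lines, sprintf(
        "%s: %s vs %s: t = %.3f, df = %.1f, p = %s",
        tt$cross_id[i], tt$group1[i], tt$group2[i], tt$t[i], tt$df[i],
        format_pval(tt$p.value[i])))
    }
  } else if (!is.null(summary_stats)) {
    lines <- c(lines, "", "Phenotype comparisons (Welch t)",
               "-------------------------------", "no data")
  }

  if (length(compare_proportions)) {
    pr_rows <- lapply(compare_proportions, function(pair) {
      get_xn <- function(id) {
        cd <- counts[counts$cross_id == id, ]
        c(x = sum(cd$count[cd$class == "target"]), n = sum(cd$count))
      }
      a <- get_xn(pair[1]); b <- get_xn(pair[2])
      tp <- two_proportion_test(a[["x"]], a[["n"]], b[["x"]], b[["n"]])
      data.frame(group1 = pair[1], group2 = pair[2],
                 p1 = tp$p1, p2 = tp$p2, z = tp$z, p.value = tp$p.value,
                 stringsAsFactors = FALSE)
    })
    pr <- do.call(rbind, pr_rows)
    sections$proportions <- pr
    lines <- c(lines, "", "Two-proportion comparisons",
               "--------------------------")
    for (i in seq_len(nrow(pr))) {
      lines <- c(lines, sprintf(
        "%s (%s%%) vs %s (%s%%): z = %.3f, p = %s",
        pr$group1[i], format_pct(pr$p1[i]), pr$group2[i],
        format_pct(pr$p2[i]), pr$z[i], format_pval(pr$p.value[i])))
    }
  }

  if (is.null(sections$segregation) && is.null(sections$silique) &&
      is.null(sections$ttests)) {
    lines <- c(lines, "", "no data")
  }

  rep <- structure(list(sections = sections, lines = lines,
                        model = model), class = "gametrans_report")
  if (!is.null(out)) writeLines(lines, out)
  rep
}

#' @export
print.gametrans_report <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}

#' Demo reproduction report for the MIRO two-locus dataset
#'
#' Builds the full report from the packaged count and summary tables,
#' deriving the segregation hypotheses from the shipped model at call time:
#' the naive all-zygote expectation for dual resistance from a
#' double-heterozygote selfing (3/8, the "10:6" ratio) and the conditional
#' second-locus-homozygote fraction among dual-resistant seedlings (1/3,
#' the "2:1" ratio). TE and karyogamy counts in the fixture marked
#' "reconstructed" were back-calculated from published percentages and
#' totals, not observed directly.
#'
#' @param out optional output path for the text report.
#' @return A `gametrans_report`.
#' @export
miro_report <- function(out = NULL) {
  ext <- function(f) system.file("extdata", f, package = "gametrans")
  model <- miro_model()
  dhet <- cross_spec(genotype(model$loci, "+/- +/-"))
  neutral_lethal <- transmission_params(model$loci,
                                        lethal = list(hom_tdna("MIRO1")))
  p_naive <- expected_resistant_fraction(dhet, neutral_lethal,
                                         mode = "all_zygotes_naive")
  p_cond <- conditional_genotype_fraction(
    dhet, neutral_lethal, target = hom_tdna("MIRO2"),
    condition = resistant_to(c("BASTA", "kanamycin")))
  reproduction_report(
    counts = read_counts(ext("miro_segregation.csv")),
    silique_counts = read_counts(ext("miro_silique.csv")),
    summary_stats = read_summary_stats(ext("miro_phenotypes.csv")),
    model = model,
    hypotheses = list(dhet_self = list(p = p_naive,
                                       label = "3:5 (all zygotes, naive)")),
    genotyped = list(cross_id = "genotyped_subset", p = p_cond,
                     label = "2:1 (conditional)"),
    te_crosses = c("te_male", "te_female"),
    compare_proportions = list(c("karyogamy_miro1", "karyogamy_dhet")),
    out = out)
}
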