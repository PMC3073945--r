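#' Specify a cross
#'
#' A cross pairs a maternal and a paternal diploid genotype over the same
#' locus set; omitting `father` gives a selfing. Reciprocal crosses separate
#' male from female transmission: the mother's gametes pass through the
#' female selection and embryo-sac maturation steps, the father's through
#' male (pollen) selection.
#'
#' @param mother,father [genotype()] objects over the same [locus_set()];
#'   `father` defaults to `mother` (selfing).
#' @return A `cross_spec` object.
#' @examples
#' loci <- miro_loci()
#' cross_spec(genotype(loci, "+/- -/-"))                  # selfing
#' cross_spec(genotype(loci, "+/+ +/+"), genotype(loci, "+/- -/-"))
#' @export
cross_spec <- function(mother, father = mother) {
  stopifnot(inherits(mother, "dgenotype"), inherits(father, "dgenotype"))
  if (!identical(attr(mother, "loci"), attr(father, "loci"))) {
    stop("mother and father must be defined over the same locus set",
         call. = FALSE)
  }
  structure(list(mother = mother, father = father,
                 selfing = identical(unclass(mother), unclass(father))),
            class = "cross_spec")
}

#' @export
print.cross_spec <- function(x, ...) {
  if (x$selfing) {
    cat("Selfing of", format_genotype(x$mother), "\n")
  } else {
    cat("Cross:", format_genotype(x$mother), "(female) x",
        format_genotype(x$father), "(male)\n")
  }
  invisible(x)
}

#' Enumerate Mendelian gametes of a diploid genotype
#'
#' Loci are strictly unlinked, so gamete frequencies are products of
#' per-locus factors: 1 for a homozygous locus and 1/2 per heterozygous
#' locus. A genotype heterozygous at `h` loci yields `2^h` gametes.
#'
#' @param genotype a [genotype()].
#' @return Data frame with one 0/1 dosage column per locus, a canonical
#'   `label`, and Mendelian `freq` summing to 1.
#' @examples
#' enumerate_gametes(genotype(miro_loci(), "+/- +/-"))
#' @export
enumerate_gametes <- function(genotype) {
  stopifnot(inherits(genotype, "dgenotype"))
  loci <- attr(genotype, "loci")
  dos <- unclass(genotype)
  per_locus <- lapply(dos, function(d) switch(d + 1L, 0L, 0:1, 1L))
  grid <- expand.grid(per_locus, KEEP.OUT.ATTRS = FALSE)
  names(grid) <- loci$name
  h <- sum(dos == 1L)
  out <- as.data.frame(grid)
  out$label <- apply(as.matrix(grid), 1L, gamete_label, loci = loci)
  out$freq <- rep(0.5^h, nrow(out))
  attr(out, "loci") <- loci
  out
}

#' Apply gametophytic selection to a gamete pool
#'
#' Reweights gamete frequencies by the sex-specific relative transmission
#' efficiency of each haplotype and renormalises. This is the step a
#' transmission-efficiency (TE) measurement from a reciprocal cross probes.
#'
#' @param gametes data frame from [enumerate_gametes()].
#' @param sex `"male"` or `"female"`.
#' @param params [transmission_params()].
#' @return The gamete data frame with selected, renormalised `freq`.
#' @export
select_gametes <- function(gametes, sex = c("male", "female"), params) {
  sex <- match.arg(sex)
  stopifnot(inherits(params, "transmission_params"))
  map <- if (sex == "male") params$tau_male else params$tau_female
  w <- gametes$freq * tau_of(map, gametes$label)
  total <- sum(w)
  if (total <= 0) {
    stop("degenerate cross: every ", sex,
         " gamete of this parent has transmission efficiency 0",
         call. = FALSE)
  }
  gametes$freq <- w / total
  gametes
}

# Full ovule-fate accounting: one row per (female gamete [, male gamete])
# outcome with fate in {unfertilized_ovule, aborted_seed, viable}, the
# zygote dosage per locus (NA for unfertilized ovules), the viable-class
# label, and probability p summing to 1.
zygote_table <- function(cross, params) {
  stopifnot(inherits(cross, "cross_spec"),
            inherits(params, "transmission_params"))
  loci <- attr(cross$mother, "loci")
  if (!identical(loci, params$loci)) {
    stop("cross and params are defined over different locus sets",
         call. = FALSE)
  }
  fem <- select_gametes(enumerate_gametes(cross$mother), "female", params)
  mal <- select_gametes(enumerate_gametes(cross$father), "male", params)
  sac <- sac_of(params$sac_failure, fem$label)

  L <- loci$name
  rows <- vector("list", nrow(fem) * (nrow(mal) + 1L))
  k <- 0L
  for (i in seq_len(nrow(fem))) {
    if (sac[i] > 0) {
      k <- k + 1L
      rows[[k]] <- c(list(fate = "unfertilized_ovule",
                          class = "unfertilized_ovule",
                          p = fem$freq[i] * sac[i]),
                     stats::setNames(rep(NA_integer_, length(L)), L))
    }
    p_fert <- fem$freq[i] * (1 - sac[i])
    if (p_fert == 0) next
    for (j in seq_len(nrow(mal))) {
      dos <- as.integer(unlist(fem[i, L])) + as.integer(unlist(mal[j, L]))
      names(dos) <- L
      lethal <- any(vapply(params$lethal, function(f) isTRUE(f(dos, loci)),
                           logical(1)))
      if (lethal) {
        fate <- "aborted_seed"; cls <- "aborted_seed"
      } else {
        fate <- "viable"
        mk <- sort(loci$marker[dos[loci$name] >= 1L])
        cls <- paste0("viable:",
                      if (length(mk)) paste(mk, collapse = "+") else "none")
      }
      k <- k + 1L
      rows[[k]] <- c(list(fate = fate, class = cls, p = p_fert * mal$freq[j]),
                     as.list(dos))
    }
  }
  out <- do.call(rbind, lapply(rows[seq_len(k)], function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  attr(out, "loci") <- loci
  out
}

#' Exact progeny-class distribution of a cross
#'
#' Propagates both parents' Mendelian gamete pools through gametophytic
#' selection, embryo-sac failure, fertilization and zygotic lethality, and
#' returns the exact probability of each progeny class: unfertilized ovule,
#' aborted seed, and one viable class per resistance-marker pattern.
#'
#' @param cross a [cross_spec()].
#' @param params a [transmission_params()].
#' @return A `progeny_dist`: named probability vector (sums to 1) with the
#'   underlying zygote table attached.
#' @examples
#' loci <- miro_loci()
#' neutral <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
#' progeny_distribution(cross_spec(genotype(loci, "+/- +/-")), neutral)
#' @export
progeny_distribution <- function(cross, params) {
  zt <- zygote_table(cross, params)
  p <- tapply(zt$p, zt$class, sum)
  cls <- names(p)
  ord <- order(match(cls, c("unfertilized_ovule", "aborted_seed")), cls)
  p <- as.numeric(p)[ord]
  names(p) <- cls[ord]
  structure(p, cross = cross, zygotes = zt, class = "progeny_dist")
}

#' @export
print.progeny_dist <- function(x, digits = 4, ...) {
  print(attr(x, "cross"))
  df <- data.frame(class = names(x),
                   probability = round(as.numeric(x), digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Expected fraction of marker-resistant progeny
#'
#' Computes the model's expected proportion of progeny resistant to all
#' queried markers, under one of two conditionings:
#'
#' * `"all_zygotes_naive"` — denominator is every fertilized zygote,
#'   including embryo-lethal ones (the "10:6" convention used when expected
#'   segregation ratios are quoted against total zygotes); lethal zygotes
#'   are never counted as resistant.
#' * `"viable_seedlings"` — denominator is the viable classes only, matching
#'   what is actually scored on selective plates.
#'
#' @param cross a [cross_spec()].
#' @param params a [transmission_params()].
#' @param markers marker names to require resistance to; default all.
#' @param mode conditioning mode, see above.
#' @return A proportion in `[0, 1]`.
#' @examples
#' loci <- miro_loci()
#' prm <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
#' dhet <- cross_spec(genotype(loci, "+/- +/-"))
#' expected_resistant_fraction(dhet, prm, mode = "all_zygotes_naive") # 3/8
#' expected_resistant_fraction(dhet, prm, mode = "viable_seedlings")  # 1/2
#' @export
expected_resistant_fraction <- function(cross, params,
                                        markers = params$loci$marker,
                                        mode = c("all_zygotes_naive",
                                                 "viable_seedlings")) {
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("all_zygotes_naive", "viable_seedlings")) {
    stop("unknown conditioning mode: '", mode, "'", call. = FALSE)
  }
  mode <- match.arg(mode)
  zt <- zygote_table(cross, params)
  loci <- attr(zt, "loci")
  res_pred <- resistant_to(markers)
  fert <- zt$fate != "unfertilized_ovule"
  viable <- zt$fate == "viable"
  resistant <- viable & vapply(seq_len(nrow(zt)), function(i) {
    dos <- as.integer(unlist(zt[i, loci$name])); names(dos) <- loci$name
    viable[i] && isTRUE(res_pred(dos, loci))
  }, logical(1))
  denom <- if (mode == "all_zygotes_naive") sum(zt$p[fert]) else
    sum(zt$p[viable])
  if (denom <= 0) stop("conditioning set has zero probability",
                       call. = FALSE)
  sum(zt$p[resistant]) / denom
}

#' Conditional genotype fraction among viable progeny
#'
#' `P(target | condition)` under the viable-progeny genotype distribution of
#' a cross, e.g. the expected fraction of second-locus T-DNA homozygotes
#' among dual-resistant seedlings (the "2:1", 33.3% hypothesis for a
#' double-heterozygote selfing with first-locus embryo lethality).
#'
#' @param cross a [cross_spec()].
#' @param params a [transmission_params()].
#' @param condition,target zygote predicates (see [hom_tdna()] and friends);
#'   `condition` defaults to all viable progeny.
#' @return `P(target | condition)`.
#' @examples
#' loci <- miro_loci()
#' prm <- transmission_params(loci, lethal = list(hom_tdna("MIRO1")))
#' dhet <- cross_spec(genotype(loci, "+/- +/-"))
#' conditional_genotype_fraction(dhet, prm,
#'   condition = resistant_to(c("BASTA", "kanamycin")),
#'   target    = hom_tdna("MIRO2"))   # 1/3
#' @export
conditional_genotype_fraction <- function(cross, params,
                                          target,
                                          condition = function(dosage, loci)
                                            TRUE) {
  stopifnot(is.function(target), is.function(condition))
  zt <- zygote_table(cross, params)
  loci <- attr(zt, "loci")
  viable <- which(zt$fate == "viable")
  ok_cond <- logical(nrow(zt))
  ok_both <- logical(nrow(zt))
  for (i in viable) {
    dos <- as.integer(unlist(zt[i, loci$name])); names(dos) <- loci$name
    if (isTRUE(condition(dos, loci))) {
      ok_cond[i] <- TRUE
      ok_both[i] <- isTRUE(target(dos, loci))
    }
  }
  pc <- sum(zt$p[ok_cond])
  if (pc <= 0) {
    stop("conditioning event has zero probability under this cross",
         call. = FALSE)
  }
  sum(zt$p[ok_both]) / pc
}
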