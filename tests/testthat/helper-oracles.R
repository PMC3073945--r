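# Independent brute-force oracles and shared fixtures. These re-derive the
# model's quantities by explicit enumeration of homolog choices, never via
# the package's factorized code paths.

two_loci <- function() {
  locus_set(name        = c("MIRO1", "MIRO2"),
            wild_allele = c("MIRO1", "MIRO2"),
            tdna_allele = c("miro1", "miro2-2"),
            marker      = c("BASTA", "kanamycin"))
}

one_locus <- function() {
  locus_set("MIRO1", "MIRO1", "miro1", "BASTA")
}

# every gamete of a diploid, one row per explicit homolog choice: at each
# locus the two homologous copies are listed and one is picked, each full
# choice having probability (1/2)^L
brute_gametes <- function(dosage) {
  L <- length(dosage)
  homologs <- lapply(dosage, function(d) {
    switch(d + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  })
  picks <- expand.grid(rep(list(1:2), L), KEEP.OUT.ATTRS = FALSE)
  hap <- t(apply(picks, 1L, function(pk) {
    vapply(seq_len(L), function(l) homologs[[l]][pk[l]], integer(1))
  }))
  colnames(hap) <- names(dosage)
  data.frame(hap, p = rep((1 / 2)^L, nrow(hap)))
}

# aggregate brute gametes into haplotype frequencies after optional
# selection weights (named by gamete label)
brute_selected <- function(dosage, loci, tau_map = numeric()) {
  g <- brute_gametes(dosage)
  lab <- apply(as.matrix(g[loci$name]), 1L, function(h) {
    paste(ifelse(h == 1L, loci$tdna_allele, loci$wild_allele),
          collapse = ":")
  })
  w <- g$p * ifelse(lab %in% names(tau_map), tau_map[lab], 1)
  agg <- tapply(w, lab, sum)
  agg / sum(agg)
}

# full brute-force progeny-class distribution for a cross: explicit double
# enumeration of homolog picks for both parents, then per-zygote fate
brute_progeny <- function(mother_dos, father_dos, loci,
                          tau_male = numeric(), tau_female = numeric(),
                          sac_failure = numeric(),
                          lethal_hom = character()) {
  lab_of <- function(h) paste(ifelse(h == 1L, loci$tdna_allele,
                                     loci$wild_allele), collapse = ":")
  fg <- brute_gametes(mother_dos)
  mg <- brute_gametes(father_dos)
  fl <- apply(as.matrix(fg[loci$name]), 1L, lab_of)
  ml <- apply(as.matrix(mg[loci$name]), 1L, lab_of)
  wf <- fg$p * ifelse(fl %in% names(tau_female), tau_female[fl], 1)
  wm <- mg$p * ifelse(ml %in% names(tau_male), tau_male[ml], 1)
  wf <- wf / sum(wf)
  wm <- wm / sum(wm)
  probs <- list()
  add <- function(cls, p) {
    probs[[cls]] <<- (if (is.null(probs[[cls]])) 0 else probs[[cls]]) + p
  }
  for (i in seq_along(wf)) {
    sac <- if (fl[i] %in% names(sac_failure)) sac_failure[[fl[i]]] else 0
    if (sac > 0) add("unfertilized_ovule", wf[i] * sac)
    for (j in seq_along(wm)) {
      p <- wf[i] * (1 - sac) * wm[j]
      if (p == 0) next
      dos <- as.integer(unlist(fg[i, loci$name])) +
        as.integer(unlist(mg[j, loci$name]))
      names(dos) <- loci$name
      if (any(dos[lethal_hom] == 2L)) {
        add("aborted_seed", p)
      } else {
        mk <- sort(loci$marker[dos[loci$name] >= 1L])
        add(paste0("viable:",
                   if (length(mk)) paste(mk, collapse = "+") else "none"), p)
      }
    }
  }
  unlist(probs)
}

# random valid transmission parameters over a locus set (for property tests)
random_params <- function(loci) {
  labs <- setdiff(rownames(expand_labels(loci)),
                  paste(loci$wild_allele, collapse = ":"))
  tm <- stats::setNames(stats::runif(length(labs), 0, 2), labs)
  tf <- stats::setNames(stats::runif(length(labs), 0, 2), labs)
  sf <- stats::setNames(stats::runif(length(labs)), labs)
  lethal <- if (stats::runif(1) < 0.5) list(hom_tdna(loci$name[1])) else
    list()
  transmission_params(loci, tau_male = tm, tau_female = tf,
                      sac_failure = sf, lethal = lethal)
}

expand_labels <- function(loci) {
  L <- nrow(loci)
  m <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
  rownames(m) <- apply(m, 1L, function(h) {
    paste(ifelse(h == 1L, loci$tdna_allele, loci$wild_allele),
          collapse = ":")
  })
  m
}

# textbook Punnett distribution for the neutral double-heterozygote
# selfing with first-locus homozygous lethality: the explicit 16-cell table
punnett_dhet_lethal <- c(
  "aborted_seed"           = 4 / 16,
  "viable:BASTA"           = 2 / 16,
  "viable:BASTA+kanamycin" = 6 / 16,
  "viable:kanamycin"       = 3 / 16,
  "viable:none"            = 1 / 16
)

extdata <- function(f) system.file("extdata", f, package = "gametrans")
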