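#' Gametophytic transmission parameters
#'
#' Collects the selection and viability parameters of the model:
#' sex-specific relative transmission efficiencies per gamete haplotype,
#' per-haplotype female embryo-sac failure probabilities, and the set of
#' embryo-lethal zygote genotypes.
#'
#' Transmission efficiencies are \emph{relative}: the all-wild-type gamete is
#' the reference and is pinned at 1, which makes the parameterisation
#' identifiable within each sex. Haplotypes absent from a map default to 1
#' (taus) or 0 (sac failure).
#'
#' @param loci a [locus_set()].
#' @param tau_male,tau_female named numeric vectors of relative transmission
#'   efficiencies in `[0, Inf)`; names are gamete labels such as
#'   `"miro1:miro2-2"` (allele names in locus order, `:`-joined).
#' @param sac_failure named numeric vector of probabilities in `[0, 1]` that a
#'   female gametophyte of the given haplotype fails to mature (scored as an
#'   unfertilized ovule).
#' @param lethal list of zygote predicates (see [hom_tdna()] and friends);
#'   zygotes matching any predicate are scored as aborted seeds.
#' @return A `transmission_params` object.
#' @examples
#' loci <- miro_loci()
#' transmission_params(loci,
#'   tau_male = c("miro1:miro2-2" = 0.0012),
#'   lethal   = list(hom_tdna("MIRO1")))
#' @export
transmission_params <- function(loci, tau_male = numeric(),
                                tau_female = numeric(),
                                sac_failure = numeric(),
                                lethal = list()) {
  stopifnot(is_locus_set(loci))
  check_tau <- function(tau, what) {
    if (length(tau)) {
      if (is.null(names(tau)) || any(!nzchar(names(tau)))) {
        stop(what, " must be a named vector of gamete labels", call. = FALSE)
      }
      check_gamete_labels(names(tau), loci, what)
      if (any(!is.finite(tau)) || any(tau < 0)) {
        stop(what, " values must be finite and >= 0", call. = FALSE)
      }
      ref <- gamete_label(rep(0L, nrow(loci)), loci)
      if (ref %in% names(tau) && tau[[ref]] != 1) {
        stop("the all-wild-type gamete '", ref,
             "' is the reference and its ", what, " is fixed at 1",
             call. = FALSE)
      }
    }
    tau
  }
  tau_male <- check_tau(tau_male, "tau_male")
  tau_female <- check_tau(tau_female, "tau_female")
  if (length(sac_failure)) {
    if (is.null(names(sac_failure))) {
      stop("sac_failure must be a named vector of gamete labels",
           call. = FALSE)
    }
    check_gamete_labels(names(sac_failure), loci, "sac_failure")
    if (any(!is.finite(sac_failure)) ||
        any(sac_failure < 0 | sac_failure > 1)) {
      stop("sac_failure probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!is.list(lethal) || !all(vapply(lethal, is.function, logical(1)))) {
    stop("lethal must be a list of zygote predicate functions", call. = FALSE)
  }
  structure(list(loci = loci, tau_male = tau_male, tau_female = tau_female,
                 sac_failure = sac_failure, lethal = lethal),
            class = "transmission_params")
}

#' @export
print.transmission_params <- function(x, ...) {
  cat("Transmission parameters over", nrow(x$loci), "loci\n")
  show_map <- function(m, what, default) {
    if (!length(m)) {
      cat("  ", what, ": all ", default, " (neutral)\n", sep = "")
    } else {
      cat("  ", what, ":\n", sep = "")
      for (nm in names(m)) cat("    ", nm, " = ", format(m[[nm]]), "\n",
                               sep = "")
    }
  }
  show_map(x$tau_male, "tau_male", "1")
  show_map(x$tau_female, "tau_female", "1")
  show_map(x$sac_failure, "sac_failure", "0")
  cat("  lethal zygote predicates:", length(x$lethal), "\n")
  invisible(x)
}

# lookup with defaults: tau -> 1, sac_failure -> 0
tau_of <- function(map, labels) {
  out <- rep(1, length(labels))
  hit <- labels %in% names(map)
  out[hit] <- map[labels[hit]]
  out
}

sac_of <- function(map, labels) {
  out <- rep(0, length(labels))
  hit <- labels %in% names(map)
  out[hit] <- map[labels[hit]]
  out
}

#' Zygote genotype predicates
#'
#' Small constructors for the predicates used as lethality rules and as
#' conditioning / target sets in [conditional_genotype_fraction()]. Each
#' returns a function of `(dosage, loci)` where `dosage` is the named
#' per-locus T-DNA dosage vector of a zygote.
#'
#' * `hom_tdna(locus)` — homozygous for the T-DNA allele (dosage 2);
#' * `het_tdna(locus)` — heterozygous (dosage 1);
#' * `carries_tdna(locus)` — at least one T-DNA allele;
#' * `resistant_to(markers)` — carries at least one T-DNA allele at every
#'   locus whose marker is listed (fully penetrant marker resistance);
#' * `genotype_is(spec)` — exact dosage match against a `"+/-"`-style string
#'   or dosage vector.
#'
#' @param locus a locus name.
#' @param markers character vector of marker names.
#' @param spec genotype specification as in [genotype()].
#' @return A predicate `function(dosage, loci)` returning `TRUE`/`FALSE`.
#' @name zygote-predicates
NULL

#' @rdname zygote-predicates
#' @export
hom_tdna <- function(locus) {
  force(locus)
  function(dosage, loci) {
    stopifnot(locus %in% loci$name)
    dosage[[locus]] == 2L
  }
}

#' @rdname zygote-predicates
#' @export
het_tdna <- function(locus) {
  force(locus)
  function(dosage, loci) {
    stopifnot(locus %in% loci$name)
    dosage[[locus]] == 1L
  }
}

#' @rdname zygote-predicates
#' @export
carries_tdna <- function(locus) {
  force(locus)
  function(dosage, loci) {
    stopifnot(locus %in% loci$name)
    dosage[[locus]] >= 1L
  }
}

#' @rdname zygote-predicates
#' @export
resistant_to <- function(markers) {
  force(markers)
  function(dosage, loci) {
    idx <- match(markers, loci$marker)
    if (anyNA(idx)) stop("unknown marker(s): ",
                         paste(markers[is.na(idx)], collapse = ", "),
                         call. = FALSE)
    all(dosage[loci$name[idx]] >= 1L)
  }
}

#' @rdname zygote-predicates
#' @export
genotype_is <- function(spec) {
  force(spec)
  function(dosage, loci) {
    target <- genotype(loci, spec)
    all(dosage == unclass(target))
  }
}
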