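#' Define a set of biallelic T-DNA loci
#'
#' Each locus carries a wild-type allele and a T-DNA insertion allele; the
#' insertion is strictly linked to a selectable resistance marker (e.g. BASTA
#' for \emph{miro1}, kanamycin for \emph{miro2-2}). Marker resistance is
#' treated as fully penetrant, so a zygote is resistant to a marker exactly
#' when it carries at least one copy of that locus's T-DNA allele.
#'
#' @param name character vector of locus names (unique).
#' @param wild_allele character vector of wild-type allele names.
#' @param tdna_allele character vector of T-DNA allele names; must differ from
#'   the wild-type allele at the same locus.
#' @param marker character vector of resistance-marker names, unique across
#'   loci.
#' @return A `locus_set`: a data frame with one row per locus, in model order.
#' @examples
#' loci <- locus_set(
#'   name        = c("MIRO1", "MIRO2"),
#'   wild_allele = c("MIRO1", "MIRO2"),
#'   tdna_allele = c("miro1", "miro2-2"),
#'   marker      = c("BASTA", "kanamycin")
#' )
#' @export
locus_set <- function(name, wild_allele, tdna_allele, marker) {
  stopifnot(is.character(name), is.character(wild_allele),
            is.character(tdna_allele), is.character(marker))
  n <- length(name)
  if (length(wild_allele) != n || length(tdna_allele) != n ||
      length(marker) != n) {
    stop("all locus fields must have the same length", call. = FALSE)
  }
  if (anyDuplicated(name)) stop("locus names must be unique", call. = FALSE)
  if (any(wild_allele == tdna_allele)) {
    stop("wild-type and T-DNA alleles must differ at every locus",
         call. = FALSE)
  }
  if (anyDuplicated(marker)) {
    stop("resistance markers must be unique across loci", call. = FALSE)
  }
  out <- data.frame(name = name, wild_allele = wild_allele,
                    tdna_allele = tdna_allele, marker = marker,
                    stringsAsFactors = FALSE)
  class(out) <- c("locus_set", "data.frame")
  out
}

#' @export
print.locus_set <- function(x, ...) {
  cat("Locus set (", nrow(x), " biallelic loci):\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

is_locus_set <- function(x) inherits(x, "locus_set")

#' Construct a diploid genotype over a locus set
#'
#' Genotypes are stored as the per-locus T-DNA allele dosage (0 = homozygous
#' wild type, 1 = heterozygous, 2 = homozygous insertion). `spec` may be a
#' numeric dosage vector (in locus order, or named by locus) or a character
#' string of per-locus tokens such as `"+/- -/-"`, where `+` is the wild-type
#' and `-` the T-DNA allele.
#'
#' @param loci a [locus_set()].
#' @param spec dosage vector or `"+/-"`-style string, one token per locus.
#' @return A `dgenotype`: named integer dosage vector with the locus set
#'   attached.
#' @examples
#' loci <- miro_loci()
#' genotype(loci, "+/- -/-")   # miro1 (+/-) / miro2-2 (-/-)
#' genotype(loci, c(MIRO1 = 1, MIRO2 = 2))
#' @export
genotype <- function(loci, spec) {
  stopifnot(is_locus_set(loci))
  if (is.character(spec)) {
    stopifnot(length(spec) == 1L)
    tok <- strsplit(trimws(spec), "[,[:space:]]+")[[1]]
    if (length(tok) != nrow(loci)) {
      stop("genotype string must have one '+/-' token per locus (",
           nrow(loci), " expected)", call. = FALSE)
    }
    if (!all(grepl("^[+-]/[+-]$", tok))) {
      stop("genotype tokens must look like '+/+', '+/-' or '-/-'",
           call. = FALSE)
    }
    dos <- vapply(tok, function(t) {
      sum(strsplit(t, "/")[[1]] == "-")
    }, integer(1))
  } else {
    dos <- spec
    if (!is.null(names(dos))) {
      if (!setequal(names(dos), loci$name)) {
        stop("dosage names must match the locus names exactly", call. = FALSE)
      }
      dos <- dos[loci$name]
    }
    if (length(dos) != nrow(loci)) {
      stop("dosage vector must have one entry per locus", call. = FALSE)
    }
  }
  dos <- as.integer(dos)
  if (any(is.na(dos)) || any(dos < 0L | dos > 2L)) {
    stop("invalid genotype: T-DNA dosage must be 0, 1 or 2 at every locus",
         call. = FALSE)
  }
  names(dos) <- loci$name
  structure(dos, loci = loci, class = "dgenotype")
}

#' @export
print.dgenotype <- function(x, ...) {
  cat(format_genotype(x), "\n")
  invisible(x)
}

#' Format a diploid genotype as an allele-pair string
#'
#' @param g a [genotype()].
#' @return Single string, e.g. `"MIRO1/miro1 miro2-2/miro2-2"`.
#' @export
format_genotype <- function(g) {
  loci <- attr(g, "loci")
  paste(vapply(seq_len(nrow(loci)), function(i) {
    a <- switch(unclass(g)[i] + 1L,
                c(loci$wild_allele[i], loci$wild_allele[i]),
                c(loci$wild_allele[i], loci$tdna_allele[i]),
                c(loci$tdna_allele[i], loci$tdna_allele[i]))
    paste(a, collapse = "/")
  }, character(1)), collapse = " ")
}

# canonical label of a haploid gamete: allele names in locus order, ":"-joined
gamete_label <- function(g, loci) {
  paste(ifelse(g == 1L, loci$tdna_allele, loci$wild_allele), collapse = ":")
}

# all 2^L gamete haplotypes of a locus set as a 0/1 matrix with labels
all_gametes <- function(loci) {
  L <- nrow(loci)
  m <- as.matrix(expand.grid(rep(list(0:1), L), KEEP.OUT.ATTRS = FALSE))
  colnames(m) <- loci$name
  rownames(m) <- apply(m, 1L, gamete_label, loci = loci)
  m
}

# validate that user-supplied names in a tau / sac_failure map are real
# gamete labels of this locus set
check_gamete_labels <- function(labels, loci, what) {
  valid <- rownames(all_gametes(loci))
  bad <- setdiff(labels, valid)
  if (length(bad)) {
    stop(what, " refers to unknown gamete haplotype(s): ",
         paste(bad, collapse = ", "), "; valid labels are: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' The two-locus MIRO1/MIRO2 locus set
#'
#' Convenience constructor for the standard model: \emph{miro1} is a T-DNA
#' insertion in \emph{MIRO1} linked to BASTA resistance, \emph{miro2-2} an
#' insertion in \emph{MIRO2} linked to kanamycin resistance. The loci lie on
#' separate chromosomes and are modelled as strictly unlinked.
#'
#' @return A [locus_set()] with the two MIRO loci.
#' @export
miro_loci <- function() {
  locus_set(name        = c("MIRO1", "MIRO2"),
            wild_allele = c("MIRO1", "MIRO2"),
            tdna_allele = c("miro1", "miro2-2"),
            marker      = c("BASTA", "kanamycin"))
}
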