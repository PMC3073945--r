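# class labels accepted in count tables: plate scoring (resistant /
# sensitive), ovule-fate scoring, genotyped/phenotyped subsets (target /
# other), and explicit viable marker patterns
count_class_vocabulary <- function() {
  c("resistant", "sensitive", "viable", "aborted_seed",
    "unfertilized_ovule", "target", "other")
}

valid_count_class <- function(x) {
  x %in% count_class_vocabulary() | grepl("^viable:", x)
}

# delimiter sniffing on the header: comma or tab, never guessed when both
# (or neither) occur
sniff_delim <- function(path) {
  raw <- readLines(path, warn = FALSE)
  body <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  if (!length(body)) {
    stop("empty input file: ", path, call. = FALSE)
  }
  header <- body[1L]
  has_tab <- grepl("\t", header, fixed = TRUE)
  has_comma <- grepl(",", header, fixed = TRUE)
  if (has_tab && has_comma) {
    stop("ambiguous delimiter in ", path,
         ": header contains both tab and comma", call. = FALSE)
  }
  if (!has_tab && !has_comma) {
    stop("cannot determine delimiter of ", path,
         ": header contains neither tab nor comma", call. = FALSE)
  }
  if (has_tab) "\t" else ","
}

#' Read a progeny-class count table
#'
#' Delimited text (comma or tab, auto-detected from the header) with
#' columns `cross_id`, `class`, `count`; one row per class per cross.
#' Lines starting with `#` are comments. Validation failures report the
#' offending file line numbers.
#'
#' @param path file path.
#' @return Data frame with columns `cross_id`, `class`, `count`.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "\"")
  need <- c("cross_id", "class", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # physical line numbers: header + preceding comment lines are skipped by
  # read.table, so reconstruct from the raw file
  raw <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*#", raw) & nzchar(trimws(raw)))[-1L]
  line_of <- function(i) if (i <= length(body)) body[i] else NA_integer_
  bad <- which(!valid_count_class(df$class))
  if (length(bad)) {
    stop("unknown class label(s) in ", path, ": ",
         paste(sprintf("'%s' (line %d)", df$class[bad],
                       vapply(bad, line_of, integer(1))), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(df$count) || any(is.na(df$count)) ||
      any(df$count < 0) || any(df$count != round(df$count))) {
    bad <- which(is.na(df$count) | df$count < 0 | df$count != round(df$count))
    stop("invalid count(s) in ", path, " at line(s) ",
         paste(vapply(bad, line_of, integer(1)), collapse = ", "),
         ": counts must be non-negative integers", call. = FALSE)
  }
  dup <- which(duplicated(df[c("cross_id", "class")]))
  if (length(dup)) {
    stop("duplicate (cross_id, class) row(s) in ", path, " at line(s) ",
         paste(vapply(dup, line_of, integer(1)), collapse = ", "),
         call. = FALSE)
  }
  df$count <- as.integer(df$count)
  df[need]
}

#' @rdname read_counts
#' @param df data frame with columns `cross_id`, `class`, `count`.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_counts <- function(df, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("cross_id", "class", "count") %in% names(df)))
  utils::write.table(df[c("cross_id", "class", "count")], path,
                     sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract resistant/sensitive counts for one cross
#'
#' @param counts data frame from [read_counts()].
#' @param cross_id cross identifier.
#' @return List with `R` and `S`.
#' @export
count_data <- function(counts, cross_id) {
  sub <- counts[counts$cross_id == cross_id, ]
  if (!nrow(sub)) stop("no rows for cross_id '", cross_id, "'",
                       call. = FALSE)
  get1 <- function(cls) {
    i <- sub$class == cls
    if (any(i)) sum(sub$count[i]) else 0L
  }
  list(R = get1("resistant"), S = get1("sensitive"))
}

#' Read or write a summary-statistics table
#'
#' Columns `cross_id`, `group`, `mean`, `sd`, `n`: one row per measured
#' group (e.g. pollen-tube lengths of one genotype).
#'
#' @param path file path.
#' @return Data frame with the five columns.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("cross_id", "group", "mean", "sd", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$sd < 0)) stop("negative sd in ", path, call. = FALSE)
  if (any(df$n < 2)) stop("n must be >= 2 in ", path, call. = FALSE)
  df[need]
}

#' @rdname read_summary_stats
#' @param df data frame with columns `cross_id`, `group`, `mean`, `sd`, `n`.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_summary_stats <- function(df, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  need <- c("cross_id", "group", "mean", "sd", "n")
  stopifnot(all(need %in% names(df)))
  utils::write.table(df[need], path,
                     sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a transmission-model configuration
#'
#' YAML document describing the loci, the transmission parameters and the
#' crosses of a model. Schema:
#'
#' ```yaml
#' loci:
#'   - {name: MIRO1, wild_allele: MIRO1, tdna_allele: miro1, marker: BASTA}
#'   - {name: MIRO2, wild_allele: MIRO2, tdna_allele: miro2-2,
#'      marker: kanamycin}
#' params:                      # optional; omitted maps are neutral
#'   tau_male:   {"miro1:miro2-2": 0.0012}
#'   tau_female: {"miro1:miro2-2": 0.35}
#'   sac_failure: {"miro1:miro2-2": 0.45}
#'   lethal:
#'     - {locus: MIRO1, state: hom_tdna}
#' crosses:
#'   - {id: dhet_self, mother: "+/- +/-"}          # selfing
#'   - {id: te_male, mother: "+/+ +/+", father: "+/- -/-"}
#' ```
#'
#' Genotype strings use one `+/-` token per locus, in locus order (`+` =
#' wild-type allele, `-` = T-DNA allele). Missing `params` blocks default
#' to the neutral model (all taus 1, no sac failure, no lethality) and a
#' message records each default filled in.
#'
#' @param path YAML file path.
#' @param quiet suppress messages about defaults filled in.
#' @return List with `loci` ([locus_set()]), `params`
#'   ([transmission_params()]) and `crosses` (named list of [cross_spec()]).
#' @export
load_model_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$loci)) stop("config has no 'loci' block", call. = FALSE)
  get_field <- function(x, f) {
    v <- x[[f]]
    if (is.null(v)) stop("locus entry missing field '", f, "'",
                         call. = FALSE)
    as.character(v)
  }
  loci <- locus_set(
    name        = vapply(cfg$loci, get_field, character(1), "name"),
    wild_allele = vapply(cfg$loci, get_field, character(1), "wild_allele"),
    tdna_allele = vapply(cfg$loci, get_field, character(1), "tdna_allele"),
    marker      = vapply(cfg$loci, get_field, character(1), "marker"))

  note <- function(...) if (!quiet) message(...)
  pm <- cfg$params
  as_map <- function(x) {
    if (is.null(x)) return(numeric())
    stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
  }
  if (is.null(pm)) note("config has no 'params' block: using neutral model")
  lethal <- list()
  if (!is.null(pm$lethal)) {
    lethal <- lapply(pm$lethal, function(entry) {
      locus <- entry$locus
      if (is.null(locus) || !locus %in% loci$name) {
        stop("lethal rule refers to unknown locus: ",
             if (is.null(locus)) "<missing>" else locus, call. = FALSE)
      }
      state <- if (is.null(entry$state)) "hom_tdna" else entry$state
      switch(state,
             hom_tdna = hom_tdna(locus),
             het_tdna = het_tdna(locus),
             carries_tdna = carries_tdna(locus),
             stop("unknown lethal state '", state, "'", call. = FALSE))
    })
  } else {
    note("no lethal zygote rules: all fertilized zygotes viable")
  }
  params <- transmission_params(loci,
                                tau_male = as_map(pm$tau_male),
                                tau_female = as_map(pm$tau_female),
                                sac_failure = as_map(pm$sac_failure),
                                lethal = lethal)

  crosses <- list()
  if (!is.null(cfg$crosses)) {
    ids <- vapply(cfg$crosses, function(x) as.character(x$id), character(1))
    if (anyDuplicated(ids)) stop("duplicate cross ids in config",
                                 call. = FALSE)
    crosses <- stats::setNames(lapply(cfg$crosses, function(x) {
      if (is.null(x$mother)) stop("cross '", x$id, "' has no mother",
                                  call. = FALSE)
      mother <- genotype(loci, x$mother)
      father <- if (is.null(x$father)) mother else genotype(loci, x$father)
      cross_spec(mother, father)
    }), ids)
  }
  list(loci = loci, params = params, crosses = crosses)
}

#' The shipped two-locus MIRO model configuration
#'
#' Loads the packaged config for the \emph{miro1}/\emph{miro2-2} T-DNA
#' model: BASTA resistance linked to \emph{miro1}, kanamycin to
#' \emph{miro2-2}, first-locus homozygotes embryo-lethal.
#'
#' @return See [load_model_config()].
#' @export
miro_model <- function() {
  load_model_config(system.file("extdata", "miro_model.yaml",
                                package = "gametrans"),
                    quiet = TRUE)
}

#' Run manifests
#'
#' A manifest records everything needed to re-derive a pipeline output:
#' input-file MD5 digests, the seed, the package version and a timestamp.
#'
#' @param inputs character vector of input file paths.
#' @param seed the RNG seed used (or `NA`).
#' @param extra optional named list merged into the manifest.
#' @return List of manifest fields.
#' @export
run_manifest <- function(inputs = character(), seed = NA, extra = list()) {
  digests <- if (length(inputs)) {
    d <- tools::md5sum(inputs)
    stats::setNames(as.character(d), basename(names(d)))
  } else list()
  c(list(package = "gametrans",
         version = as.character(utils::packageVersion("gametrans")),
         seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         inputs = as.list(digests)),
    extra)
}

#' @rdname run_manifest
#' @param manifest a manifest list.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
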