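# Pyrimidine-centered substitution classification and per-isolate spectra.

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Classify a substitution into the six pyrimidine-centered classes
#'
#' Purine reference bases are complemented (together with their alternate)
#' before classification, so that each substitution and its reverse complement
#' fall in the same class: G&rarr;T is reported as C&gt;A.
#'
#' @param ref,alt Reference and alternate bases (A, C, G or T), vectorised.
#' @return Character vector over `"C>A"`, `"C>G"`, `"C>T"`, `"T>A"`, `"T>C"`,
#'   `"T>G"`.
#' @examples
#' classify_substitution(c("G", "C", "A"), c("T", "T", "G"))
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(ref %in% BASES) || !all(alt %in% BASES)) {
    abort("ref and alt must be single bases in A, C, G, T")
  }
  if (any(ref == alt)) abort("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  out <- paste0(ref, ">", alt)
  stopifnot(all(out %in% SPECTRUM_CLASSES))
  out
}

#' Pyrimidine-centered trinucleotide context of SNVs
#'
#' Adds the reference trinucleotide centered on each call, reverse-
#' complemented when the reference base is a purine so the center is always a
#' pyrimidine. Positions at contig ends are padded with `N`.
#'
#' @param calls Tibble of SNV calls (`contig`, `pos`, `ref`, ...).
#' @param genome A `mut_genome`.
#' @return `calls` with an added `context` column.
#' @export
mut_context <- function(calls, genome) {
  genome <- as_genome(genome)
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    calls$context <- character(0)
    return(calls)
  }
  if (!all(is_snv(toupper(calls$ref), toupper(calls$alt)))) {
    abort("mut_context() requires SNV calls")
  }
  seqs <- unclass(genome)[match(calls$contig, names(genome))]
  if (anyNA(seqs)) abort(paste0("unknown contig: ",
                                calls$contig[is.na(seqs)][1]))
  len <- nchar(seqs)
  if (any(calls$pos < 1 | calls$pos > len)) abort("position out of range")
  ctx <- paste0(
    ifelse(calls$pos > 1, substr(seqs, calls$pos - 1, calls$pos - 1), "N"),
    substr(seqs, calls$pos, calls$pos),
    ifelse(calls$pos < len, substr(seqs, calls$pos + 1, calls$pos + 1), "N")
  )
  center <- substr(ctx, 2, 2)
  flip <- center %in% c("A", "G")
  ctx[flip] <- rev_comp(ctx[flip])
  calls$context <- ctx
  calls
}

#' Per-isolate mutation spectrum
#'
#' Tabulates filtered SNVs into the six pyrimidine-centered substitution
#' classes per sample; with `by_context = TRUE` (and a genome) the table is
#' additionally stratified by the 16 pyrimidine-centered trinucleotide
#' contexts (96 strata). Context strata touching a contig end (context
#' containing `N`) are excluded from the 96-class table.
#'
#' @param calls Tibble of SNV calls across samples.
#' @param genome A `mut_genome`; required only when `by_context = TRUE`.
#' @param by_context Stratify by trinucleotide context?
#' @return An object of class `mut_spectrum`: a tibble with columns `sample`,
#'   `class` (and `context`), `n`, complete over all samples and classes.
#' @export
mutation_spectrum <- function(calls, genome = NULL, by_context = FALSE) {
  calls <- as_tibble(calls)
  if (nrow(calls) > 0 && !all(is_snv(toupper(calls$ref), toupper(calls$alt)))) {
    abort("mutation_spectrum() requires SNV calls")
  }
  samples <- unique(calls$sample)
  if (nrow(calls) == 0) {
    out <- tidyr::expand_grid(sample = character(0), class = SPECTRUM_CLASSES, n = 0L)
  } else {
    calls$class <- classify_substitution(calls$ref, calls$alt)
    if (by_context) {
      if (is.null(genome)) abort("by_context = TRUE requires a genome")
      calls <- mut_context(calls, genome)
      calls <- calls[!stringr::str_detect(calls$context, "N"), , drop = FALSE]
      out <- calls %>%
        count(.data$sample, .data$class, .data$context) %>%
        tidyr::complete(sample = samples,
                        class = SPECTRUM_CLASSES,
                        context = all_contexts(),
                        fill = list(n = 0L)) %>%
        filter(substr(.data$context, 2, 2) == substr(.data$class, 1, 1))
    } else {
      out <- calls %>%
        count(.data$sample, .data$class) %>%
        tidyr::complete(sample = samples, class = SPECTRUM_CLASSES,
                        fill = list(n = 0L))
    }
  }
  structure(out, class = c("mut_spectrum", class(out)))
}

all_contexts <- function() {
  grid <- tidyr::expand_grid(p5 = BASES, center = PYRIMIDINES, p3 = BASES)
  paste0(grid$p5, grid$center, grid$p3)
}

#' Cohort summary of a mutation spectrum
#'
#' Mean count per isolate for each substitution class (and context, if
#' present), plus the cohort total. The mean is the arithmetic mean over the
#' samples present in the table.
#'
#' @param spectrum A `mut_spectrum`.
#' @return A tibble with columns `class` (and `context`), `total`,
#'   `mean_per_isolate`.
#' @export
spectrum_summary <- function(spectrum) {
  stopifnot(inherits(spectrum, "mut_spectrum"))
  d <- as_tibble(spectrum)
  n_iso <- length(unique(d$sample))
  grp <- intersect(c("class", "context"), names(d))
  d %>%
    group_by(across(dplyr::all_of(grp))) %>%
    summarise(total = sum(.data$n),
              mean_per_isolate = sum(.data$n) / n_iso,
              .groups = "drop")
}

#' @export
tidy.mut_spectrum <- function(x, ...) as_tibble(x)

#' @export
glance.mut_spectrum <- function(x, ...) {
  d <- as_tibble(x)
  tibble(
    n_samples = length(unique(d$sample)),
    n_mutations = sum(d$n),
    mean_per_isolate = sum(d$n) / max(1L, length(unique(d$sample)))
  )
}

#' Write a mutation spectrum as long-format TSV
#'
#' @param spectrum A `mut_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  readr::write_tsv(as_tibble(spectrum), path, progress = FALSE)
  invisible(path)
}
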