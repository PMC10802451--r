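# The core statistic: motif fold-enrichment of class mutations relative to
# sequence opportunity, a one-sided Fisher's exact test, and the motif-
# attributable mutation load.

#' One-sided Fisher's exact test for motif over-representation
#'
#' Exact one-sided p-value for over-representation of the motif among
#' mutations relative to contexts, on the 2x2 table
#' `[[m_motif, m_class - m_motif], [x_motif, x_class - x_motif]]`.
#' Conditional on the margins this is the upper hypergeometric tail
#' `P(X >= m_motif)`. Degenerate tables (a zero margin) return `p = 1`.
#' Vectorised over all four counts.
#'
#' @param m_motif Motif-matching class mutations.
#' @param m_class All class mutations.
#' @param x_motif Motif context opportunities.
#' @param x_class All base-class context opportunities.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_one_sided(8, 10, 100, 1000)
#' @export
fisher_one_sided <- function(m_motif, m_class, x_motif, x_class) {
  if (any(m_motif < 0 | x_motif < 0 | m_motif > m_class | x_motif > x_class)) {
    abort("counts must satisfy 0 <= m_motif <= m_class and 0 <= x_motif <= x_class")
  }
  # White balls = motif column, draws = mutation row.
  k <- m_motif + x_motif
  total <- m_class + x_class
  p <- phyper(m_motif - 1, k, total - k, m_class, lower.tail = FALSE)
  pmin(1, pmax(p, .Machine$double.xmin))
}

#' Motif-attributable mutation load
#'
#' The number of motif-matching mutations attributable to the signature,
#' `m_motif * (E - 1) / E`, floored at 0 when the enrichment is at most 1 and
#' equal to `m_motif` in the infinite-enrichment limit. Vectorised.
#'
#' @param m_motif Count of motif-matching class mutations.
#' @param enrichment Fold-enrichment E (> 0; may be `Inf`).
#' @return Numeric vector, in `[0, m_motif]`.
#' @examples
#' mutation_load(10, 2)
#' @export
mutation_load <- function(m_motif, enrichment) {
  if (any(is.na(enrichment))) abort("enrichment is undefined (NA)")
  if (any(enrichment <= 0)) abort("enrichment must be > 0")
  n <- max(length(m_motif), length(enrichment))
  m <- rep_len(m_motif, n)
  e <- rep_len(enrichment, n)
  load <- ifelse(is.infinite(e), m, m * (e - 1) / e)
  pmax(0, load)
}

# Which class calls match the motif, strand-aware: the reference pyrimidine
# with its canonical pattern on the forward strand, or the complementary
# purine with the reverse-complemented pattern.
matches_motif <- function(calls, genome, motif) {
  if (nrow(calls) == 0) return(logical(0))
  seqs <- unclass(genome)[match(calls$contig, names(genome))]
  len <- nchar(seqs)
  fwd_start <- calls$pos - (motif$up - 1L)
  fwd_end <- calls$pos + (motif$size - motif$up)
  rev_start <- calls$pos - (motif$size - motif$up)
  rev_end <- calls$pos + (motif$up - 1L)
  is_pyr <- calls$ref == motif$from
  start <- ifelse(is_pyr, fwd_start, rev_start)
  end <- ifelse(is_pyr, fwd_end, rev_end)
  ctx <- substr(seqs, pmax(1, start), pmin(len, end))
  in_range <- start >= 1 & end <= len
  pat <- ifelse(is_pyr,
                paste0("^", motif$forward_regex, "$"),
                paste0("^", motif$reverse_regex, "$"))
  in_range & stringr::str_detect(ctx, pat)
}

enrich_one <- function(calls, genome, motif, flank, opp) {
  class_label <- classify_substitution(motif$from, motif$to)
  if (nrow(calls) > 0) {
    cls <- classify_substitution(calls$ref, calls$alt)
    calls <- calls[cls == class_label, , drop = FALSE]
  }
  m_class <- nrow(calls)
  if (m_class == 0) {
    return(tibble(m_motif = 0L, m_class = 0L,
                  x_motif = opp$x_motif %||% NA_integer_,
                  x_class = opp$x_class %||% NA_integer_,
                  enrichment = NA_real_, p_value = NA_real_, load = NA_real_,
                  note = "no_class_mutations"))
  }
  m_motif <- sum(matches_motif(calls, genome, motif))
  if (is.null(opp)) {
    w <- context_window(genome, calls$contig, calls$pos, flank = flank)
    cc <- count_contexts(w$window, motif)
  } else {
    cc <- opp
  }
  note <- NA_character_
  if (cc$x_motif == 0 || cc$x_class == 0) {
    enrichment <- if (m_motif > 0) Inf else NA_real_
    note <- if (m_motif > 0) "infinite_enrichment" else "degenerate_table"
  } else {
    enrichment <- (m_motif / m_class) / (cc$x_motif / cc$x_class)
  }
  p <- fisher_one_sided(m_motif, m_class, cc$x_motif, cc$x_class)
  load <- if (is.na(enrichment)) {
    NA_real_
  } else if (enrichment <= 0) {
    0
  } else {
    mutation_load(m_motif, enrichment)
  }
  tibble(m_motif = as.integer(m_motif), m_class = as.integer(m_class),
         x_motif = as.integer(cc$x_motif), x_class = as.integer(cc$x_class),
         enrichment = enrichment, p_value = p, load = load, note = note)
}

#' Motif fold-enrichment of class mutations
#'
#' For each sample (or for the pooled cohort), selects the mutations of the
#' motif's pyrimidine-folded substitution class (for gCn&rarr;A: C&rarr;A and
#' G&rarr;T), counts those whose strand-aware reference context matches the
#' motif, measures the motif and base-class opportunity, and reports the
#' fold-enrichment
#' `E = (m_motif / m_class) / (x_motif / x_class)`,
#' a one-sided Fisher's exact p-value, and the motif-attributable load.
#'
#' With `opportunity = "window"` (default) the opportunity counts come from
#' windows of `flank` bp on each side of every class mutation (overlapping
#' windows counted with multiplicity, the mutated base included); with
#' `"genome"` they are the genome-wide occurrence counts.
#'
#' @param calls Tibble of filtered SNV calls (columns `sample`, `contig`,
#'   `pos`, `ref`, `alt`).
#' @param genome A `mut_genome`.
#' @param motif A [motif()] object (default gCn&rarr;A).
#' @param flank Window flank in bp (default 20).
#' @param opportunity `"window"` or `"genome"`.
#' @param pooled Pool all samples into a single result?
#' @param adjust Add Benjamini-Hochberg adjusted q-values across samples?
#' @return An object of class `mut_enrichment`: a tibble with one row per
#'   sample (or one pooled row) and columns `sample`, `m_motif`, `m_class`,
#'   `x_motif`, `x_class`, `enrichment`, `p_value` (and `q_value`), `load`,
#'   `note`. Samples without class mutations get `NA` enrichment, p and load,
#'   flagged in `note`.
#' @export
motif_enrichment <- function(calls, genome, motif = mutmotif::motif(),
                             flank = 20, opportunity = c("window", "genome"),
                             pooled = FALSE, adjust = FALSE) {
  opportunity <- match.arg(opportunity)
  genome <- as_genome(genome)
  stopifnot(is_mut_motif(motif))
  calls <- validate_calls(calls)
  if (nrow(calls) > 0 && !all(is_snv(calls$ref, calls$alt))) {
    abort("motif_enrichment() requires SNV calls; run apply_filters() first")
  }
  opp <- if (opportunity == "genome") genome_opportunity(genome, motif) else NULL

  if (pooled) {
    out <- enrich_one(calls, genome, motif, flank, opp)
    out <- mutate(out, sample = "pooled", .before = 1)
  } else {
    groups <- split(calls, calls$sample)
    out <- purrr::map(groups, enrich_one, genome = genome, motif = motif,
                      flank = flank, opp = opp)
    out <- bind_rows(out, .id = "sample")
  }
  if (adjust) {
    out$q_value <- p.adjust(out$p_value, method = "BH")
  }
  structure(out,
            motif = motif$label, flank = flank, opportunity = opportunity,
            class = c("mut_enrichment", class(out)))
}

#' @export
tidy.mut_enrichment <- function(x, ...) as_tibble(x)

#' @export
glance.mut_enrichment <- function(x, alpha = 0.05, ...) {
  d <- as_tibble(x)
  tibble(
    n_samples = nrow(d),
    n_significant = sum(d$p_value < alpha & d$enrichment > 1, na.rm = TRUE),
    median_enrichment = median(d$enrichment[is.finite(d$enrichment)], na.rm = TRUE),
    total_load = sum(d$load, na.rm = TRUE),
    motif = attr(x, "motif"),
    opportunity = attr(x, "opportunity")
  )
}

#' Write enrichment results as TSV
#'
#' @param enrichment A `mut_enrichment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  readr::write_tsv(as_tibble(enrichment), path, progress = FALSE)
  invisible(path)
}
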