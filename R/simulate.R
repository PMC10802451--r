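# Seeded generators for every input the pipeline consumes: toy genomes,
# isolate cohorts with a known planted motif enrichment and planted filter
# confounders, and plate-assay colony-count data.

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`. Deterministic given `seed`.
#'
#' @param length Genome length in bp (>= 100).
#' @param gc_fraction GC content in (0, 1); default 0.38, a yeast-like value.
#' @param seed Integer seed.
#' @param contig Contig name.
#' @return A `mut_genome` with a single contig.
#' @export
simulate_genome <- function(length, gc_fraction = 0.38, seed = 1,
                            contig = "chr1") {
  if (length < 100) abort("genome length must be >= 100")
  if (gc_fraction <= 0 || gc_fraction >= 1) abort("gc_fraction must lie in (0, 1)")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, paste(sample(BASES, length, replace = TRUE,
                                      prob = p[BASES]), collapse = ""))
  as_genome(setNames(seq, contig))
}

site_alt <- function(ref, motif) {
  ifelse(ref == motif$from, motif$to, complement_base(motif$to))
}

#' Generate an isolate cohort with known planted enrichment
#'
#' Places class mutations (for gCn&rarr;A: C&rarr;A on either strand) on a
#' genome such that the expected motif fold-enrichment against genome-wide
#' opportunity equals `enrichment`: each mutation is a motif-site mutation
#' with probability `enrichment * f`, where `f = x_motif / x_class` is the
#' genome's motif fraction among class sites, and sites are then drawn
#' uniformly without replacement from the corresponding inventory
#' (`enrichment * f` must be at most 1). Genuine calls get high VAFs.
#'
#' Planted confounders, at sites disjoint from all genuine calls and from
#' each other, exercise the filter cascade: `n_shared` variant keys are each
#' copied into two or more samples; `n_parent` keys appear in the parent call
#' set and in a random subset of samples; `n_low_vaf` calls per sample carry
#' sub-threshold VAFs.
#'
#' @param genome A `mut_genome`.
#' @param n_samples Number of isolates (default 36, a typical sequenced
#'   cohort size per group).
#' @param n_mutations Class mutations per sample.
#' @param enrichment Target fold-enrichment E* (>= 0 and at most `1 / f`).
#' @param motif A [motif()] object.
#' @param n_shared,n_parent Planted shared / parent-strain keys (cohort-wide).
#' @param n_low_vaf Planted low-VAF artifacts per sample.
#' @param vaf_range VAF range for genuine and planted high-VAF calls
#'   (default `c(0.90, 1)`).
#' @param low_vaf_range VAF range for the low-VAF artifacts
#'   (default `c(0.10, 0.80)`).
#' @param distinct_sites If `TRUE`, genuine sites are unique across the whole
#'   cohort (not just within samples), so that no genuine call can be removed
#'   by the recurrence filter; use for exact filter-accuracy checks.
#' @param seed Integer seed; fixes all randomness.
#' @return A list with `calls` (tibble over all samples), `parent` (tibble of
#'   parent-strain calls), and `truth` (every emitted call with its
#'   `category`: `"genuine"`, `"shared"`, `"parent"`, `"low_vaf"`, and for
#'   genuine calls whether it was placed at a motif site), plus the planted
#'   `enrichment` and the genome motif fraction `f`.
#' @export
simulate_cohort <- function(genome, n_samples = 36, n_mutations = 200,
                            enrichment = 1, motif = mutmotif::motif(),
                            n_shared = 5, n_parent = 3, n_low_vaf = 4,
                            vaf_range = c(0.90, 1), low_vaf_range = c(0.10, 0.80),
                            distinct_sites = FALSE, seed = 1) {
  genome <- as_genome(genome)
  stopifnot(is_mut_motif(motif), enrichment >= 0,
            n_samples >= 1, n_mutations >= 0,
            n_shared >= 0, n_parent >= 0, n_low_vaf >= 0)
  msites <- motif_sites(genome, motif)
  csites <- class_sites(genome, motif)
  if (nrow(msites) == 0) abort("genome contains no motif sites")
  mkey <- paste(msites$contig, msites$pos)
  ckey <- paste(csites$contig, csites$pos)
  # Non-motif class sites; motif sites are removed by position (a position can
  # host motif occurrences on both strands but is one mutable site).
  nsites <- csites[!ckey %in% mkey, , drop = FALSE]
  if (nrow(nsites) == 0) abort("genome contains no non-motif class sites")
  msites <- distinct(msites, .data$contig, .data$pos, .keep_all = TRUE)

  f <- genome_motif_fraction(genome, motif)
  p_motif <- enrichment * f
  if (p_motif > 1) {
    abort(sprintf(
      "requested enrichment %.3g exceeds the attainable maximum 1/f = %.3g for this genome",
      enrichment, 1 / f))
  }

  with_seed(seed, {
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    m_pool <- msites
    n_pool <- nsites
    genuine <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      n_mot <- rbinom(1, n_mutations, p_motif)
      n_non <- n_mutations - n_mot
      if (n_mot > nrow(m_pool) || n_non > nrow(n_pool)) {
        abort("requested mutations exceed available sites")
      }
      mi <- sample.int(nrow(m_pool), n_mot)
      ni <- sample.int(nrow(n_pool), n_non)
      g <- bind_rows(
        mutate(m_pool[mi, c("contig", "pos", "ref")], motif_site = TRUE),
        mutate(n_pool[ni, c("contig", "pos", "ref")], motif_site = FALSE)
      )
      g$sample <- sample_ids[i]
      genuine[[i]] <- g
      if (distinct_sites) {
        m_pool <- m_pool[-mi, , drop = FALSE]
        n_pool <- n_pool[-ni, , drop = FALSE]
      }
    }
    genuine <- bind_rows(genuine)
    genuine$alt <- site_alt(genuine$ref, motif)
    genuine$vaf <- runif(nrow(genuine), vaf_range[1], vaf_range[2])
    genuine$category <- "genuine"

    # Confounder sites: class sites disjoint from every genuine site.
    used <- unique(paste(genuine$contig, genuine$pos))
    free <- csites[!paste(csites$contig, csites$pos) %in% used, , drop = FALSE]
    free <- distinct(free, .data$contig, .data$pos, .keep_all = TRUE)
    n_conf <- n_shared + n_parent + n_samples * n_low_vaf
    if (n_conf > nrow(free)) abort("not enough free sites for planted confounders")
    conf <- free[sample.int(nrow(free), n_conf), , drop = FALSE]
    conf$alt <- site_alt(conf$ref, motif)
    take <- function(n) {
      if (n == 0) return(conf[0, , drop = FALSE])
      out <- conf[seq_len(n), , drop = FALSE]
      conf <<- conf[-seq_len(n), , drop = FALSE]
      out
    }

    shared <- take(n_shared)
    shared_calls <- NULL
    if (n_shared > 0) {
      shared_calls <- purrr::map_dfr(seq_len(n_shared), function(j) {
        k <- if (n_samples <= 2) 2L else sample(c(2L, 3L), 1)
        into <- sample(sample_ids, min(k, n_samples))
        tibble(sample = into, contig = shared$contig[j], pos = shared$pos[j],
               ref = shared$ref[j], alt = shared$alt[j],
               vaf = runif(length(into), vaf_range[1], vaf_range[2]),
               motif_site = NA, category = "shared")
      })
    }

    parent <- take(n_parent)
    parent_calls <- NULL
    parent_table <- tibble(sample = character(), contig = character(),
                           pos = integer(), ref = character(),
                           alt = character(), vaf = double())
    if (n_parent > 0) {
      parent_table <- tibble(sample = "parent", contig = parent$contig,
                             pos = parent$pos, ref = parent$ref,
                             alt = parent$alt,
                             vaf = runif(n_parent, vaf_range[1], vaf_range[2]))
      parent_calls <- purrr::map_dfr(seq_len(n_parent), function(j) {
        n_into <- sample.int(min(3, n_samples), 1)
        into <- sample(sample_ids, n_into)
        tibble(sample = into, contig = parent$contig[j], pos = parent$pos[j],
               ref = parent$ref[j], alt = parent$alt[j],
               vaf = runif(length(into), vaf_range[1], vaf_range[2]),
               motif_site = NA, category = "parent")
      })
    }

    low_calls <- NULL
    if (n_low_vaf > 0) {
      low <- take(n_samples * n_low_vaf)
      low$sample <- rep(sample_ids, each = n_low_vaf)
      low$vaf <- runif(nrow(low), low_vaf_range[1], low_vaf_range[2])
      low$motif_site <- NA
      low$category <- "low_vaf"
      low_calls <- low
    }

    truth <- bind_rows(genuine, shared_calls, parent_calls, low_calls) %>%
      select("sample", "contig", "pos", "ref", "alt", "vaf",
             "category", "motif_site") %>%
      arrange(.data$sample, .data$contig, .data$pos)

    calls <- select(truth, "sample", "contig", "pos", "ref", "alt", "vaf")
    list(calls = calls, parent = parent_table, truth = truth,
         enrichment = enrichment, f = f)
  })
}

#' Genome motif fraction among class sites
#'
#' `f = x_motif / x_class` computed genome-wide; the null probability that a
#' class mutation falls at a motif site, and the scale against which a
#' planted enrichment is defined (`E* = p_motif / f`).
#'
#' @inheritParams genome_opportunity
#' @return A single number in (0, 1).
#' @export
genome_motif_fraction <- function(genome, motif = mutmotif::motif()) {
  opp <- genome_opportunity(genome, motif)
  opp$x_motif / opp$x_class
}

#' Generate plate-assay measurements with known true frequencies
#'
#' Per culture, the viable titer is drawn log-normally around
#' `nominal_titer` with standard deviation `dispersion` on the log scale, and
#' the resistant-colony count is Poisson with mean
#' `frequency * cells_plated`, converted back to a per-ml titer so that the
#' derived frequency estimates the planted truth. Deterministic given `seed`.
#'
#' @param truth Tibble with columns `genotype`, `treatment`, `frequency`
#'   (the planted per-cell mutant frequency).
#' @param n_cultures Cultures per genotype-by-treatment cell (default 6).
#' @param nominal_titer Nominal viable titer per ml (default `1e7`).
#' @param cells_plated Viable cells plated on the selective plate
#'   (default `1e7`).
#' @param dispersion Log-scale SD of the culture-to-culture viable titer
#'   (default 0.3).
#' @param seed Integer seed.
#' @return A tibble of measurements: `culture`, `genotype`, `treatment`,
#'   `canr_per_ml`, `viable_per_ml`.
#' @export
simulate_assay <- function(truth, n_cultures = 6, nominal_titer = 1e7,
                           cells_plated = 1e7, dispersion = 0.3, seed = 1) {
  truth <- as_tibble(truth)
  stopifnot(all(c("genotype", "treatment", "frequency") %in% names(truth)),
            n_cultures >= 1, nominal_titer > 0, cells_plated > 0,
            dispersion >= 0)
  if (any(truth$frequency < 0)) abort("frequencies must be non-negative")
  with_seed(seed, {
    purrr::pmap_dfr(truth, function(genotype, treatment, frequency, ...) {
      viable <- nominal_titer * exp(rnorm(n_cultures, 0, dispersion))
      counts <- rpois(n_cultures, frequency * cells_plated)
      tibble(
        culture = sprintf("%s_%s_%02d", genotype, treatment,
                          seq_len(n_cultures)),
        genotype = genotype,
        treatment = treatment,
        canr_per_ml = counts * viable / cells_plated,
        viable_per_ml = viable
      )
    })
  })
}
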