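# Forward-mutation plate-assay arithmetic and nonparametric group statistics:
# frequencies, viability, distribution-free median CIs, fold-changes and the
# exact one-sided Mann-Whitney U test.

#' Forward-mutation frequency
#'
#' Resistant-colony titer divided by viable titer. Vectorised; scale-invariant
#' in the titers.
#'
#' @param canr_per_ml Resistant colonies per ml.
#' @param viable_per_ml Viable colonies per ml (> 0).
#' @return Numeric vector of frequencies.
#' @examples
#' mutation_frequency(30, 1e7)
#' @export
mutation_frequency <- function(canr_per_ml, viable_per_ml) {
  if (any(canr_per_ml < 0 | viable_per_ml < 0)) abort("titers must be non-negative")
  if (any(viable_per_ml == 0)) abort("viable titer must be > 0")
  canr_per_ml / viable_per_ml
}

#' Post-treatment viability percentage
#'
#' `100 * treated viable titer / untreated viable titer`; not clamped at
#' 100 percent.
#'
#' @param treated_viable_per_ml Viable titer after treatment.
#' @param untreated_viable_per_ml Viable titer of the untreated control (> 0).
#' @return Numeric vector of percentages.
#' @export
viability_percent <- function(treated_viable_per_ml, untreated_viable_per_ml) {
  if (any(treated_viable_per_ml < 0 | untreated_viable_per_ml < 0)) {
    abort("titers must be non-negative")
  }
  if (any(untreated_viable_per_ml == 0)) abort("untreated viable titer must be > 0")
  100 * treated_viable_per_ml / untreated_viable_per_ml
}

#' Colony counts to per-ml titers
#'
#' `count / (volume_ml * dilution)` where `dilution` is the fraction of the
#' culture represented on the plate (e.g. `1e-5` for a 10^-5 dilution).
#'
#' @param count Colony count.
#' @param volume_ml Volume plated, in ml.
#' @param dilution Dilution factor as a fraction.
#' @return Titer per ml of the original culture.
#' @export
titer_per_ml <- function(count, volume_ml, dilution) {
  if (any(volume_ml <= 0 | dilution <= 0)) abort("volume and dilution must be > 0")
  count / (volume_ml * dilution)
}

#' Median with a distribution-free confidence interval
#'
#' Sample median (midpoint convention for even n) with the conservative
#' order-statistic confidence interval from the binomial(n, 1/2)
#' construction: the interval `(x_(d), x_(n-d+1))` with the largest `d` such
#' that `P(Binom(n, 1/2) < d) <= (1 - level) / 2`, giving coverage at least
#' `level`. For `n < 6` no such interval exists at the 95 percent level; the
#' bounds fall back to the sample range and are flagged.
#'
#' @param values Numeric vector (non-empty).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `n`, `median`, `lower`, `upper`, `coverage`
#'   (exact coverage of the order-statistic interval, `NA` for the range
#'   fallback), `exact` (logical flag).
#' @export
median_with_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) abort("median_with_ci() requires at least one value")
  s <- sort(values)
  med <- median(s)
  alpha <- (1 - level) / 2
  # largest d with pbinom(d - 1, n, 1/2) <= alpha
  d <- 0L
  while (d + 1L <= n && pbinom(d, n, 0.5) <= alpha) d <- d + 1L
  if (d >= 1L && d <= n - d + 1L) {
    tibble(n = n, median = med, lower = s[d], upper = s[n - d + 1L],
           coverage = 1 - 2 * pbinom(d - 1, n, 0.5), exact = TRUE)
  } else {
    tibble(n = n, median = med, lower = s[1], upper = s[n],
           coverage = NA_real_, exact = FALSE)
  }
}

# Cache of rank-subset matrices for the exact Mann-Whitney branch.
.mw_cache <- new.env(parent = emptyenv())

mw_combinations <- function(n_total, n_y) {
  key <- paste(n_total, n_y, sep = "_")
  if (is.null(.mw_cache[[key]])) {
    .mw_cache[[key]] <- combn(n_total, n_y)
  }
  .mw_cache[[key]]
}

#' One-sided Mann-Whitney U test
#'
#' Tests the alternative that `y` is stochastically greater than `x`. Ties
#' are handled with midranks; `U` is the number of (x, y) pairs with `y > x`
#' plus half the tied pairs. When the number of rank assignments
#' `choose(n1 + n2, n2)` is at most `max_exact`, the p-value is exact: the
#' fraction of all equally likely assignments of the pooled midranks to the
#' `y` group whose U is at least the observed U. Otherwise the normal
#' approximation with tie-corrected variance and continuity correction is
#' used.
#'
#' @param x Numeric vector (reference / untreated group).
#' @param y Numeric vector (alternative / treated group).
#' @param max_exact Enumeration bound for the exact branch (default `1e6`).
#' @return A one-row tibble: `u`, `p_value`, `method` (`"exact"` or
#'   `"normal"`).
#' @examples
#' mann_whitney_one_sided(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_one_sided <- function(x, y, max_exact = 1e6) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  u_obs <- sum(r[(n1 + 1):(n1 + n2)]) - n2 * (n2 + 1) / 2

  if (choose(n1 + n2, n2) <= max_exact) {
    idx <- mw_combinations(n1 + n2, n2)
    u_all <- colSums(matrix(r[idx], nrow = n2)) - n2 * (n2 + 1) / 2
    p <- mean(u_all >= u_obs - 1e-9)
    method <- "exact"
  } else {
    n <- n1 + n2
    t_tab <- table(pooled)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(t_tab^3 - t_tab) / (n * (n - 1)))
    z <- (u_obs - mu - 0.5) / sqrt(sigma2)
    p <- pnorm(z, lower.tail = FALSE)
    method <- "normal"
  }
  tibble(u = u_obs, p_value = min(1, max(p, .Machine$double.xmin)),
         method = method)
}

#' Attach derived frequencies to assay measurements
#'
#' @param measurements Tibble with columns `canr_per_ml` and `viable_per_ml`.
#' @return The tibble with a `frequency` column added.
#' @export
assay_frequencies <- function(measurements) {
  d <- as_tibble(measurements)
  d$frequency <- mutation_frequency(d$canr_per_ml, d$viable_per_ml)
  d
}

#' Compare treated vs untreated assay groups
#'
#' Per genotype: median mutation frequencies with distribution-free 95
#' percent confidence intervals for the untreated and treated groups, the
#' fold-change as the ratio of medians (treated / untreated), and the exact
#' one-sided Mann-Whitney p-value for the alternative that treated
#' frequencies are greater.
#'
#' @param measurements Tibble with columns `genotype`, `treatment`,
#'   `canr_per_ml`, `viable_per_ml` (a `frequency` column is computed if
#'   absent).
#' @param untreated,treated The `treatment` labels of the two groups
#'   (defaults `"water"` and `"acetaldehyde"`).
#' @param level Confidence level for the median CIs.
#' @return An object of class `assay_comparison`: a tibble with one row per
#'   genotype (`n_untreated`, `n_treated`, medians with CI bounds,
#'   `fold_change`, `u`, `p_value`, `method`, `note`). Genotypes missing one
#'   group are reported with the available medians and an `NA` comparison,
#'   with a warning.
#' @export
compare_groups <- function(measurements, untreated = "water",
                           treated = "acetaldehyde", level = 0.95) {
  d <- as_tibble(measurements)
  if (!"frequency" %in% names(d)) d <- assay_frequencies(d)
  one <- function(g) {
    fx <- g$frequency[g$treatment == untreated]
    fy <- g$frequency[g$treatment == treated]
    res <- tibble(
      n_untreated = length(fx), n_treated = length(fy),
      median_untreated = NA_real_, untreated_lower = NA_real_,
      untreated_upper = NA_real_,
      median_treated = NA_real_, treated_lower = NA_real_,
      treated_upper = NA_real_,
      fold_change = NA_real_, u = NA_real_, p_value = NA_real_,
      method = NA_character_, note = NA_character_
    )
    if (length(fx) > 0) {
      ci <- median_with_ci(fx, level)
      res$median_untreated <- ci$median
      res$untreated_lower <- ci$lower; res$untreated_upper <- ci$upper
    }
    if (length(fy) > 0) {
      ci <- median_with_ci(fy, level)
      res$median_treated <- ci$median
      res$treated_lower <- ci$lower; res$treated_upper <- ci$upper
    }
    if (length(fx) == 0 || length(fy) == 0) {
      warn("group with no cultures: comparison skipped")
      res$note <- "missing_group"
      return(res)
    }
    if (res$median_untreated == 0) {
      res$note <- "zero_untreated_median"
    } else {
      res$fold_change <- res$median_treated / res$median_untreated
    }
    mw <- mann_whitney_one_sided(fx, fy)
    res$u <- mw$u; res$p_value <- mw$p_value; res$method <- mw$method
    res
  }
  out <- d %>%
    group_by(.data$genotype) %>%
    dplyr::group_modify(~ one(.x)) %>%
    ungroup()
  structure(out, untreated = untreated, treated = treated,
            class = c("assay_comparison", class(out)))
}

#' Median viability per genotype
#'
#' Percentage of the untreated median viable titer retained by the treated
#' group, per genotype.
#'
#' @inheritParams compare_groups
#' @return A tibble with columns `genotype` and `viability_percent`.
#' @export
assay_viability <- function(measurements, untreated = "water",
                            treated = "acetaldehyde") {
  d <- as_tibble(measurements)
  d %>%
    group_by(.data$genotype) %>%
    summarise(
      viability_percent = viability_percent(
        median(.data$viable_per_ml[.data$treatment == treated]),
        median(.data$viable_per_ml[.data$treatment == untreated])
      ),
      .groups = "drop"
    )
}

#' @export
tidy.assay_comparison <- function(x, ...) as_tibble(x)

#' @export
glance.assay_comparison <- function(x, alpha = 0.05, ...) {
  d <- as_tibble(x)
  tibble(
    n_genotypes = nrow(d),
    n_significant = sum(d$p_value < alpha, na.rm = TRUE),
    median_fold_change = median(d$fold_change, na.rm = TRUE)
  )
}
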