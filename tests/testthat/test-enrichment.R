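test_that("one-sided Fisher p agrees with enumeration, fisher.test, and is monotone", {
  # spot grid, including the documented example table [[8,2],[100,900]]
  cases <- expand.grid(mm = c(0, 1, 5, 8), mc = c(8, 10, 20),
                       xm = c(0, 10, 100), xc = c(150, 1000))
  cases <- cases[cases$mm <= cases$mc & cases$xm <= cases$xc, ]
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      p <- fisher_one_sided(mm, mc, xm, xc)
      expect_equal(p, oracle_fisher(mm, mc, xm, xc), tolerance = 1e-12)
      ft <- stats::fisher.test(matrix(c(mm, xm, mc - mm, xc - xm), 2),
                               alternative = "greater")
      expect_equal(p, ft$p.value, tolerance = 1e-9)
    })
  }
  # zero motif mutations carry no enrichment evidence
  expect_equal(fisher_one_sided(0, 10, 50, 1000), 1)
  # monotone decreasing in m_motif at fixed margins
  p_seq <- fisher_one_sided(0:10, 10, 100, 1000)
  expect_true(all(diff(p_seq) <= 1e-15))
  expect_error(fisher_one_sided(5, 3, 1, 10), "counts")
})

test_that("mutation load follows m(E-1)/E with its null and limits", {
  expect_equal(mutation_load(10, 2), 5)
  expect_equal(mutation_load(10, 1), 0)
  expect_equal(mutation_load(7, 0.5), 0)       # floored below E = 1
  expect_equal(mutation_load(10, Inf), 10)
  e <- c(1, 1.5, 2, 4, 100, 1e9)
  l <- mutation_load(10, e)
  expect_true(all(diff(l) > 0))
  expect_true(all(l >= 0 & l <= 10))
  expect_error(mutation_load(10, 0), "> 0")
  expect_error(mutation_load(10, NA), "undefined")
})

test_that("enrichment arithmetic matches the defining ratio", {
  # degenerate toy genome engineered so the counts are transparent:
  # the sample's class mutations sit in known contexts
  g <- as_genome(c(c1 = "TTGCATTTTTCATTTTTGCATTTT"))
  # gCn sites: C at 4 and 19 (5' G), G at 3 and 18 (3' C); plain C at 11
  calls <- make_calls("S1", "c1", c(4, 11), "C", "A")
  e <- tidy(motif_enrichment(calls, g, flank = 3))
  expect_equal(e$m_class, 2L)
  expect_equal(e$m_motif, 1L)
  expect_equal(e$enrichment,
               (e$m_motif / e$m_class) / (e$x_motif / e$x_class))
  # windows: pos 4 -> "TTGCATT" (G3,C4 motif pair, class GCC? recount by hand)
  w <- context_window(g, "c1", c(4, 11), flank = 3)
  cc <- count_contexts(w$window, motif())
  expect_equal(e$x_motif, cc$x_motif)
  expect_equal(e$x_class, cc$x_class)
})

test_that("strand-aware motif matching counts C with 5' g and G with 3' c", {
  g <- as_genome(c(c1 = "AGCATGCTAC"))
  #            positions 123456789.
  calls <- dplyr::bind_rows(
    make_calls("S1", "c1", 3, "C", "A"),   # C, 5' G: motif
    make_calls("S1", "c1", 6, "G", "T"),   # G, 3' C (pos 7): motif on - strand
    make_calls("S1", "c1", 10, "C", "A"),  # C, 5' A: class only
    make_calls("S1", "c1", 9, "A", "C")    # T>G class: ignored entirely
  )
  e <- tidy(motif_enrichment(calls, g))
  expect_equal(e$m_class, 3L)
  expect_equal(e$m_motif, 2L)
})

test_that("samples without class mutations are flagged, not zeroed", {
  g <- as_genome(c(c1 = "AGCATGCTAC"))
  calls <- make_calls("S1", "c1", 9, "A", "C")  # T>G only
  e <- tidy(motif_enrichment(calls, g))
  expect_equal(e$m_class, 0L)
  expect_true(is.na(e$enrichment))
  expect_true(is.na(e$p_value))
  expect_true(is.na(e$load))
  expect_equal(e$note, "no_class_mutations")
})

test_that("pooled enrichment equals single-sample enrichment on concatenated calls", {
  withr::with_seed(13, {
    g <- simulate_genome(20000, seed = 13)
    coh <- simulate_cohort(g, n_samples = 4, n_mutations = 30, enrichment = 2,
                           n_shared = 0, n_parent = 0, n_low_vaf = 0, seed = 14)
    pooled <- tidy(motif_enrichment(coh$calls, g, pooled = TRUE))
    one <- coh$calls
    one$sample <- "all"
    single <- tidy(motif_enrichment(one, g))
    expect_equal(pooled[, -1], single[, -1])
  })
})

test_that("BH adjustment is monotone in p and bounded by it", {
  withr::with_seed(17, {
    g <- simulate_genome(20000, seed = 17)
    coh <- simulate_cohort(g, n_samples = 8, n_mutations = 40, enrichment = 1.5,
                           n_shared = 0, n_parent = 0, n_low_vaf = 0, seed = 18)
    e <- tidy(motif_enrichment(coh$calls, g, adjust = TRUE))
    o <- order(e$p_value)
    expect_true(all(diff(e$q_value[o]) >= -1e-12))
    expect_true(all(e$q_value >= e$p_value - 1e-12))
  })
})

test_that("enrichment counts are invariant under reverse complement", {
  withr::with_seed(19, {
    for (i in 1:5) {
      g <- as_genome(c(c1 = random_dna(2000)))
      coh <- simulate_cohort(g, n_samples = 1, n_mutations = 20,
                             n_shared = 0, n_parent = 0, n_low_vaf = 0,
                             seed = 100 + i)
      a <- tidy(motif_enrichment(coh$calls, g))
      b <- tidy(motif_enrichment(revcomp_calls(coh$calls, g),
                                 rev_comp_genome(g)))
      expect_equal(a[, c("m_motif", "m_class", "x_motif", "x_class",
                         "enrichment", "p_value")],
                   b[, c("m_motif", "m_class", "x_motif", "x_class",
                         "enrichment", "p_value")])
    }
  })
})

test_that("the generic motif machinery handles a tCw preset", {
  m <- motif("tCw", "T")
  g <- as_genome(c(c1 = "ATCAATCTTTGAA"))
  # tCa at 2-4 (C at 3), tCt at 6-8 (C at 7); reverse strand: tGa = complement
  calls <- make_calls("S1", "c1", c(3, 7), "C", "T")
  e <- tidy(motif_enrichment(calls, g, motif = m, flank = 2))
  expect_equal(e$m_motif, 2L)
  expect_equal(e$m_class, 2L)
})
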