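test_that("variant tables and VCFs round-trip through the readers", {
  calls <- make_calls("S1", "chr1", c(100, 200, 300), c("C", "G", "T"),
                      c("A", "T", "G"), vaf = c(0.95, 1, 0.42))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(calls, tsv)
  expect_equal(read_variant_table(tsv), calls)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(calls, vcf)
  back <- read_variant_vcf(vcf)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$vaf, calls$vaf, tolerance = 1e-6)
  expect_equal(back$sample, calls$sample)
})

test_that("multi-allelic VCF records split into one call per alternate", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"VAF\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "iso1", sep = "\t"),
    paste("chr1", "100", ".", "C", "A,T", ".", "PASS", ".", "GT:FREQ",
          "1:95%", sep = "\t")
  ), vcf)
  d <- read_variant_vcf(vcf)
  expect_equal(nrow(d), 2L)
  expect_equal(d$alt, c("A", "T"))
  expect_equal(d$vaf, c(0.95, 0.95))
  expect_equal(d$sample, c("iso1", "iso1"))
})

test_that("a VCF without any VAF field errors unless a default is given", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "100", ".", "C", "A", ".", "PASS", ".", sep = "\t")
  ), vcf)
  expect_error(read_variant_vcf(vcf), "VAF")
  d <- read_variant_vcf(vcf, sample = "s", default_vaf = 1)
  expect_equal(d$vaf, 1)
})

test_that("the allele-frequency filter keeps calls at or above the threshold", {
  calls <- make_calls("S1", "chr1", 1:3, "C", "A", vaf = c(0.95, 0.90, 0.85))
  fv <- filter_vaf(calls)
  expect_equal(fv$kept$vaf, c(0.95, 0.90))  # 0.90 boundary kept
  expect_equal(fv$removed$vaf, 0.85)
  expect_error(filter_vaf(calls, threshold = 1.2), "0, 1")
  empty <- filter_vaf(calls[0, ])
  expect_equal(nrow(empty$kept), 0L)
  expect_equal(nrow(empty$removed), 0L)
})

test_that("parent subtraction matches on the full variant key only", {
  calls <- make_calls("S1", "chr1", c(100, 100, 200), c("C", "C", "G"),
                      c("A", "T", "T"))
  parent <- make_calls("parent", "chr1", 100, "C", "A")
  sp <- subtract_parent(calls, parent)
  expect_equal(nrow(sp$removed), 1L)
  expect_equal(sp$removed$alt, "A")         # alt mismatch is kept
  expect_equal(nrow(sp$kept), 2L)
  all_kept <- subtract_parent(calls, NULL)
  expect_equal(nrow(all_kept$kept), 3L)
})

test_that("recurrence removal strikes shared keys from every carrier", {
  calls <- dplyr::bind_rows(
    make_calls("S1", "chr1", c(100, 150), "C", "A"),
    make_calls("S2", "chr1", c(100, 250), "C", "A"),
    make_calls("S3", "chr1", 350, "C", "A")
  )
  rr <- remove_recurrent(calls)
  expect_equal(sort(rr$removed$sample), c("S1", "S2"))
  expect_equal(unique(rr$removed$pos), 100L)
  expect_equal(nrow(rr$kept) + nrow(rr$removed), nrow(calls))
  expect_error(remove_recurrent(calls, min_samples = 1), "min_samples")
  # symmetric in sample order
  shuf <- calls[sample(nrow(calls)), ]
  rr2 <- remove_recurrent(shuf)
  expect_equal(dplyr::arrange(rr2$kept, sample, pos),
               dplyr::arrange(rr$kept, sample, pos))
})

test_that("the cascade attributes each removal to exactly one reason, in order", {
  calls <- dplyr::bind_rows(
    make_calls("S1", "chr1", 10, "C", "AT", vaf = 0.95),   # non-SNV
    make_calls("S1", "chr1", 20, "C", "A", vaf = 0.30),    # low VAF
    make_calls("S1", "chr1", 30, "C", "A", vaf = 0.95),    # parent hit
    make_calls("S1", "chr1", 40, "C", "A", vaf = 0.95),    # shared with S2
    make_calls("S1", "chr1", 50, "C", "A", vaf = 0.95),    # genuine
    make_calls("S2", "chr1", 40, "C", "A", vaf = 0.95),    # shared with S1
    # in parent AND shared: parent wins because it is applied first
    make_calls("S2", "chr1", 30, "C", "A", vaf = 0.95)
  )
  parent <- make_calls("parent", "chr1", 30, "C", "A")
  flt <- apply_filters(calls, parent)
  rep <- filter_report(flt)
  s1 <- rep[rep$sample == "S1", ]
  expect_equal(s1$n_input, 5L)
  expect_equal(s1$n_kept, 1L)
  expect_equal(s1$n_removed_non_snv, 1L)
  expect_equal(s1$n_removed_vaf, 1L)
  expect_equal(s1$n_removed_parent, 1L)
  expect_equal(s1$n_removed_recurrent, 1L)
  s2 <- rep[rep$sample == "S2", ]
  expect_equal(s2$n_removed_parent, 1L)
  # the S2 pos-40 call is only recurrent because S1 also carries it, and S1's
  # copy survived the earlier filters
  expect_equal(s2$n_removed_recurrent, 1L)
  # counters balance
  expect_equal(rep$n_input,
               rep$n_kept + rep$n_removed_non_snv + rep$n_removed_vaf +
                 rep$n_removed_parent + rep$n_removed_recurrent)
})

test_that("filtering is idempotent and conserves calls", {
  withr::with_seed(5, {
    g <- simulate_genome(20000, seed = 5)
    coh <- simulate_cohort(g, n_samples = 4, n_mutations = 30,
                           distinct_sites = TRUE, seed = 9)
    flt <- apply_filters(coh$calls, coh$parent)
    expect_equal(nrow(flt), nrow(coh$calls))
    kept <- kept_calls(flt)
    flt2 <- apply_filters(kept, coh$parent)
    expect_equal(kept_calls(flt2), kept)
    expect_true(all(flt2$status == "kept"))
  })
})
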