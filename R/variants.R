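# Variant ingestion and the filtering cascade applied before spectrum and
# enrichment analysis: SNV-only -> allele-frequency floor -> parent-strain
# subtraction -> cross-sample recurrence removal.

variant_cols <- c("sample", "contig", "pos", "ref", "alt", "vaf")

validate_calls <- function(calls, require_sample = TRUE) {
  calls <- as_tibble(calls)
  need <- if (require_sample) variant_cols else setdiff(variant_cols, "sample")
  missing <- setdiff(need, names(calls))
  if (length(missing) > 0) {
    abort(paste0("variant table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  calls$pos <- as.integer(calls$pos)
  calls$ref <- toupper(calls$ref)
  calls$alt <- toupper(calls$alt)
  if (any(calls$ref == calls$alt)) abort("ref and alt must differ")
  if (any(calls$vaf < 0 | calls$vaf > 1, na.rm = TRUE)) {
    abort("vaf must lie in [0, 1]")
  }
  calls
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1 & nchar(alt) == 1 & ref %in% BASES & alt %in% BASES
}

variant_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Read a variant table (TSV dialect)
#'
#' Reads the tab-separated variant dialect with columns `sample`, `contig`,
#' `pos`, `ref`, `alt`, `vaf` (1-based positions, VAF as a fraction in
#' \[0, 1\]).
#'
#' @param path Path to a TSV file.
#' @return A tibble of variant calls.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) abort(paste0("variant table not found: ", path))
  # pin the types: a ref/alt column of all T (or F) must not be guessed
  # as logical
  d <- readr::read_tsv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      sample = "c", contig = "c", pos = "i", ref = "c", alt = "c", vaf = "d",
      .default = readr::col_guess()
    )
  )
  validate_calls(d)
}

#' Write a variant table (TSV dialect)
#'
#' @param calls Tibble of variant calls.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(calls, path) {
  readr::write_tsv(validate_calls(calls), path, progress = FALSE)
  invisible(path)
}

#' Read variant calls from a VCF file
#'
#' Reads a minimal VCF (v4.x) for one sample. The variant allele frequency is
#' taken, in order of preference, from the FORMAT field `FREQ` (a percentage,
#' as written by common somatic callers), the FORMAT field `AF`, or the INFO
#' field `AF`; `vaf_field` restricts the search to one of these. Multi-allelic
#' records are split into one call per alternate allele.
#'
#' @param path Path to a VCF file.
#' @param sample Sample identifier to attach to the calls. Defaults to the
#'   VCF's (single) genotype column name, or the file name.
#' @param vaf_field One of `"auto"`, `"FREQ"`, `"AF"`, `"INFO/AF"`.
#' @param default_vaf Used when no VAF field is present; if `NULL` (default)
#'   a missing VAF field is an error.
#' @return A tibble of variant calls.
#' @export
read_variant_vcf <- function(path, sample = NULL,
                             vaf_field = c("auto", "FREQ", "AF", "INFO/AF"),
                             default_vaf = NULL) {
  vaf_field <- match.arg(vaf_field)
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt_samples <- if (ncol(v@gt) >= 2) colnames(v@gt)[-1] else character(0)
  if (is.null(sample)) {
    sample <- if (length(gt_samples) >= 1) gt_samples[1] else basename(path)
  }
  n <- nrow(fix)
  if (n == 0) {
    return(tibble(sample = character(), contig = character(),
                  pos = integer(), ref = character(), alt = character(),
                  vaf = double()))
  }

  vaf <- rep(NA_real_, n)
  got <- FALSE
  if (vaf_field %in% c("auto", "FREQ") && length(gt_samples) >= 1) {
    fr <- tryCatch(vcfR::extract.gt(v, element = "FREQ")[, 1],
                   error = function(e) NULL)
    if (!is.null(fr) && !all(is.na(fr))) {
      vaf <- as.numeric(sub("%$", "", fr)) / 100
      got <- TRUE
    }
  }
  if (!got && vaf_field %in% c("auto", "AF") && length(gt_samples) >= 1) {
    af <- tryCatch(vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)[, 1],
                   error = function(e) NULL)
    if (!is.null(af) && !all(is.na(af))) {
      vaf <- as.numeric(af)
      got <- TRUE
    }
  }
  if (!got && vaf_field %in% c("auto", "INFO/AF")) {
    af <- tryCatch(vcfR::extract.info(v, element = "AF", as.numeric = TRUE),
                   error = function(e) NULL)
    if (!is.null(af) && !all(is.na(af))) {
      vaf <- as.numeric(af)
      got <- TRUE
    }
  }
  if (!got) {
    if (is.null(default_vaf)) {
      abort(paste0("no VAF field (FREQ/AF) found in ", path,
                   "; supply default_vaf to override"))
    }
    vaf <- rep(default_vaf, n)
  }

  d <- tibble(
    sample = sample,
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vaf = vaf
  )
  # Split multi-allelic records (ALT "A,T" -> two calls sharing the VAF
  # unless the VAF itself is comma-separated per allele).
  d <- tidyr::separate_rows(d, "alt", sep = ",")
  validate_calls(d)
}

#' Write variant calls to a minimal VCF
#'
#' Emits a minimal single-sample VCF v4.2 with the VAF in the FORMAT field
#' `FREQ` (percentage), round-trippable through [read_variant_vcf()].
#'
#' @param calls Tibble of variant calls for one sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  calls <- validate_calls(calls)
  if (length(unique(calls$sample)) > 1) {
    abort("write_variant_vcf() writes one sample per file")
  }
  sample <- if (nrow(calls) > 0) calls$sample[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Variant allele frequency\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t")
  )
  body <- if (nrow(calls) == 0) character(0) else {
    paste(calls$contig, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
          ".", "GT:FREQ",
          paste0("1:", formatC(calls$vaf * 100, format = "fg", digits = 6), "%"),
          sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Allele-frequency filter
#'
#' Partitions calls into those kept (VAF at or above the threshold) and those
#' removed. The threshold is inclusive: a call at exactly the threshold is
#' kept.
#'
#' @param calls Tibble of variant calls.
#' @param threshold Retention threshold on the variant allele frequency
#'   (default 0.90).
#' @return A list with tibbles `kept` and `removed`.
#' @export
filter_vaf <- function(calls, threshold = 0.90) {
  if (threshold < 0 || threshold > 1) abort("threshold must lie in [0, 1]")
  calls <- validate_calls(calls)
  keep <- calls$vaf >= threshold
  list(kept = calls[keep, , drop = FALSE], removed = calls[!keep, , drop = FALSE])
}

#' Subtract parent-strain / pre-existing calls
#'
#' Removes every call matching a parent call on (contig, pos, ref, alt);
#' sample identity and VAF are ignored in the match.
#'
#' @param calls Tibble of variant calls.
#' @param parent_calls Tibble of parent / untreated-culture calls (may lack a
#'   `sample` column).
#' @return A list with tibbles `kept` and `removed`.
#' @export
subtract_parent <- function(calls, parent_calls) {
  calls <- validate_calls(calls)
  if (is.null(parent_calls) || nrow(as_tibble(parent_calls)) == 0) {
    return(list(kept = calls, removed = calls[0, , drop = FALSE]))
  }
  parent_calls <- as_tibble(parent_calls)
  pk <- paste(parent_calls$contig, parent_calls$pos,
              toupper(parent_calls$ref), toupper(parent_calls$alt), sep = ":")
  hit <- variant_key(calls) %in% pk
  list(kept = calls[!hit, , drop = FALSE], removed = calls[hit, , drop = FALSE])
}

#' Remove recurrent cross-sample calls
#'
#' A variant key (contig, pos, ref, alt) observed in at least `min_samples`
#' distinct samples is removed from every sample carrying it; such calls are
#' interpreted as pre-existing in the shared culture rather than independent
#' events.
#'
#' @param calls Tibble of variant calls across samples.
#' @param min_samples Minimum number of distinct samples sharing a key for
#'   removal (default 2).
#' @return A list with tibbles `kept` and `removed`.
#' @export
remove_recurrent <- function(calls, min_samples = 2) {
  if (min_samples < 2) abort("min_samples must be >= 2")
  calls <- validate_calls(calls)
  key <- variant_key(calls)
  n_samples <- tapply(calls$sample, key, function(s) length(unique(s)))
  hit <- unname(n_samples[key]) >= min_samples
  list(kept = calls[!hit, , drop = FALSE], removed = calls[hit, , drop = FALSE])
}

#' Apply the full variant-filter cascade
#'
#' Applies, in a fixed order, (1) SNV-only restriction, (2) the allele-
#' frequency filter, (3) parent-strain subtraction, (4) cross-sample
#' recurrence removal. Each call is removed for exactly one reason (the first
#' applicable), so the per-sample counters in the report always balance.
#'
#' @param calls Tibble of variant calls across samples.
#' @param parent_calls Optional tibble of parent calls.
#' @param vaf_threshold Retention threshold for [filter_vaf()].
#' @param min_samples Recurrence threshold for [remove_recurrent()].
#' @return An object of class `mut_filtered`: a tibble of all input calls with
#'   a `status` column (`"kept"`, `"non_snv"`, `"low_vaf"`, `"parent"`,
#'   `"recurrent"`). Use [kept_calls()] and [filter_report()] to extract the
#'   surviving calls and the per-sample accounting.
#' @export
apply_filters <- function(calls, parent_calls = NULL, vaf_threshold = 0.90,
                          min_samples = 2) {
  calls <- validate_calls(calls)
  calls$.id <- seq_len(nrow(calls))
  status <- rep(NA_character_, nrow(calls))

  snv <- is_snv(calls$ref, calls$alt)
  status[!snv] <- "non_snv"
  cur <- calls[snv, , drop = FALSE]

  fv <- filter_vaf(cur, vaf_threshold)
  status[fv$removed$.id] <- "low_vaf"
  cur <- fv$kept

  sp <- subtract_parent(cur, parent_calls)
  status[sp$removed$.id] <- "parent"
  cur <- sp$kept

  rr <- remove_recurrent(cur, min_samples)
  status[rr$removed$.id] <- "recurrent"
  status[rr$kept$.id] <- "kept"

  calls$.id <- NULL
  calls$status <- status
  class(calls) <- c("mut_filtered", class(calls))
  calls
}

#' Surviving calls after filtering
#'
#' @param filtered Result of [apply_filters()].
#' @return A plain tibble of the calls with `status == "kept"` (the `status`
#'   column is dropped).
#' @export
kept_calls <- function(filtered) {
  stopifnot(inherits(filtered, "mut_filtered"))
  out <- as_tibble(filtered)[filtered$status == "kept", , drop = FALSE]
  out$status <- NULL
  out
}

#' Per-sample filter accounting
#'
#' @param filtered Result of [apply_filters()].
#' @return A tibble with one row per sample: `n_input`, `n_kept`,
#'   `n_removed_non_snv`, `n_removed_vaf`, `n_removed_parent`,
#'   `n_removed_recurrent`. Counters sum to `n_input` by construction.
#' @export
filter_report <- function(filtered) {
  stopifnot(inherits(filtered, "mut_filtered"))
  d <- as_tibble(filtered)
  d %>%
    group_by(.data$sample) %>%
    summarise(
      n_input = n(),
      n_kept = sum(.data$status == "kept"),
      n_removed_non_snv = sum(.data$status == "non_snv"),
      n_removed_vaf = sum(.data$status == "low_vaf"),
      n_removed_parent = sum(.data$status == "parent"),
      n_removed_recurrent = sum(.data$status == "recurrent"),
      .groups = "drop"
    )
}

#' @export
tidy.mut_filtered <- function(x, ...) as_tibble(x)

#' @export
glance.mut_filtered <- function(x, ...) {
  tibble(
    n_samples = length(unique(x$sample)),
    n_input = nrow(x),
    n_kept = sum(x$status == "kept"),
    n_removed = sum(x$status != "kept")
  )
}
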