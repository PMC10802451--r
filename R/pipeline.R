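# End-to-end orchestration: filter -> spectrum -> enrichment, and the assay
# analysis, each reading a flat key-value config and writing TSV tables plus
# a JSON manifest. Outputs are pure functions of (inputs, config).

default_config <- function() {
  list(
    genome_fasta = NULL,
    variants = NULL,          # TSV dialect (all samples) or character vector of VCFs
    parent_variants = NULL,   # optional TSV or VCF
    assay_table = NULL,
    motif_pattern = "gCn",
    motif_to = "A",
    flank = 20,
    vaf_threshold = 0.90,
    min_samples = 2,
    opportunity = "window",
    pooled = FALSE,
    untreated = "water",
    treated = "acetaldehyde",
    out_dir = "."
  )
}

#' Read a run configuration
#'
#' Flat key-value YAML document; unknown keys are rejected, missing keys take
#' the documented defaults.
#'
#' @param path Path to a YAML config file.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(user)] <- user
  cfg
}

resolve_config <- function(config) {
  cfg <- default_config()
  if (is.character(config) && length(config) == 1) {
    cfg <- read_run_config(config)
  } else if (is.list(config)) {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown) > 0) {
      abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg[names(config)] <- config
  } else {
    abort("config must be a path or a named list")
  }
  cfg
}

read_any_variants <- function(paths) {
  read_one <- function(p) {
    if (!file.exists(p)) abort(paste0("variant file not found: ", p))
    if (grepl("\\.vcf$", p, ignore.case = TRUE)) {
      read_variant_vcf(p)
    } else {
      read_variant_table(p)
    }
  }
  bind_rows(lapply(paths, read_one))
}

manifest_for <- function(cfg, inputs, outputs) {
  list(
    package = "mutmotif",
    version = as.character(utils::packageVersion("mutmotif")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    input_md5 = as.list(tools::md5sum(inputs)),
    outputs = basename(outputs)
  )
}

#' Run the genomics pipeline
#'
#' Filter cascade, mutation spectrum and motif enrichment on a cohort of
#' variant calls, written as TSV tables plus a JSON manifest recording the
#' configuration, package version and input checksums. Identical inputs and
#' configuration give identical outputs.
#'
#' @param config A named list or path to a YAML file; keys: `genome_fasta`,
#'   `variants` (variant-table TSV or vector of per-sample VCFs),
#'   `parent_variants` (optional), `motif_pattern`, `motif_to`, `flank`,
#'   `vaf_threshold`, `min_samples`, `opportunity`, `pooled`, `out_dir`.
#' @return A list (invisibly) with `filtered`, `report`, `spectrum`,
#'   `enrichment`, and the written `paths`.
#' @export
run_genomics <- function(config) {
  cfg <- resolve_config(config)
  for (key in c("genome_fasta", "variants")) {
    if (is.null(cfg[[key]])) abort(paste0("config key required: ", key))
  }
  genome <- read_genome_fasta(cfg$genome_fasta)
  calls <- read_any_variants(cfg$variants)
  parent <- if (!is.null(cfg$parent_variants)) {
    read_any_variants(cfg$parent_variants)
  } else NULL
  mot <- motif(cfg$motif_pattern, cfg$motif_to)

  filtered <- apply_filters(calls, parent,
                            vaf_threshold = cfg$vaf_threshold,
                            min_samples = cfg$min_samples)
  report <- filter_report(filtered)
  kept <- kept_calls(filtered)
  spectrum <- mutation_spectrum(kept)
  enrichment <- motif_enrichment(kept, genome, motif = mot,
                                 flank = cfg$flank,
                                 opportunity = cfg$opportunity,
                                 pooled = isTRUE(cfg$pooled))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(cfg$out_dir, c("filter_report.tsv", "spectrum.tsv",
                                    "enrichment.tsv", "manifest.json"))
  readr::write_tsv(report, paths[1], progress = FALSE)
  write_spectrum(spectrum, paths[2])
  write_enrichment(enrichment, paths[3])
  inputs <- c(cfg$genome_fasta, cfg$variants, cfg$parent_variants)
  jsonlite::write_json(manifest_for(cfg, inputs, paths), paths[4],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(filtered = filtered, report = report, spectrum = spectrum,
                 enrichment = enrichment, paths = paths))
}

#' Run the plate-assay analysis
#'
#' Per genotype: median frequencies with confidence intervals, the
#' treated/untreated fold-change, the one-sided Mann-Whitney p-value and the
#' median viability percentage, written as TSV plus a JSON manifest.
#'
#' @param config A named list or path to a YAML file; keys: `assay_table`
#'   (TSV with columns `culture`, `genotype`, `treatment`, `canr_per_ml`,
#'   `viable_per_ml`), `untreated`, `treated`, `out_dir`.
#' @return A list (invisibly) with `comparison`, `viability` and `paths`.
#' @export
run_assay <- function(config) {
  cfg <- resolve_config(config)
  if (is.null(cfg$assay_table)) abort("config key required: assay_table")
  if (!file.exists(cfg$assay_table)) {
    abort(paste0("assay table not found: ", cfg$assay_table))
  }
  d <- readr::read_tsv(cfg$assay_table, show_col_types = FALSE, progress = FALSE)
  comparison <- compare_groups(d, untreated = cfg$untreated,
                               treated = cfg$treated)
  has_both <- all(c(cfg$untreated, cfg$treated) %in% unique(d$treatment))
  viability <- if (has_both) {
    assay_viability(d, untreated = cfg$untreated, treated = cfg$treated)
  } else {
    tibble(genotype = character(), viability_percent = double())
  }

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(cfg$out_dir, c("assay_comparison.tsv", "viability.tsv",
                                    "assay_manifest.json"))
  readr::write_tsv(as_tibble(comparison), paths[1], progress = FALSE)
  readr::write_tsv(viability, paths[2], progress = FALSE)
  jsonlite::write_json(manifest_for(cfg, cfg$assay_table, paths), paths[3],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(comparison = comparison, viability = viability, paths = paths))
}
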