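#' Load a reference genome from FASTA
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a
#' reference-genome object. Sequences are uppercased; any character outside
#' A, C, G, T, N is rejected with an error naming the contig and offset.
#'
#' @param path Path to a FASTA file.
#' @return A `mut_genome` object: a named character vector of uppercase contig
#'   sequences, with a `total_length` attribute.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) abort(paste0("FASTA file is empty: ", path))
  as_genome(setNames(as.character(seqs), names(seqs)))
}

#' Construct a reference genome from named sequences
#'
#' @param contigs Named character vector: contig name to DNA sequence
#'   (alphabet A, C, G, T, N; either case).
#' @return A `mut_genome` object (uppercase sequences, `total_length`
#'   attribute).
#' @examples
#' as_genome(c(chr1 = "acgt"))
#' @export
as_genome <- function(contigs) {
  if (inherits(contigs, "mut_genome")) return(contigs)
  nm <- names(contigs)
  # FASTA headers may carry descriptions; the contig name is the first token.
  nm <- stringr::str_extract(nm, "^\\S+")
  if (is.null(nm) || any(is.na(nm)) || any(nm == "")) {
    abort("all contigs must have non-empty names")
  }
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate contig name: ", nm[duplicated(nm)][1]))
  }
  seqs <- toupper(unname(contigs))
  bad_at <- regexpr("[^ACGTN]", seqs)
  if (any(bad_at > 0)) {
    i <- which(bad_at > 0)[1]
    abort(sprintf("illegal character '%s' in contig '%s' at offset %d",
                  substr(seqs[i], bad_at[i], bad_at[i]), nm[i], bad_at[i]))
  }
  structure(setNames(seqs, nm),
            total_length = sum(nchar(seqs)),
            class = "mut_genome")
}

#' @export
print.mut_genome <- function(x, ...) {
  cat("<mut_genome> ", length(x), " contig(s), ",
      attr(x, "total_length"), " bp\n", sep = "")
  for (nm in head(names(x), 6)) {
    cat("  ", nm, ": ", nchar(x[[nm]]), " bp\n", sep = "")
  }
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}

contig_seq <- function(genome, contig) {
  if (!contig %in% names(genome)) {
    abort(paste0("unknown contig: ", contig))
  }
  unclass(genome)[[contig]]
}

#' Extract context windows around genomic positions
#'
#' Returns the subsequence from `max(1, pos - flank)` to
#' `min(contig_length, pos + flank)` around each position, together with the
#' 0-based offset of the focal base inside the window. Windows are truncated
#' at contig edges, so their length is at most `2 * flank + 1`.
#'
#' @param genome A `mut_genome`.
#' @param contig Contig name(s), recycled against `pos`.
#' @param pos 1-based position(s) within the contig.
#' @param flank Flank size in bp on each side (default 20).
#' @return A tibble with columns `contig`, `pos`, `window`, `offset`.
#' @examples
#' g <- as_genome(c(c1 = "ACGTACGTAC"))
#' context_window(g, "c1", 5, flank = 2)
#' @export
context_window <- function(genome, contig, pos, flank = 20) {
  genome <- as_genome(genome)
  stopifnot(flank >= 0, all(pos == floor(pos)))
  d <- tibble(contig = contig, pos = as.integer(pos))
  d$len <- nchar(unclass(genome))[match(d$contig, names(genome))]
  if (anyNA(d$len)) {
    abort(paste0("unknown contig: ", d$contig[is.na(d$len)][1]))
  }
  oob <- d$pos < 1 | d$pos > d$len
  if (any(oob)) {
    abort(sprintf("position %d out of range for contig '%s' (length %d)",
                  d$pos[oob][1], d$contig[oob][1], d$len[oob][1]))
  }
  start <- pmax(1L, d$pos - flank)
  end <- pmin(d$len, d$pos + flank)
  d$window <- unname(substr(unclass(genome)[match(d$contig, names(genome))],
                            start, end))
  d$offset <- unname(d$pos - start)
  d$len <- NULL
  d
}

#' Count motif and base-class occurrences in context windows
#'
#' Counts, over a set of windows, the double-stranded occurrences of a motif
#' (forward matches of the canonical pattern plus forward matches of its
#' reverse complement) and of the mutated-base class (for a C-centered motif,
#' C plus G per window). Overlapping occurrences are counted, and windows are
#' counted with multiplicity: each window is an independent opportunity set.
#' `N` bases match nothing.
#'
#' @param windows Character vector of DNA windows (uppercase A, C, G, T, N).
#' @param motif A [motif()] object.
#' @return A one-row tibble with integer columns `x_motif` and `x_class`.
#' @examples
#' count_contexts("AGCAT", motif())
#' @export
count_contexts <- function(windows, motif = mutmotif::motif()) {
  stopifnot(is_mut_motif(motif))
  if (length(windows) == 0) return(tibble(x_motif = 0L, x_class = 0L))
  class_chars <- paste0("[", motif$from, complement_base(motif$from), "]")
  x_class <- sum(stringr::str_count(windows, class_chars))
  fwd <- stringr::str_count(windows, stringr::regex(paste0("(?=", motif$forward_regex, ")")))
  rev <- stringr::str_count(windows, stringr::regex(paste0("(?=", motif$reverse_regex, ")")))
  tibble(x_motif = as.integer(sum(fwd) + sum(rev)), x_class = as.integer(x_class))
}

#' Genome-wide opportunity counts for a motif
#'
#' Double-stranded motif and base-class occurrence counts over all contigs of
#' a genome; the genome-wide analogue of [count_contexts()].
#'
#' @inheritParams count_contexts
#' @param genome A `mut_genome`.
#' @return A one-row tibble with `x_motif` and `x_class`.
#' @export
genome_opportunity <- function(genome, motif = mutmotif::motif()) {
  genome <- as_genome(genome)
  count_contexts(unclass(genome), motif)
}

#' Locate motif sites in a genome
#'
#' Returns the positions of the mutated-position base of every double-stranded
#' motif occurrence: for gCn, each C with a 5' G on the forward strand
#' (`strand = "+"`) and each G with a 3' C (`strand = "-"`, i.e. a gCn on the
#' opposite strand).
#'
#' @inheritParams genome_opportunity
#' @return A tibble with columns `contig`, `pos`, `strand`, `ref`.
#' @export
motif_sites <- function(genome, motif = mutmotif::motif()) {
  genome <- as_genome(genome)
  stopifnot(is_mut_motif(motif))
  one <- function(contig) {
    s <- contig_seq(genome, contig)
    fwd <- stringr::str_locate_all(s, stringr::regex(paste0("(?=", motif$forward_regex, ")")))[[1]][, 1]
    rev <- stringr::str_locate_all(s, stringr::regex(paste0("(?=", motif$reverse_regex, ")")))[[1]][, 1]
    bind_rows(
      tibble(contig = contig, pos = as.integer(fwd + motif$up - 1L),
             strand = "+", ref = motif$from),
      tibble(contig = contig, pos = as.integer(rev + motif$size - motif$up),
             strand = "-", ref = complement_base(motif$from))
    )
  }
  out <- bind_rows(lapply(names(genome), one))
  arrange(out, .data$contig, .data$pos, .data$strand)
}

#' Locate all base-class sites in a genome
#'
#' Positions where the reference base belongs to the motif's mutated-base
#' class on either strand (for a C-centered motif: every C and every G).
#'
#' @inheritParams genome_opportunity
#' @return A tibble with columns `contig`, `pos`, `ref`.
#' @export
class_sites <- function(genome, motif = mutmotif::motif()) {
  genome <- as_genome(genome)
  stopifnot(is_mut_motif(motif))
  chars <- paste0("[", motif$from, complement_base(motif$from), "]")
  one <- function(contig) {
    s <- contig_seq(genome, contig)
    hit <- stringr::str_locate_all(s, chars)[[1]][, 1]
    tibble(contig = contig, pos = as.integer(hit),
           ref = substring(s, hit, hit))
  }
  bind_rows(lapply(names(genome), one))
}

#' Reverse complement a whole genome
#'
#' Utility for strand-symmetry checks: every contig is reverse-complemented,
#' so position `p` maps to `L - p + 1`.
#'
#' @param genome A `mut_genome`.
#' @return A `mut_genome` of identical lengths.
#' @export
rev_comp_genome <- function(genome) {
  genome <- as_genome(genome)
  as_genome(setNames(rev_comp(unclass(genome)), names(genome)))
}

#' Write a genome to FASTA
#'
#' @param genome A `mut_genome`.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  genome <- as_genome(genome)
  x <- Biostrings::DNAStringSet(setNames(unclass(genome), names(genome)))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}
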