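# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")

# Watson-Crick complement for uppercase bases (N self-complements).
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# IUPAC context codes (lowercase in motif patterns). N in a *sequence* never
# matches any code, including n: an unknown base is not evidence of opportunity.
IUPAC <- list(
  a = "A", c = "C", g = "G", t = "T",
  r = c("A", "G"), y = c("C", "T"), s = c("C", "G"), w = c("A", "T"),
  k = c("G", "T"), m = c("A", "C"),
  b = c("C", "G", "T"), d = c("A", "G", "T"), h = c("A", "C", "T"),
  v = c("A", "C", "G"), n = c("A", "C", "G", "T")
)

# Complement of an IUPAC code, case preserved by the caller.
IUPAC_COMP <- c(
  a = "t", c = "g", g = "c", t = "a", r = "y", y = "r", s = "s", w = "w",
  k = "m", m = "k", b = "v", v = "b", d = "h", h = "d", n = "n"
)

complement_base <- function(x) {
  out <- unname(COMP[x])
  if (anyNA(out)) {
    abort(paste0("cannot complement base(s): ",
                 paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed. `N` maps to `N`; the empty string maps
#' to itself. Vectorised over `seq`.
#'
#' @param seq Character vector of DNA sequences over the alphabet A, C, G, T, N
#'   (either case; output is uppercase).
#' @return Character vector of the same length.
#' @examples
#' rev_comp("GCA")
#' @export
rev_comp <- function(seq) {
  if (length(seq) == 0) return(character(0))
  up <- toupper(seq)
  bad <- stringr::str_detect(up, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0("illegal character in sequence: ",
                 stringr::str_extract(up[bad][1], "[^ACGTN]")))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}

# Reverse complement of a motif pattern, preserving the case convention
# (uppercase = mutated position, lowercase = IUPAC context).
rev_comp_pattern <- function(pattern) {
  chars <- rev(strsplit(pattern, "")[[1]])
  out <- vapply(chars, function(ch) {
    if (ch %in% names(COMP)) unname(COMP[ch]) else unname(IUPAC_COMP[ch])
  }, character(1))
  if (anyNA(out)) abort(paste0("illegal character in motif pattern: ", pattern))
  paste(out, collapse = "")
}

# Seeded evaluation that does not disturb the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}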