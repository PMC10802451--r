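#' Define a mutation-signature motif
#'
#' A motif couples a short DNA pattern with a single-base substitution. The
#' mutated position is written in uppercase; lowercase letters are IUPAC
#' context codes (`n` = any base). The canonical representation always has a
#' pyrimidine (C or T) at the mutated position: purine-centered input is
#' reverse-complemented on construction, and the target base is complemented
#' with it. The default, `motif()`, is the acetaldehyde-associated gCn with
#' C&rarr;A (equivalently nGc with G&rarr;T on the opposite strand).
#'
#' @param pattern Pattern string with exactly one uppercase (mutated) position,
#'   e.g. `"gCn"` or `"tCw"`.
#' @param to Alternate base the mutated position changes to, on the same strand
#'   as `pattern`.
#' @return An object of class `mut_motif`: a list with the canonical `pattern`,
#'   `from` and `to` bases, the uppercase index `up`, pattern `size`, and
#'   precompiled regular expressions for both strands.
#' @examples
#' motif()             # gCn -> A
#' motif("nGc", "T")   # same motif entered purine-centered
#' @export
motif <- function(pattern = "gCn", to = "A") {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) >= 1)
  chars <- strsplit(pattern, "")[[1]]
  up_idx <- which(chars %in% c("A", "C", "G", "T"))
  if (length(up_idx) != 1) {
    abort("motif pattern must contain exactly one uppercase base (the mutated position)")
  }
  lower_ok <- chars[-up_idx] %in% names(IUPAC)
  if (length(chars) > 1 && !all(lower_ok)) {
    abort(paste0("illegal context code(s) in motif pattern: ",
                 paste(chars[-up_idx][!lower_ok], collapse = ", ")))
  }
  from <- chars[up_idx]
  to <- toupper(to)
  if (!to %in% BASES) abort("'to' must be one of A, C, G, T")
  if (to == from) abort("'to' must differ from the mutated base")

  # Canonicalise to a pyrimidine-centered pattern.
  if (from %in% c("A", "G")) {
    pattern <- rev_comp_pattern(pattern)
    chars <- strsplit(pattern, "")[[1]]
    up_idx <- nchar(pattern) - up_idx + 1
    from <- complement_base(from)
    to <- complement_base(to)
  }

  structure(
    list(
      pattern = pattern,
      from = from,
      to = to,
      up = up_idx,
      size = nchar(pattern),
      forward_regex = motif_regex(pattern),
      reverse_regex = motif_regex(rev_comp_pattern(pattern)),
      label = paste0(pattern, ">", to)
    ),
    class = "mut_motif"
  )
}

# Translate a cased pattern into a plain character-class regex. N in the
# subject sequence matches nothing because the classes list explicit bases.
motif_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  parts <- vapply(chars, function(ch) {
    if (ch %in% BASES) return(ch)
    set <- IUPAC[[ch]]
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  paste(parts, collapse = "")
}

#' @export
print.mut_motif <- function(x, ...) {
  cat("<mut_motif> ", x$label,
      "  (", x$from, ">", x$to, " at position ", x$up, " of ", x$pattern, ")\n",
      sep = "")
  invisible(x)
}

is_mut_motif <- function(x) inherits(x, "mut_motif")
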