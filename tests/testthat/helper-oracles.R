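# Independent oracles and tiny fixture builders used across the suite.

# Hypergeometric upper-tail probability by direct enumeration of the point
# probabilities with choose(); independent of phyper/fisher.test.
oracle_fisher <- function(m_motif, m_class, x_motif, x_class) {
  K <- m_motif + x_motif          # motif column total
  N <- m_class + x_class          # grand total
  j <- seq(max(0, m_class - (N - K)), min(m_class, K))
  pj <- choose(K, j) * choose(N - K, m_class - j) / choose(N, m_class)
  sum(pj[j >= m_motif])
}

# Exact one-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the y group, computing U by direct pairwise comparison
# (wins + half-ties), independently of the rank-sum route.
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  n2 <- length(y)
  M <- outer(pooled, pooled, function(a, b) (b > a) + 0.5 * (b == a))
  u_obs <- sum(M[seq_along(x), length(x) + seq_len(n2), drop = FALSE])
  subsets <- utils::combn(n, n2)
  u_all <- apply(subsets, 2, function(s) sum(M[-s, s, drop = FALSE]))
  mean(u_all >= u_obs - 1e-9)
}

# Brute-force double-stranded gCn site scan: C with 5' G (+) and G with 3' C
# (-); written against the glossary definition, not the package scanner.
oracle_gcn_sites <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  out <- NULL
  for (i in seq_len(n)) {
    if (chars[i] == "C" && i > 1 && chars[i - 1] == "G" && i < n &&
        chars[i + 1] %in% c("A", "C", "G", "T")) {
      out <- rbind(out, data.frame(pos = i, strand = "+"))
    }
    if (chars[i] == "G" && i < n && chars[i + 1] == "C" && i > 1 &&
        chars[i - 1] %in% c("A", "C", "G", "T")) {
      out <- rbind(out, data.frame(pos = i, strand = "-"))
    }
  }
  out
}

# Map a call table onto the reverse-complemented genome: position L - p + 1,
# both alleles complemented.
revcomp_calls <- function(calls, genome) {
  len <- nchar(unclass(genome))[match(calls$contig, names(genome))]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  calls$pos <- as.integer(len - calls$pos + 1)
  calls$ref <- unname(comp[calls$ref])
  calls$alt <- unname(comp[calls$alt])
  calls
}

random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

make_calls <- function(sample, contig, pos, ref, alt, vaf = 0.95) {
  tibble::tibble(sample = sample, contig = contig, pos = as.integer(pos),
                 ref = ref, alt = alt, vaf = vaf)
}
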