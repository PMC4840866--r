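# Independent brute-force oracles, kept deliberately naive and separate from
# the implementations they check.

# Pearson correlation from the raw sum formula
brute_pcc <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# hypergeometric upper tail by exact combinatorial enumeration
brute_hyper_upper <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# dominance probability by an explicit double loop over noise pairs
brute_dominance <- function(abs_m, d, noise_m, noise_d) {
  hits <- 0L
  for (j in seq_along(noise_m)) {
    if (noise_m[j] < abs_m && noise_d[j] < d) hits <- hits + 1L
  }
  hits / length(noise_m)
}

# longest ATG..stop ORF by enumerating every candidate substring (O(n^2))
brute_longest_orf <- function(seq) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (s in c(seq, rc(seq))) {
    n <- nchar(s)
    for (start in seq_len(max(n - 5, 0))) {
      if (substring(s, start, start + 2) != "ATG") next
      pos <- start + 3
      while (pos + 2 <= n) {
        codon <- substring(s, pos, pos + 2)
        if (grepl("[^ACGT]", codon)) break
        if (codon %in% stops) {
          best <- max(best, (pos - start) / 3)
          break
        }
        pos <- pos + 3
      }
    }
  }
  as.integer(best)
}

# small helper: expression tibble from a named-row matrix
make_expr <- function(values, gene_ids, lib_ids) {
  m <- matrix(values, nrow = length(gene_ids), ncol = length(lib_ids),
              byrow = TRUE, dimnames = list(NULL, lib_ids))
  tibble::tibble(gene_id = gene_ids, tibble::as_tibble(m))
}

# design with one library per condition (replicate-free worked examples)
single_rep_design <- function(conditions) {
  lnckit::default_design(conditions, n_reps = 1)
}
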