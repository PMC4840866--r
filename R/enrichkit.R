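#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes in a draw of `n` from a background of `N`
#' genes of which `K` carry the term. Computed in log space via
#' [stats::phyper()].
#'
#' @param k Observed annotated genes in the drawn set.
#' @param n Size of the drawn (e.g. DEG) set.
#' @param K Background genes carrying the term.
#' @param N Background size.
#' @return Probability in (0, 1\]. Vectorized over all arguments.
#' @export
hypergeom_upper <- function(k, n, K, N) {
  args <- vctrs_recycle(k, n, K, N)
  k <- args[[1]]; n <- args[[2]]; K <- args[[3]]; N <- args[[4]]
  if (any(k < 0 | k > n | n > N | K > N | k > K)) {
    abort("inconsistent counts: need 0 <= k <= n <= N and k <= K <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(vapply(xs, length, integer(1)))
  lapply(xs, rep_len, n)
}

#' Term enrichment of a gene set against a background
#'
#' One hypergeometric upper-tail test per term with at least one background
#' gene, Benjamini-Hochberg adjustment across all tested terms, and
#' significance at `q < alpha` (strict).
#'
#' @param de_set Character vector of genes of interest (must be contained in
#'   `background`).
#' @param term_map Tibble (`term_id`, `gene_id`, optionally `source`).
#'   Annotations to genes outside the background are ignored.
#' @param background Character vector: the gene universe.
#' @param alpha Significance level on the adjusted value (default 0.01).
#' @return Tibble (`term_id`, `k`, `n`, `K`, `N`, `p`, `q`, `significant`),
#'   ordered by `p` then `term_id`; a `source` column is carried through
#'   when present and unique per term.
#' @export
enrich <- function(de_set, term_map, background, alpha = 0.01) {
  de_set <- unique(de_set)
  background <- unique(background)
  outside <- setdiff(de_set, background)
  if (length(outside) > 0) {
    abort(paste0("gene outside background: ", outside[[1]]))
  }
  term_map <- filter(term_map, .data$gene_id %in% background)
  term_map <- distinct(term_map, .data$term_id, .data$gene_id,
                       .keep_all = TRUE)
  if (nrow(term_map) == 0) {
    return(tibble(term_id = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), p = numeric(), q = numeric(),
                  significant = logical()))
  }
  N <- length(background)
  n <- length(de_set)
  per_term <- term_map |>
    group_by(term_id = .data$term_id) |>
    summarise(
      K = dplyr::n(),
      k = sum(.data$gene_id %in% de_set),
      .groups = "drop"
    )
  out <- mutate(per_term,
    n = n, N = N,
    p = hypergeom_upper(.data$k, n, .data$K, N)
  )
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  if ("source" %in% names(term_map)) {
    src <- term_map |>
      group_by(term_id = .data$term_id) |>
      summarise(source = if (dplyr::n_distinct(.data$source) == 1)
        .data$source[[1]] else NA_character_, .groups = "drop")
    out <- left_join(out, src, by = "term_id")
  }
  out <- out[, c("term_id", "k", "n", "K", "N", "p", "q", "significant",
                 intersect("source", names(out)))]
  arrange(out, .data$p, .data$term_id)
}

#' Genes backing the significant terms of an enrichment
#'
#' The union of the genes of interest annotated to at least one significant
#' term — the "enriched genes" used for cross-treatment comparisons.
#'
#' @param enrichment Result tibble from [enrich()].
#' @param term_map The term map used for the enrichment.
#' @param de_set The gene set that was tested.
#' @return Sorted character vector of enriched genes.
#' @export
enriched_genes <- function(enrichment, term_map, de_set) {
  sig_terms <- enrichment$term_id[enrichment$significant]
  hits <- filter(term_map, .data$term_id %in% sig_terms,
                 .data$gene_id %in% de_set)
  sort(unique(hits$gene_id))
}

#' Venn region sizes of enriched-gene sets
#'
#' Exact sizes of every non-empty membership region across two or more gene
#' sets (e.g. per-treatment enriched genes), plus the all-set intersection.
#'
#' @param sets Named list (length >= 2) of gene-id character vectors.
#' @return List with `regions` (tibble `region`, `size`) and `shared_all`
#'   (character vector common to every set).
#' @export
enrichment_intersections <- function(sets) {
  if (length(sets) < 2) abort("enrichment_intersections needs >= 2 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("sets must be named")
  }
  sets <- lapply(sets, unique)
  list(
    regions = region_counts(sets),
    shared_all = sort(Reduce(intersect, sets))
  )
}

#' Combine enriched-gene sets across annotation sources
#'
#' With `mode = "and"` a gene counts only if it is enriched in every source
#' (e.g. both GO and KEGG); with `mode = "or"` in at least one.
#'
#' @param sets_by_source Named list of gene-id vectors, one per source.
#' @param mode `"and"` (intersection) or `"or"` (union).
#' @return Sorted character vector of genes.
#' @export
combine_sources <- function(sets_by_source, mode = c("and", "or")) {
  mode <- match.arg(mode)
  f <- if (mode == "and") intersect else union
  sort(unique(Reduce(f, sets_by_source)))
}
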