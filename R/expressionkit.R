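#' FPKM from fragment counts
#'
#' FPKM = 1e9 * C / (N * L), with C the fragment count of a gene in a
#' library, L the gene's effective length in bp and N the library's total
#' mapped fragments.
#'
#' @param counts Tibble with `gene_id` and one integer column per library.
#' @param effective_length_bp Numeric vector of per-gene effective lengths
#'   (recycled if length 1, or named by gene id).
#' @param total_mapped_fragments Per-library totals: a named numeric vector,
#'   a single number, or `NULL` to use the column sums of `counts`.
#' @return Tibble in the same layout with FPKM values.
#' @export
fpkm <- function(counts, effective_length_bp, total_mapped_fragments = NULL) {
  libs <- setdiff(names(counts), "gene_id")
  m <- as.matrix(counts[libs])
  L <- effective_length_bp
  if (!is.null(names(L))) L <- L[counts$gene_id]
  L <- rep_len(as.numeric(L), nrow(counts))
  if (anyNA(L) || any(L <= 0)) abort("effective lengths must be positive")
  N <- total_mapped_fragments
  if (is.null(N)) N <- colSums(m)
  if (!is.null(names(N))) N <- N[libs]
  N <- rep_len(as.numeric(N), length(libs))
  if (anyNA(N) || any(N <= 0)) abort("library totals must be positive")
  out <- 1e9 * sweep(m / L, 2, N, "/")
  tibble(gene_id = counts$gene_id, as_tibble(out))
}

#' Expression-level categories
#'
#' Assigns each (gene, library) FPKM to exactly one category: `high`
#' (FPKM > 50), `medium` (5 < FPKM <= 50) or `low` (FPKM <= 5).
#'
#' @param expr Expression tibble (`gene_id` + library columns).
#' @return Long tibble (`gene_id`, `library_id`, `fpkm`, `category`).
#' @export
categorize <- function(expr) {
  long <- tidyr::pivot_longer(expr, -"gene_id", names_to = "library_id",
                              values_to = "fpkm")
  mutate(long, category = dplyr::case_when(
    .data$fpkm > 50 ~ "high",
    .data$fpkm > 5 ~ "medium",
    TRUE ~ "low"
  ))
}

#' Between-library replicate concordance
#'
#' Pearson correlation of `log2(FPKM + offset)` vectors between every pair
#' of libraries. A zero-variance library yields missing (`NA`) correlations
#' with every other library; the diagonal is 1 by definition.
#'
#' @param expr Expression tibble.
#' @param log_offset Offset added before the log (default 1).
#' @return Long tibble (`library_a`, `library_b`, `pcc`) over all ordered
#'   pairs, diagonal included.
#' @export
replicate_pcc <- function(expr, log_offset = 1) {
  libs <- setdiff(names(expr), "gene_id")
  m <- log2(as.matrix(expr[libs]) + log_offset)
  if (nrow(m) < 3) abort("replicate_pcc needs at least 3 genes")
  cc <- suppressWarnings(cor(m))
  sds <- apply(m, 2, stats::sd)
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc) <- 1
  tibble(
    library_a = rep(libs, times = length(libs)),
    library_b = rep(libs, each = length(libs)),
    pcc = as.vector(cc)
  )
}

#' Heatmap of replicate concordance
#'
#' @param pcc_table Output of [replicate_pcc()].
#' @return A ggplot object.
#' @export
plot_replicate_pcc <- function(pcc_table) {
  libs <- unique(pcc_table$library_a)
  pcc_table$library_a <- factor(pcc_table$library_a, levels = libs)
  pcc_table$library_b <- factor(pcc_table$library_b, levels = rev(libs))
  ggplot2::ggplot(pcc_table,
                  ggplot2::aes(.data$library_a, .data$library_b,
                               fill = .data$pcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "PCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Cumulative gene detection as libraries accumulate
#'
#' Adds libraries in design order and reports, after each addition, how many
#' genes have been detected (FPKM strictly above `detect_threshold`) in at
#' least one library so far. The sequence is non-decreasing and its final
#' value does not depend on library order.
#'
#' @param expr Expression tibble.
#' @param design Design tibble fixing library order.
#' @param detect_threshold Detection threshold on FPKM (strict `>`,
#'   default 0).
#' @return Tibble (`library_id`, `n_new`, `n_cumulative`).
#' @export
cumulative_detection <- function(expr, design, detect_threshold = 0) {
  m <- expr_matrix(expr, design) > detect_threshold
  seen <- rep(FALSE, nrow(m))
  n_new <- integer(ncol(m))
  n_cum <- integer(ncol(m))
  for (k in seq_len(ncol(m))) {
    new <- m[, k] & !seen
    seen <- seen | m[, k]
    n_new[k] <- sum(new)
    n_cum[k] <- sum(seen)
  }
  tibble(library_id = design$library_id, n_new = n_new, n_cumulative = n_cum)
}

#' Expression summaries per transcript class
#'
#' Aggregates each gene's FPKM across all libraries (mean by default, or
#' max), then summarises per class with the average, median and maximum of
#' the per-gene values. Classes named in `class_map` but matching no gene in
#' the matrix are reported with `n = 0` and missing summaries.
#'
#' @param expr Expression tibble.
#' @param class_map Tibble (`gene_id`, `class`) or named character vector.
#' @param aggregate Per-gene aggregation across libraries: `"mean"` or
#'   `"max"`.
#' @return Tibble (`class`, `n`, `average`, `median`, `maximum`).
#' @export
class_expression_summary <- function(expr, class_map,
                                     aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  if (!is.data.frame(class_map)) {
    class_map <- tibble(gene_id = names(class_map),
                        class = unname(class_map))
  }
  m <- expr_matrix(expr)
  per_gene <- if (aggregate == "mean") rowMeans(m) else
    apply(m, 1, max)
  joined <- left_join(class_map,
                      tibble(gene_id = expr$gene_id, value = per_gene),
                      by = "gene_id")
  all_classes <- unique(class_map$class)
  out <- joined |>
    filter(!is.na(.data$value)) |>
    group_by(class = .data$class) |>
    summarise(
      n = dplyr::n(),
      average = mean(.data$value),
      median = stats::median(.data$value),
      maximum = max(.data$value),
      .groups = "drop"
    )
  missing_cls <- setdiff(all_classes, out$class)
  if (length(missing_cls) > 0) {
    out <- bind_rows(out, tibble(class = missing_cls, n = 0L,
                                 average = NA_real_, median = NA_real_,
                                 maximum = NA_real_))
  }
  out[match(all_classes, out$class), ]
}

#' Relative qRT-PCR expression by the 2^-ddCt method
#'
#' `fold = 2^-((Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator))`.
#'
#' @param ct_target_sample,ct_ref_sample Ct values of the target and
#'   reference gene in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct values in the calibrator
#'   sample.
#' @return Numeric fold change relative to the calibrator.
#' @export
relative_expression <- function(ct_target_sample, ct_ref_sample,
                                ct_target_calibrator, ct_ref_calibrator) {
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  if (any(!is.finite(ddct))) abort("Ct values must be finite")
  2^(-ddct)
}
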