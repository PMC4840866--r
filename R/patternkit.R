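#' Classify one temperature step into U, D or M
#'
#' The step fold change uses the higher temperature as the denominator:
#' `FC = (mean_lower + c)/(mean_higher + c)`. Letters: `U` iff `FC >= 2`,
#' `D` iff `FC <= 0.5`, `M` otherwise (0.5 < FC < 2).
#'
#' @param mean_lower_temp,mean_higher_temp Mean FPKM at the lower / higher
#'   temperature of the step (vectorized).
#' @param pseudocount Pseudocount `c` (default 1).
#' @return Character vector over `c("U", "D", "M")`.
#' @export
classify_step <- function(mean_lower_temp, mean_higher_temp, pseudocount = 1) {
  fc <- (mean_lower_temp + pseudocount) / (mean_higher_temp + pseudocount)
  dplyr::case_when(fc >= 2 ~ "U", fc <= 0.5 ~ "D", TRUE ~ "M")
}

#' Classify temperature-course expression patterns
#'
#' Concatenates [classify_step()] over adjacent condition pairs of an
#' ordered course (default: the first four design conditions, i.e. the cold
#' decrease 25 -> 4 -> 0 -> -4 degrees C), yielding a pattern string of
#' length `length(course) - 1` over U/D/M. With the default course there are
#' 27 possible patterns.
#'
#' @param expr Expression tibble.
#' @param design Design tibble.
#' @param course Ordered condition labels, from the highest temperature
#'   down; all must be present in the design.
#' @param pseudocount Pseudocount on FPKM (default 1).
#' @return Tibble with `gene_id`, `pattern`, and one `fc_*` column per step
#'   (step fold change, higher temperature as denominator).
#' @export
classify_pattern <- function(expr, design, course = NULL, pseudocount = 1) {
  conds <- condition_levels(design)
  if (is.null(course)) course <- conds[seq_len(min(4, length(conds)))]
  if (length(course) < 2) abort("course needs at least 2 conditions")
  missing_cond <- setdiff(course, conds)
  if (length(missing_cond) > 0) {
    abort(paste0("course condition missing from design: ", missing_cond[[1]]))
  }
  cm <- condition_means(expr, design)
  steps <- seq_len(length(course) - 1)
  fc_cols <- lapply(steps, function(k) {
    (cm[[course[k + 1]]] + pseudocount) / (cm[[course[k]]] + pseudocount)
  })
  names(fc_cols) <- paste0("fc_", course[-1], "_vs_", course[-length(course)])
  letters_mat <- vapply(fc_cols, function(fc) {
    dplyr::case_when(fc >= 2 ~ "U", fc <= 0.5 ~ "D", TRUE ~ "M")
  }, character(nrow(cm)))
  if (nrow(cm) == 1) letters_mat <- matrix(letters_mat, nrow = 1)
  pattern <- if (nrow(cm) == 0) character(0) else
    apply(letters_mat, 1, paste, collapse = "")
  tibble(gene_id = cm$gene_id, pattern = pattern, !!!fc_cols)
}

#' All possible U/D/M patterns for a course
#'
#' @param n_steps Number of adjacent-condition steps.
#' @return Character vector of the `3^n_steps` patterns in canonical
#'   (U before M before D) order.
#' @export
all_patterns <- function(n_steps) {
  grid <- expand.grid(rep(list(c("U", "M", "D")), n_steps),
                      stringsAsFactors = FALSE)[, n_steps:1, drop = FALSE]
  apply(grid, 1, paste, collapse = "")
}

#' Census of temperature-course patterns
#'
#' Counts genes per pattern over the complete pattern space (all
#' `3^(k-1)` classes for a k-condition course), including zero counts;
#' counts always sum to the number of genes.
#'
#' @param x Either a pattern-call tibble from [classify_pattern()] (any data
#'   frame with a `pattern` column), or an expression tibble to classify
#'   first.
#' @param design,course,pseudocount Used only when `x` is an expression
#'   tibble; see [classify_pattern()].
#' @return Tibble (`pattern`, `n`) covering every class.
#' @export
pattern_census <- function(x, design = NULL, course = NULL, pseudocount = 1) {
  calls <- if ("pattern" %in% names(x)) x else {
    if (is.null(design)) abort("design is required to classify an expression matrix")
    classify_pattern(x, design, course, pseudocount)
  }
  n_steps <- if (nrow(calls) > 0) nchar(calls$pattern[[1]]) else {
    if (is.null(course)) 3L else length(course) - 1L
  }
  keys <- all_patterns(n_steps)
  bad <- setdiff(unique(calls$pattern), keys)
  if (length(bad) > 0) abort(paste0("invalid pattern: ", bad[[1]]))
  counts <- table(factor(calls$pattern, levels = keys))
  tibble(pattern = keys, n = as.integer(counts))
}

#' Bar chart of a pattern census
#'
#' @param census Tibble from [pattern_census()].
#' @param log_scale Log10-scale the count axis (counts of 0 are dropped from
#'   the plot when `TRUE`).
#' @return A ggplot object.
#' @export
plot_pattern_census <- function(census, log_scale = FALSE) {
  census$pattern <- factor(census$pattern, levels = census$pattern)
  p <- ggplot2::ggplot(census,
                       ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange3") +
    ggplot2::labs(x = "temperature-course pattern", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}
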