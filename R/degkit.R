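#' Within-condition replicate noise distribution
#'
#' For every condition with at least two replicates, every ordered replicate
#' library pair and every gene, records the noise signal pair
#' `(|M|, D)` with `M = log2((a + c)/(b + c))` and `D = |a - b|` on FPKM,
#' pooled across genes and conditions. This pool is the empirical null
#' against which treatment-vs-control signals are ranked by
#' [deg_probability()].
#'
#' @param expr Expression tibble.
#' @param design Design tibble.
#' @param pseudocount Pseudocount `c` on FPKM before the log ratio
#'   (default 1).
#' @return Tibble (`condition`, `rep_a`, `rep_b`, `gene_id`, `abs_m`, `d`),
#'   one row per gene per ordered within-condition replicate pair.
#' @export
noise_distribution <- function(expr, design, pseudocount = 1) {
  m <- expr_matrix(expr, design)
  conds <- condition_levels(design)
  rows <- list()
  for (cc in conds) {
    libs <- design$library_id[design$condition == cc]
    if (length(libs) < 2) next
    for (a in libs) for (b in libs) {
      if (a == b) next
      rows[[length(rows) + 1L]] <- tibble(
        condition = cc, rep_a = a, rep_b = b, gene_id = rownames(m),
        abs_m = abs(log2((m[, a] + pseudocount) / (m[, b] + pseudocount))),
        d = abs(m[, a] - m[, b])
      )
    }
  }
  if (length(rows) == 0) {
    abort("no condition has >= 2 replicates; cannot form a noise distribution")
  }
  bind_rows(rows)
}

#' Differential-expression probability by noise dominance
#'
#' The probability that a gene's signal pair strictly dominates the replicate
#' noise: `q` is the fraction of noise pairs `(|M_n|, D_n)` with
#' `|M_n| < |M|` and `D_n < D`. A gene whose treatment and control means are
#' equal gets `q = 0`; a signal strictly exceeding every noise pair gets
#' `q = 1`. Monotone: increasing `|M|` or `D` never decreases `q`.
#'
#' @param abs_m Absolute log2 ratio(s) of the signal (vectorized).
#' @param d Absolute FPKM difference(s) of the signal (vectorized).
#' @param noise Noise tibble from [noise_distribution()] (columns `abs_m`,
#'   `d`).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
deg_probability <- function(abs_m, d, noise) {
  if (nrow(noise) == 0) abort("noise distribution is empty")
  nm <- noise$abs_m
  nd <- noise$d
  vapply(seq_along(abs_m), function(i) {
    mean(nm < abs_m[[i]] & nd < d[[i]])
  }, numeric(1))
}

#' Classify a fold change / probability pair into a DEG direction
#'
#' `up` iff `fc >= fc_threshold` and `q > q_threshold`; `down` iff
#' `fc <= 1/fc_threshold` and `q > q_threshold`; otherwise `none`. Both
#' fold-change bounds are inclusive; the probability bound is strict.
#'
#' @param fc Fold change(s), treatment over control on pseudocounted means.
#' @param q Differential probability(ies) in \[0, 1\].
#' @param fc_threshold Fold-change threshold (default 2).
#' @param q_threshold Probability threshold (default 0.8).
#' @return Character vector over `c("up", "down", "none")`.
#' @export
deg_direction <- function(fc, q, fc_threshold = 2, q_threshold = 0.8) {
  dplyr::case_when(
    fc >= fc_threshold & q > q_threshold ~ "up",
    fc <= 1 / fc_threshold & q > q_threshold ~ "down",
    TRUE ~ "none"
  )
}

#' Call differentially expressed genes against a control condition
#'
#' For every gene and every treatment condition, computes the fold change of
#' pseudocounted condition-mean FPKM against the control,
#' `fc = (mean_T + c)/(mean_C + c)`, the differential probability `q`
#' (noise-dominance, [deg_probability()]), and the direction at the
#' `FC >= 2` (or `<= 0.5`) and `q > 0.8` criterion.
#'
#' @param expr Expression tibble.
#' @param design Design tibble.
#' @param control Control condition label (default: first condition).
#' @param fc_threshold,q_threshold,pseudocount Calling parameters.
#' @param q_values Optional replacement for the built-in probability: a
#'   single number applied to every call (use 1 for a pure fold-change
#'   classification of data without replicates), or a tibble
#'   (`gene_id`, `condition`, `q`) of externally computed probabilities.
#' @return Tibble (`gene_id`, `condition`, `comparison`, `fc`, `log2fc`,
#'   `q`, `direction`), one row per gene per treatment comparison.
#' @export
call_degs <- function(expr, design, control = NULL, fc_threshold = 2,
                      q_threshold = 0.8, pseudocount = 1, q_values = NULL) {
  conds <- condition_levels(design)
  if (is.null(control)) control <- conds[[1]]
  if (!control %in% conds) abort(paste0("control condition not in design: ",
                                        control))
  cm <- condition_means(expr, design)
  treatments <- setdiff(conds, control)
  noise <- NULL
  if (is.null(q_values)) {
    noise <- noise_distribution(expr, design, pseudocount)
  }
  out <- lapply(treatments, function(tr) {
    fc <- (cm[[tr]] + pseudocount) / (cm[[control]] + pseudocount)
    d <- abs(cm[[tr]] - cm[[control]])
    q <- if (is.null(q_values)) {
      deg_probability(abs(log2(fc)), d, noise)
    } else if (is.data.frame(q_values)) {
      qq <- filter(q_values, .data$condition == tr)
      qq$q[match(cm$gene_id, qq$gene_id)]
    } else {
      rep_len(as.numeric(q_values), nrow(cm))
    }
    tibble(
      gene_id = cm$gene_id, condition = tr,
      comparison = paste0(tr, "_vs_", control),
      fc = fc, log2fc = log2(fc), q = q,
      direction = deg_direction(fc, q, fc_threshold, q_threshold)
    )
  })
  bind_rows(out)
}

region_counts <- function(sets) {
  genes <- unique(unlist(sets, use.names = FALSE))
  if (length(genes) == 0) {
    return(tibble(region = character(), size = integer()))
  }
  membership <- vapply(genes, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1), USE.NAMES = FALSE)
  out <- count(tibble(region = membership), .data$region, name = "size")
  arrange(out, dplyr::desc(.data$size), .data$region)
}

#' Treatment overlap and specificity of DEG sets
#'
#' Exact set algebra over per-treatment DEG sets: per-treatment totals and
#' treatment-specific counts, the set shared by all treatments, and the size
#' of every non-empty membership region of the venn diagram.
#'
#' @param deg_sets Named list (length >= 2) of gene-id character vectors, or
#'   a DEG call tibble from [call_degs()] (genes with direction != "none"
#'   are grouped by condition).
#' @return An object of class `overlap_report`: list with `sets` (tibble
#'   `treatment`, `n`, `n_specific`), `shared_all` (character vector) and
#'   `regions` (tibble `region`, `size`).
#' @export
overlap_analysis <- function(deg_sets) {
  if (is.data.frame(deg_sets)) {
    hits <- filter(deg_sets, .data$direction != "none")
    deg_sets <- split(hits$gene_id, hits$condition)
  }
  if (length(deg_sets) < 2) abort("overlap_analysis needs >= 2 treatments")
  if (is.null(names(deg_sets)) || any(!nzchar(names(deg_sets)))) {
    abort("deg_sets must be named by treatment")
  }
  deg_sets <- lapply(deg_sets, unique)
  shared <- Reduce(intersect, deg_sets)
  sets <- tibble(
    treatment = names(deg_sets),
    n = vapply(deg_sets, length, integer(1)),
    n_specific = vapply(seq_along(deg_sets), function(i) {
      others <- unique(unlist(deg_sets[-i], use.names = FALSE))
      length(setdiff(deg_sets[[i]], others))
    }, integer(1))
  )
  structure(
    list(sets = sets, shared_all = sort(shared),
         regions = region_counts(deg_sets)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Treatment overlap across", nrow(x$sets), "sets;",
      length(x$shared_all), "genes shared by all\n")
  print(x$sets)
  invisible(x)
}

#' @rdname overlap_analysis
#' @param x,object An `overlap_report`.
#' @param ... Unused.
#' @export
tidy.overlap_report <- function(x, ...) x$regions

#' @rdname overlap_analysis
#' @export
glance.overlap_report <- function(x, ...) {
  tibble(
    n_treatments = nrow(x$sets),
    n_union = sum(x$regions$size),
    n_shared_all = length(x$shared_all)
  )
}

#' @rdname overlap_analysis
#' @export
autoplot.overlap_report <- function(object, ...) {
  ggplot2::ggplot(object$regions,
                  ggplot2::aes(x = stats::reorder(.data$region, -.data$size),
                               y = .data$size)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "membership region", y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Condition-specific expressed transcripts
#'
#' A gene is specific to condition X iff its mean FPKM exceeds
#' `expressed_threshold` in X and does not exceed it in any other condition.
#'
#' @param expr Expression tibble.
#' @param design Design tibble.
#' @param expressed_threshold Expression threshold (strict `>`, default 0).
#' @return Tibble (`gene_id`, `condition`) of specific transcripts only.
#' @export
specific_expressed <- function(expr, design, expressed_threshold = 0) {
  cm <- condition_means(expr, design)
  conds <- condition_levels(design)
  on <- as.matrix(cm[conds]) > expressed_threshold
  k <- rowSums(on)
  keep <- which(k == 1)
  tibble(
    gene_id = cm$gene_id[keep],
    condition = conds[max.col(on[keep, , drop = FALSE], ties.method = "first")]
  )
}
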