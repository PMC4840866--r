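#' Pearson product-moment correlation
#'
#' Thin, validated wrapper used by the network builders. A zero-variance
#' vector makes the correlation undefined; it is reported as `NA`, never 0.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("pcc needs at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  as.numeric(cor(x, y))
}

transform_values <- function(m, transform, log_offset) {
  switch(transform, log2 = log2(m + log_offset), none = m,
         abort(paste0("unknown transform: ", transform)))
}

cor_rows <- function(m_a, m_b = NULL) {
  suppressWarnings(if (is.null(m_b)) cor(t(m_a)) else cor(t(m_a), t(m_b)))
}

restrict_libraries <- function(expr, design, conditions) {
  if (is.null(conditions)) return(expr)
  missing_cond <- setdiff(conditions, condition_levels(design))
  if (length(missing_cond) > 0) {
    abort(paste0("condition not in design: ", missing_cond[[1]]))
  }
  libs <- design$library_id[design$condition %in% conditions]
  if (length(libs) < 3) abort("fewer than 3 libraries after restriction")
  expr[c("gene_id", libs)]
}

check_nodes <- function(nodes, expr) {
  missing_nodes <- setdiff(nodes, expr$gene_id)
  if (length(missing_nodes) > 0) {
    abort(paste0("node(s) absent from matrix: ",
                 paste(head(missing_nodes, 5), collapse = ", ")))
  }
}

#' Build a Pearson-correlation coexpression network
#'
#' Computes pairwise correlations of the transformed expression profiles
#' (default `log2(FPKM + 1)`) and keeps edges with `|PCC|` strictly above
#' the threshold. Edges are undirected and deduplicated with
#' `node_a < node_b`; self-pairs are excluded; pairs with undefined
#' correlation (a zero-variance profile) are dropped.
#'
#' @param expr Expression tibble.
#' @param nodes_a Character vector of node gene ids; default all genes.
#' @param nodes_b Optional second node set: edges are then restricted to
#'   (a, b) pairs between the two sets.
#' @param threshold Strict threshold on `|PCC|` (e.g. 0.8 for a TF
#'   interaction network, 0.95 for a lncRNA-mRNA network).
#' @param transform `"log2"` (default) or `"none"` (raw FPKM).
#' @param log_offset Offset for the log transform.
#' @param node_classes Optional named character vector (gene id -> class,
#'   e.g. `"lncRNA"`, `"coding"`, `"TF"`) used to label each edge's
#'   `pair_type`.
#' @param design,conditions Optional design + condition labels restricting
#'   the correlation to the libraries of those conditions.
#' @return An object of class `coexpression_network`: an edge tibble
#'   (`node_a`, `node_b`, `pcc`, `sign`, and `pair_type` when classes are
#'   given) ordered lexicographically, with the threshold and node count as
#'   attributes.
#' @export
build_network <- function(expr, nodes_a = NULL, nodes_b = NULL,
                          threshold = 0.95, transform = c("log2", "none"),
                          log_offset = 1, node_classes = NULL,
                          design = NULL, conditions = NULL) {
  transform <- match.arg(transform)
  stopifnot(threshold > 0, threshold <= 1)
  if (!is.null(conditions)) {
    if (is.null(design)) abort("design is required to restrict conditions")
    expr <- restrict_libraries(expr, design, conditions)
  }
  if (is.null(nodes_a)) nodes_a <- expr$gene_id
  check_nodes(nodes_a, expr)
  if (!is.null(nodes_b)) check_nodes(nodes_b, expr)
  m <- transform_values(expr_matrix(expr), transform, log_offset)

  if (is.null(nodes_b)) {
    nodes_a <- sort(unique(nodes_a))
    cc <- cor_rows(m[nodes_a, , drop = FALSE])
    idx <- which(upper.tri(cc), arr.ind = TRUE)
    edges <- tibble(
      node_a = nodes_a[idx[, 1]], node_b = nodes_a[idx[, 2]],
      pcc = cc[idx]
    )
  } else {
    ca <- cor_rows(m[unique(nodes_a), , drop = FALSE],
                   m[unique(nodes_b), , drop = FALSE])
    idx <- which(!is.na(ca) | is.na(ca), arr.ind = TRUE)
    edges <- tibble(
      node_a = rownames(ca)[idx[, 1]], node_b = colnames(ca)[idx[, 2]],
      pcc = ca[idx]
    )
    edges <- filter(edges, .data$node_a != .data$node_b)
    flip <- edges$node_a > edges$node_b
    tmp <- edges$node_a[flip]
    edges$node_a[flip] <- edges$node_b[flip]
    edges$node_b[flip] <- tmp
    edges <- distinct(edges, .data$node_a, .data$node_b, .keep_all = TRUE)
  }
  edges <- filter(edges, !is.na(.data$pcc), abs(.data$pcc) > threshold)
  edges <- mutate(edges,
                  sign = ifelse(.data$pcc > 0, "positive", "negative"))
  if (!is.null(node_classes)) {
    cls_a <- unname(node_classes[edges$node_a])
    cls_b <- unname(node_classes[edges$node_b])
    edges$pair_type <- paste(pmin(cls_a, cls_b), pmax(cls_a, cls_b),
                             sep = "-")
  }
  edges <- arrange(edges, .data$node_a, .data$node_b)
  structure(edges,
            class = c("coexpression_network", class(edges)),
            threshold = threshold,
            n_nodes = length(unique(c(edges$node_a, edges$node_b))))
}

#' @rdname build_network
#' @param x,object A `coexpression_network`.
#' @param ... Unused.
#' @export
tidy.coexpression_network <- function(x, ...) {
  as_tibble(unclass(x)[c(intersect(c("node_a", "node_b", "pcc", "sign",
                                     "pair_type"), names(x)))])
}

#' @rdname build_network
#' @export
glance.coexpression_network <- function(x, ...) {
  cen <- sign_census(x)
  tibble(
    n_edges = nrow(x),
    n_nodes = attr(x, "n_nodes"),
    threshold = attr(x, "threshold"),
    n_positive = cen$n_positive,
    n_negative = cen$n_negative
  )
}

#' @rdname build_network
#' @export
autoplot.coexpression_network <- function(object, ...) {
  edges <- tidy(object)
  g <- igraph::graph_from_data_frame(edges[c("node_a", "node_b")],
                                     directed = FALSE)
  set.seed(1)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = lay[, 1], y = lay[, 2])
  seg <- left_join(edges, nodes, by = c(node_a = "name")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes, by = c(node_b = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x,
                   yend = .data$y, colour = .data$sign),
      linewidth = 0.3
    ) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 1.5) +
    ggplot2::scale_colour_manual(values = c(positive = "steelblue",
                                            negative = "firebrick")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "correlation sign")
}

#' Sign census of a network's edges
#'
#' @param edges Edge tibble with a `pcc` column.
#' @return One-row tibble (`n_positive`, `n_negative`, `prop_positive`,
#'   `prop_negative`); proportions are `NA` for an empty edge list and are
#'   taken over nonzero-correlation edges.
#' @export
sign_census <- function(edges) {
  nz <- edges$pcc[!is.na(edges$pcc) & edges$pcc != 0]
  n_pos <- sum(nz > 0)
  n_neg <- sum(nz < 0)
  tot <- n_pos + n_neg
  tibble(
    n_positive = n_pos, n_negative = n_neg,
    prop_positive = if (tot > 0) n_pos / tot else NA_real_,
    prop_negative = if (tot > 0) n_neg / tot else NA_real_
  )
}

#' Connected components of a coexpression network
#'
#' Clusters are the connected components of the undirected edge graph,
#' ordered by decreasing size and then by lexicographically smallest member.
#'
#' @param edges Edge tibble (`node_a`, `node_b`, `pcc`).
#' @return Tibble (`cluster`, `n_nodes`, `n_edges`, `n_positive`,
#'   `n_negative`, `members` list-column of sorted node ids).
#' @export
network_components <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble(cluster = integer(), n_nodes = integer(),
                  n_edges = integer(), n_positive = integer(),
                  n_negative = integer(), members = list()))
  }
  g <- igraph::graph_from_data_frame(edges[c("node_a", "node_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  member_of <- setNames(comp$membership, igraph::V(g)$name)
  groups <- split(names(member_of), member_of)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, `[[`, character(1), 1))
  groups <- groups[ord]
  rows <- lapply(seq_along(groups), function(i) {
    mem <- groups[[i]]
    in_comp <- edges$node_a %in% mem
    tibble(
      cluster = i, n_nodes = length(mem), n_edges = sum(in_comp),
      n_positive = sum(in_comp & edges$pcc > 0),
      n_negative = sum(in_comp & edges$pcc < 0),
      members = list(mem)
    )
  })
  bind_rows(rows)
}

#' Link source transcripts to correlated candidate targets
#'
#' For each source (e.g. a lncRNA or a transcription factor), reports the
#' candidate genes whose expression correlation with the source exceeds
#' `min_pcc` strictly (on the Pearson correlation itself, or on its
#' absolute value with `use_abs = TRUE`). Optionally restricted to the
#' libraries of given conditions.
#'
#' @param expr Expression tibble.
#' @param sources,candidates Disjoint character vectors of gene ids.
#' @param min_pcc Strict lower bound on the (signed or absolute)
#'   correlation.
#' @param use_abs Threshold `|PCC|` instead of signed PCC.
#' @param transform,log_offset As in [build_network()].
#' @param design,conditions Optional library restriction by condition.
#' @return Tibble (`source`, `target`, `pcc`).
#' @export
link_targets <- function(expr, sources, candidates, min_pcc = 0.9,
                         use_abs = FALSE, transform = c("log2", "none"),
                         log_offset = 1, design = NULL, conditions = NULL) {
  transform <- match.arg(transform)
  if (length(intersect(sources, candidates)) > 0) {
    abort("sources and candidates must be disjoint")
  }
  if (!is.null(conditions)) {
    if (is.null(design)) abort("design is required to restrict conditions")
    expr <- restrict_libraries(expr, design, conditions)
  }
  check_nodes(c(sources, candidates), expr)
  m <- transform_values(expr_matrix(expr), transform, log_offset)
  cc <- cor_rows(m[sources, , drop = FALSE], m[candidates, , drop = FALSE])
  val <- if (use_abs) abs(cc) else cc
  idx <- which(!is.na(val) & val > min_pcc, arr.ind = TRUE)
  out <- tibble(
    source = sources[idx[, 1]],
    target = candidates[idx[, 2]],
    pcc = cc[idx]
  )
  arrange(out, .data$source, .data$target)
}

#' Intersect target linkages across runs
#'
#' Keeps only (source, target) pairs present in every linkage table, e.g.
#' targets recovered under each of several condition-restricted runs.
#'
#' @param ... Linkage tibbles from [link_targets()], or one list of them.
#' @return Tibble (`source`, `target`) of pairs common to all runs.
#' @export
intersect_targets <- function(...) {
  runs <- list(...)
  if (length(runs) == 1 && !is.data.frame(runs[[1]])) runs <- runs[[1]]
  if (length(runs) < 2) abort("intersect_targets needs >= 2 runs")
  keys <- lapply(runs, function(r) paste(r$source, r$target, sep = "\r"))
  common <- Reduce(intersect, keys)
  first <- runs[[1]]
  keep <- keys[[1]] %in% common
  arrange(tibble(source = first$source[keep], target = first$target[keep]),
          .data$source, .data$target)
}

#' Export a network as GraphML
#'
#' @param edges Edge tibble (`node_a`, `node_b`, `pcc`, ...).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$node_a, to = edges$node_b, pcc = edges$pcc),
    directed = FALSE
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
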