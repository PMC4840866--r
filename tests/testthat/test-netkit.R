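test_that("pcc matches hand-derived values and handles degenerate input", {
  expect_equal(pcc(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pcc(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_equal(pcc(c(1, 2, 3), c(1, 3, 2)), brute_pcc(c(1, 2, 3), c(1, 3, 2)))
  expect_true(is.na(pcc(c(1, 1, 1), c(1, 2, 3))))
  expect_error(pcc(1:2, 1:3), "equal length")
  expect_error(pcc(1:2, 2:1), "at least 3")
})

# raw-valued test matrix: 5 libraries, controlled profiles
net_expr <- function() {
  libs <- paste0("L", 1:5)
  make_expr(c(1, 2, 3, 4, 5,        # a
              2, 4, 6, 8, 10,       # b: pcc(a,b) = 1
              5, 4, 3, 2, 1,        # c: pcc(a,c) = -1
              1, 3, 2, 5, 4),       # d: intermediate
            c("a", "b", "c", "d"), libs)
}

test_that("network edges respect the strict absolute threshold", {
  expr <- net_expr()
  net <- build_network(expr, threshold = 0.95, transform = "none")
  expect_equal(nrow(net), 3L)  # a-b, a-c, b-c
  ab <- net[net$node_a == "a" & net$node_b == "b", ]
  expect_equal(ab$pcc, 1)
  expect_equal(ab$sign, "positive")
  ac <- net[net$node_a == "a" & net$node_b == "c", ]
  expect_equal(ac$sign, "negative")
  expect_true(all(net$node_a < net$node_b))

  # |pcc| exactly at the threshold is excluded
  r_ad <- pcc(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  at <- build_network(expr, nodes_a = c("a", "d"), threshold = r_ad,
                      transform = "none")
  expect_equal(nrow(at), 0L)
  below <- build_network(expr, nodes_a = c("a", "d"),
                         threshold = r_ad - 1e-9, transform = "none")
  expect_equal(nrow(below), 1L)

  expect_error(build_network(expr, nodes_a = c("a", "zz")), "zz")
})

test_that("edges are invariant to gene order and global rescaling", {
  expr <- net_expr()
  net <- build_network(expr, threshold = 0.9, transform = "none")
  shuf <- expr[c(3, 1, 4, 2), ]
  net2 <- build_network(shuf, threshold = 0.9, transform = "none")
  expect_equal(as.data.frame(net2), as.data.frame(net))
  scaled <- dplyr::mutate(expr, dplyr::across(-gene_id, ~ .x * 7.3))
  net3 <- build_network(scaled, threshold = 0.9, transform = "none")
  expect_equal(net3$pcc, net$pcc)
})

test_that("network construction agrees with the brute-force all-pairs loop", {
  set.seed(30)
  n <- 60
  libs <- paste0("L", 1:8)
  expr <- make_expr(10^runif(n * 8, 0, 3), sprintf("g%03d", 1:n), libs)
  thr <- 0.7
  net <- build_network(expr, threshold = thr, transform = "log2")
  m <- log2(as.matrix(expr[libs]) + 1)
  expected <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- brute_pcc(m[i, ], m[j, ])
    if (abs(r) > thr) {
      expected[[length(expected) + 1]] <- data.frame(
        node_a = expr$gene_id[i], node_b = expr$gene_id[j], pcc = r
      )
    }
  }
  expected <- do.call(rbind, expected)
  expected <- expected[order(expected$node_a, expected$node_b), ]
  expect_equal(nrow(net), nrow(expected))
  expect_equal(net$node_a, expected$node_a)
  expect_equal(net$pcc, expected$pcc, tolerance = 1e-12)
})

test_that("sign census reports counts and proportions over signed edges", {
  edges <- tibble::tibble(pcc = c(rep(0.99, 82), rep(-0.97, 13)))
  cen <- sign_census(edges)
  expect_equal(cen$n_positive, 82L)
  expect_equal(cen$n_negative, 13L)
  expect_equal(cen$prop_positive, 82 / 95)
  expect_equal(cen$prop_negative, 13 / 95)
  allpos <- sign_census(tibble::tibble(pcc = c(0.96, 0.98)))
  expect_equal(c(allpos$prop_positive, allpos$prop_negative), c(1, 0))
  none <- sign_census(tibble::tibble(pcc = numeric()))
  expect_true(is.na(none$prop_positive))
  expect_equal(none$n_positive + none$n_negative, 0L)
})

test_that("connected components cluster nodes deterministically", {
  edges <- tibble::tibble(
    node_a = c("a", "b", "d"), node_b = c("b", "c", "e"),
    pcc = c(0.99, 0.98, -0.97)
  )
  comp <- network_components(edges)
  expect_equal(comp$n_nodes, c(3L, 2L))
  expect_equal(comp$members[[1]], c("a", "b", "c"))
  expect_equal(comp$n_negative, c(0L, 1L))
  expect_equal(sum(comp$n_edges), nrow(edges))

  expect_equal(nrow(network_components(edges[0, ])), 0L)

  # complete graph on 4 nodes -> one cluster with 6 edges
  k4 <- t(combn(letters[1:4], 2))
  comp4 <- network_components(tibble::tibble(
    node_a = k4[, 1], node_b = k4[, 2], pcc = 0.99
  ))
  expect_equal(nrow(comp4), 1L)
  expect_equal(comp4$n_edges, 6L)
  expect_equal(comp4$n_nodes, 4L)
})

test_that("target linkage thresholds strictly and matches enumeration", {
  expr <- net_expr()
  lk <- link_targets(expr, sources = "a", candidates = c("b", "c", "d"),
                     min_pcc = 0.9, transform = "none")
  expect_equal(lk$target, "b")
  expect_equal(lk$pcc, 1)
  lk_abs <- link_targets(expr, "a", c("b", "c", "d"), min_pcc = 0.9,
                         use_abs = TRUE, transform = "none")
  expect_setequal(lk_abs$target, c("b", "c"))
  expect_error(link_targets(expr, "a", c("a", "b")), "disjoint")

  # uncorrelated noise at a high bar: compare against brute enumeration
  set.seed(31)
  libs <- paste0("L", 1:5)
  rnd <- make_expr(runif(60, 1, 100), sprintf("n%02d", 1:12), libs)
  got <- link_targets(rnd, sources = c("n01", "n02"),
                      candidates = sprintf("n%02d", 3:12),
                      min_pcc = 0.9, transform = "log2")
  m <- log2(as.matrix(rnd[libs]) + 1)
  rownames(m) <- rnd$gene_id
  expected <- 0L
  for (s in c("n01", "n02")) for (t in sprintf("n%02d", 3:12)) {
    if (brute_pcc(m[s, ], m[t, ]) > 0.9) expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
})

test_that("linkage intersection keeps only pairs present in every run", {
  r1 <- tibble::tibble(source = c("s1", "s1"), target = c("t1", "t2"),
                       pcc = c(0.99, 0.97))
  r2 <- tibble::tibble(source = "s1", target = "t1", pcc = 0.98)
  got <- intersect_targets(r1, r2)
  expect_equal(nrow(got), 1L)
  expect_equal(got$target, "t1")
  expect_equal(intersect_targets(list(r1, r2)), got)
  expect_error(intersect_targets(r1), ">= 2")
})

test_that("planted coexpression pairs are recovered exactly at zero noise", {
  cs <- tibble::tibble(sign = c("positive", "negative"), n = c(4, 3))
  sim <- simulate_expression(n_genes = 80, coexpr_spec = cs, noise_sd = 0,
                             seed = 32)
  truth <- sim$truth$coexpr
  sources <- truth$source
  candidates <- setdiff(sim$expr$gene_id, sources)
  lk <- link_targets(sim$expr, sources, candidates, min_pcc = 0.95,
                     use_abs = TRUE)
  expect_setequal(paste(lk$source, lk$target),
                  paste(truth$source, truth$target))
  merged <- dplyr::inner_join(lk, truth,
                              by = c(source = "source", target = "target"))
  expect_equal(sign(merged$pcc), merged$planted_pcc)
  expect_equal(abs(merged$pcc), rep(1, nrow(merged)), tolerance = 1e-9)
})

test_that("condition restriction uses only the requested libraries", {
  design <- default_design(c("T25", "T4"), n_reps = 3)
  # correlated within T25 libraries, anti within T4
  expr <- make_expr(c(1, 2, 3, 3, 2, 1,
                      2, 4, 6, 1, 2, 3), c("x", "y"), design$library_id)
  all_lk <- link_targets(expr, "x", "y", min_pcc = 0.95,
                         transform = "none", design = design,
                         conditions = "T25")
  expect_equal(nrow(all_lk), 1L)
  expect_error(
    link_targets(expr, "x", "y", design = design, conditions = "T9"),
    "T9"
  )
  net <- build_network(expr, threshold = 0.9, transform = "none",
                       design = design, conditions = "T25")
  expect_equal(nrow(net), 1L)
})

test_that("network summaries, classes and GraphML export round-trip", {
  expr <- net_expr()
  classes <- c(a = "lncRNA", b = "coding", c = "coding", d = "TF")
  net <- build_network(expr, threshold = 0.9, transform = "none",
                       node_classes = classes)
  expect_true(all(net$pair_type %in% c("coding-lncRNA", "coding-coding")))
  g <- glance(net)
  expect_equal(g$n_edges, nrow(net))
  expect_equal(g$n_positive + g$n_negative, nrow(net))
  expect_s3_class(tidy(net), "tbl_df")
  expect_s3_class(autoplot(net), "ggplot")

  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gsize(back), nrow(net))
})
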