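edge_keys_test <- function(net) paste(net$edges$gene_a, net$edges$gene_b)

make_expr <- function(mat, genes = sprintf("g%02d", seq_len(nrow(mat)))) {
  n <- ncol(mat) / 2
  samples <- c(sprintf("null_%d", seq_len(n)), sprintf("mir142_%d", seq_len(n)))
  colnames(mat) <- samples
  list(expr = dplyr::bind_cols(tibble::tibble(gene = genes),
                               tibble::as_tibble(mat)),
       conditions = tibble::tibble(sample = samples,
                                   condition = rep(c("null", "mir142"),
                                                   each = n)))
}

test_that("pairwise Pearson correlations match hand values and the loop oracle", {
  d <- make_expr(rbind(c(1, 2, 3, 0, 0, 1), c(2, 4, 6, 0, 1, 0),
                       c(3, 2, 1, 1, 0, 0), c(1, 2, 4, 1, 1, 0),
                       c(1, 3, 4, 0, 1, 1)))
  pp <- pearson_pairs(d$expr, d$conditions, "null")
  expect_equal(nrow(pp), choose(5, 2))
  r_of <- function(a, b) pp$r[pp$gene_a == a & pp$gene_b == b]
  expect_equal(r_of("g01", "g02"), 1)
  expect_equal(r_of("g01", "g03"), -1)
  expect_equal(r_of("g04", "g05"), 13 / 14)

  # naive per-pair loop oracle on a random 50-gene matrix
  set.seed(20)
  dd <- make_expr(matrix(rnorm(50 * 6), nrow = 50))
  ppr <- pearson_pairs(dd$expr, dd$conditions, "mir142")
  mat <- as.matrix(dd$expr[dd$conditions$sample[dd$conditions$condition ==
                                                  "mir142"]])
  rownames(mat) <- dd$expr$gene
  for (i in sample(nrow(ppr), 40)) {
    expect_equal(ppr$r[i],
                 stats::cor(mat[ppr$gene_a[i], ], mat[ppr$gene_b[i], ]),
                 tolerance = 1e-12)
  }
})

test_that("zero-variance genes are dropped with a warning, tiny conditions rejected", {
  d <- make_expr(rbind(c(1, 2, 3, 0, 0, 1), c(5, 5, 5, 0, 1, 0),
                       c(3, 2, 1, 1, 0, 0)))
  expect_warning(pp <- pearson_pairs(d$expr, d$conditions, "null"),
                 "zero-variance")
  expect_equal(attr(pp, "dropped_genes"), "g02")
  expect_equal(nrow(pp), 1L)
  cond2 <- d$conditions[c(1, 2, 4, 5, 6), ]
  expect_error(pearson_pairs(d$expr, cond2, "null"), "fewer than 3")
})

test_that("correlation p-values follow the exact t reference distribution", {
  expect_equal(cor_pvalue(0, 5), 1)
  expect_equal(cor_pvalue(1, 3), 0)
  expect_equal(cor_pvalue(-1, 4), 0)
  # closed form at df = 1: p = 1 - (2/pi) * atan(|t|)
  r <- 0.9998
  t_ <- r * sqrt(1 / (1 - r^2))
  expect_equal(cor_pvalue(r, 3), 1 - (2 / pi) * atan(t_), tolerance = 1e-12)
  expect_equal(cor_pvalue(r, 3), 0.012732, tolerance = 1e-4)
  # agreement with cor.test
  set.seed(3)
  for (n in c(3, 5, 8)) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(cor_pvalue(cor(x, y), n), cor.test(x, y)$p.value,
                 tolerance = 1e-12)
  }
  # strictly decreasing in |r|
  rs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(cor_pvalue(rs, 6)) < 0))
  expect_error(cor_pvalue(0.5, 2), "3 samples")
})

test_that("p-value adjustment matches the step formulas and ordering invariants", {
  expect_equal(adjust_pvalues(0.05, "BH"), 0.05)
  expect_equal(adjust_pvalues(rep(0.5, 3), "bonferroni"), rep(1, 3))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
  set.seed(9)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(adjust_pvalues(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    bh <- adjust_pvalues(p, "BH"); holm <- adjust_pvalues(p, "holm")
    hoch <- adjust_pvalues(p, "hochberg"); bonf <- adjust_pvalues(p, "bonferroni")
    expect_true(all(bonf >= holm - 1e-12))
    expect_true(all(holm >= bh - 1e-12))
    expect_true(all(holm >= hoch - 1e-12))
    for (adj in list(bh, holm, hoch, bonf)) {
      expect_true(all(adj >= p - 1e-12 & adj <= 1))
    }
  }
})

test_that("network construction retains only positive suprathreshold edges", {
  pairs <- tibble::tibble(
    gene_a = c("a", "a", "b", "c"), gene_b = c("b", "c", "c", "d"),
    r = c(0.99995, -0.9999, 0.9999, 0.5),
    p_raw = cor_pvalue(abs(c(0.99995, -0.9999, 0.9999, 0.5)), 3))
  net <- build_network(pairs, r_min = 0.9998)
  expect_s3_class(net, "coex_network")
  expect_equal(nrow(net$edges), 2L) # negative edge excluded despite |r|
  expect_equal(net$nodes, c("a", "b", "c"))
  expect_equal(net$r_min_retained, 0.9999)
  expect_error(build_network(pairs, r_min = 1.5), "r_min")

  # raising r_min is monotone: never adds nodes or edges
  net_hi <- build_network(pairs, r_min = 0.99992)
  expect_true(all(edge_keys_test(net_hi) %in% edge_keys_test(net)))
  expect_true(all(net_hi$nodes %in% net$nodes))

  # adjusted-p mode
  netp <- build_network(pairs, mode = "adjusted-p", alpha = 0.05,
                        method = "bonferroni")
  expect_gt(nrow(netp$edges), 0L)
  expect_true(all(netp$edges$p_adj <= 0.05))
})

test_that("an empty retained set yields an empty network with zero density", {
  pairs <- tibble::tibble(gene_a = "a", gene_b = "b", r = -0.5,
                          p_raw = 0.5)
  net <- build_network(pairs)
  st <- network_stats(net)
  expect_equal(st$n_nodes, 0L)
  expect_equal(st$n_edges, 0L)
  expect_equal(st$density, 0)
  expect_false(st$density_defined)
  expect_true(is.na(net$r_min_retained))
})

test_that("edge density reproduces the published network table arithmetic", {
  expect_equal(round(edge_density(57, 217), 3), 0.136)
  expect_equal(round(edge_density(52, 158), 3), 0.119)
  expect_equal(edge_density(4, 6), 1) # complete graph
})

test_that("network comparison is symmetric with correct Jaccard arithmetic", {
  pairs <- tibble::tibble(gene_a = c("a", "c"), gene_b = c("b", "d"),
                          r = c(0.9999, 0.99991), p_raw = c(0.01, 0.01))
  net <- build_network(pairs)
  self <- compare_networks(net, net)
  expect_equal(self$node_jaccard, 1)
  expect_equal(self$edge_jaccard, 1)

  half <- build_network(pairs[1, ])
  cmp <- compare_networks(half, net)
  expect_equal(cmp$node_jaccard, 0.5)
  expect_equal(cmp$shared_edges, 1L)
  expect_identical(cmp, compare_networks(net, half))

  other <- build_network(tibble::tibble(gene_a = "x", gene_b = "y",
                                        r = 0.9999, p_raw = 0.01))
  expect_equal(compare_networks(net, other)$shared_nodes, 0L)
  expect_equal(compare_networks(net, other)$edge_jaccard, 0)
})

test_that("tidy and glance expose the edge list and the stats row", {
  pairs <- tibble::tibble(gene_a = "a", gene_b = "b", r = 0.9999,
                          p_raw = 0.01)
  net <- build_network(pairs, condition = "null")
  expect_equal(tidy(net)$r, 0.9999)
  g <- glance(net)
  expect_equal(g$condition, "null")
  expect_equal(g$n_edges, 1L)
})
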