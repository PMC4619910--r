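test_that("invalid simulation configs are rejected", {
  expect_error(tiny_sim(n_genes = 5), "exceed")
  expect_error(tiny_sim(n_per_group = 2), "n_per_group")
  expect_error(tiny_sim(clique_noise_sd = 0.5, background_sd = 0.5),
               "clique_noise_sd")
  expect_error(tiny_sim(cliques_null = list(c("g0001", "g0002"),
                                            c("g0002", "g0003"))),
               "two cliques")
  expect_error(tiny_sim(planted_sites = tibble::tibble(
    gene = "zz", arm = "5p", quality = "exact", count = 1L)), "unknown genes")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- tiny_sim(planted_sites = NULL, n_genes = 30, n_de_genes = 4,
                  cliques_null = c(4), cliques_mir142 = c(3))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  ua <- simulate_utrs(cfg)
  ub <- simulate_utrs(cfg)
  expect_identical(ua, ub)
  # a different seed changes the draw
  c_ <- simulate_expression(tiny_sim(planted_sites = NULL, n_genes = 30,
                                     n_de_genes = 4, cliques_null = c(4),
                                     cliques_mir142 = c(3), rng_seed = 999L))
  expect_false(identical(a$expression, c_$expression))
})

test_that("matrix shape and condition labels follow the design", {
  cfg <- tiny_sim(n_per_group = 4)
  sim <- simulate_expression(cfg)
  expect_equal(nrow(sim$expression), 40L)
  expect_equal(ncol(sim$expression), 1L + 8L)
  expect_equal(table(sim$conditions$condition),
               table(factor(rep(c("mir142", "null"), each = 4))))
  expect_true(all(sim$conditions$sample %in% names(sim$expression)))
})

test_that("zero-noise cliques have unit within-clique correlation in their condition", {
  cfg <- tiny_sim(n_genes = 20, cliques_null = c(5), cliques_mir142 = integer(0),
                  n_de_genes = 0, clique_noise_sd = 0)
  sim <- simulate_expression(cfg)
  genes <- sim$truth$cliques$gene
  cols <- sim$conditions$sample[sim$conditions$condition == "null"]
  cm <- stats::cor(t(as.matrix(sim$expression[match(genes, sim$expression$gene),
                                              cols])))
  expect_equal(unname(cm[upper.tri(cm)]), rep(1, 10), tolerance = 1e-12)
})

test_that("cross-clique correlations are centred at zero", {
  cfg <- tiny_sim(n_genes = 60, n_per_group = 20,
                  cliques_null = c(5, 5), cliques_mir142 = integer(0),
                  n_de_genes = 0, clique_noise_sd = 0)
  sim <- simulate_expression(cfg)
  truth <- sim$truth$cliques
  g1 <- truth$gene[truth$clique == "null_c1"]
  g2 <- truth$gene[truth$clique == "null_c2"]
  cols <- sim$conditions$sample[sim$conditions$condition == "null"]
  mat <- as.matrix(sim$expression[-1])[, cols]
  rownames(mat) <- sim$expression$gene
  cross <- as.vector(stats::cor(t(mat[g1, ]), t(mat[g2, ])))
  expect_lt(abs(mean(cross)), 0.35) # 25 correlations at n = 20
})

test_that("fully separated planted DE genes all sit at the exact 3v3 rank-sum floor", {
  cfg <- tiny_sim(n_genes = 40, cliques_null = integer(0),
                  cliques_mir142 = integer(0), n_de_genes = 10,
                  de_shift = 5, background_sd = 0.1, clique_noise_sd = 0.001)
  sim <- simulate_expression(cfg)
  de <- run_diffexp(sim$expression, sim$conditions, test = "wrs")
  planted <- de[de$gene %in% sim$truth$de$gene, ]
  # enumeration oracle: 1 of the C(6,3)=20 assignments at the observed
  # extreme, doubled for two sides
  expect_equal(planted$p_raw, rep(2 * 1 / 20, 10))
  expect_equal(planted$direction, sim$truth$de$direction)
})

test_that("background UTRs are free of all exact and mutant sites of both arms", {
  cfg <- tiny_sim(n_genes = 50, planted_sites = "none",
                  utr_length_range = c(80L, 160L))
  sim <- simulate_utrs(cfg)
  expect_equal(nrow(scan_utrs(sim$utrs)), 0L)
  lens <- nchar(sim$utrs$sequence)
  expect_true(all(lens >= 80 & lens <= 160))
})

test_that("planted sites are recovered by the scanner at manifest positions", {
  plan <- tibble::tibble(gene = c("g0001", "g0002", "g0002"),
                         arm = c("5p", "3p", "5p"),
                         quality = c("exact", "inexact", "exact"),
                         count = c(1L, 1L, 1L))
  cfg <- tiny_sim(n_genes = 10, cliques_null = integer(0),
                  cliques_mir142 = integer(0), n_de_genes = 0,
                  planted_sites = plan, utr_length_range = c(120L, 160L))
  sim <- simulate_utrs(cfg)
  hits <- scan_utrs(sim$utrs)
  truth <- dplyr::arrange(sim$truth$sites, gene, position)
  expect_equal(hits$gene, truth$gene)
  expect_equal(hits$position, truth$position)
  expect_equal(hits$arm, truth$arm)
  expect_equal(hits$quality, truth$quality)
})

test_that("UTRs too short for the requested sites are rejected", {
  plan <- tibble::tibble(gene = "g0001", arm = "5p", quality = "exact",
                         count = 5L)
  cfg <- tiny_sim(n_genes = 5, cliques_null = integer(0),
                  cliques_mir142 = integer(0), n_de_genes = 0,
                  planted_sites = plan, utr_length_range = c(20L, 25L))
  expect_error(simulate_utrs(cfg), "too short")
})

test_that("ground-truth manifests round-trip through JSON unchanged", {
  cfg <- tiny_sim(n_genes = 15, planted_sites = tibble::tibble(
    gene = "g0003", arm = "3p", quality = "exact", count = 1L))
  sim <- simulate_expression(cfg)
  us <- simulate_utrs(cfg)
  truth <- c(sim$truth, us$truth["sites"])
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$cliques, sim$truth$cliques)
  expect_equal(back$de, sim$truth$de)
  expect_equal(back$sites, us$truth$sites)
  expect_equal(back$rng_seed, cfg$rng_seed)
})
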