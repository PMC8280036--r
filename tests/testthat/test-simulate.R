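test_that("generators are seed-deterministic and truth-complete", {
  cfg <- simulation_config(n_genes = 40L, n_trios = 100L, n_cases = 120L,
                           n_controls = 300L)
  a <- simulate_cohort(cfg, seed = 17L)
  b <- simulate_cohort(cfg, seed = 17L)
  expect_identical(a, b)
  expect_false(identical(a$variants, simulate_cohort(cfg, seed = 18L)$variants))
  # truth covers every gene with planted rate and risk status
  expect_identical(a$truth$gene, a$mutation_rates$gene)
  expect_true(all(a$variants$gene[!grepl("^noise", a$variants$variant_id)]
                  %in% a$truth$gene))
  e1 <- simulate_expression(cfg, seed = 2L)
  e2 <- simulate_expression(cfg, seed = 2L)
  expect_identical(e1, e2)
  p1 <- simulate_ppi(cfg, e1$modules, seed = 2L)
  expect_identical(p1, simulate_ppi(cfg, e1$modules, seed = 2L))
})

test_that("simulated qualifying counts follow the planted Poisson model", {
  # gamma = 1 everywhere: de novo count totals match 2*N*mu in expectation
  cfg <- simulation_config(n_genes = 300L, n_trios = 1000L,
                           gamma_ptv = 1, gamma_dmis = 1, gamma_cc = 1,
                           n_noise_variants = 0L)
  ch <- simulate_cohort(cfg, seed = 4L)
  sel <- select_potential_functional(ch$variants)
  counts <- tabulate_gene_counts(sel, ch$n_trios, ch$n_cases, ch$n_controls,
                                 ch$control_variants,
                                 genes = ch$mutation_rates$gene)
  lam <- 2 * cfg$n_trios * sum(ch$mutation_rates$mu_PTV)
  total <- sum(counts$x_dn_PTV)
  expect_lt(abs(total - lam) / sqrt(lam), 4)   # within 4 sd of Poisson total
  # every generated qualifying row survives the filters (round-trip property)
  expect_identical(nrow(sel), nrow(ch$variants))
})

test_that("noise rows are rejected by the functional and frequency filters", {
  cfg <- simulation_config(n_genes = 30L, n_trios = 50L,
                           n_noise_variants = 40L)
  ch <- simulate_cohort(cfg, seed = 9L)
  sel <- select_potential_functional(ch$variants)
  expect_false(any(grepl("^noise", sel$variant_id)))
})

test_that("expression modules hit the designed within-module correlation", {
  cfg <- simulation_config(n_genes = 100L, n_modules = 2L, module_size = 20L,
                           expr_samples = c(postnatal_cortical = 100L,
                                            prenatal_cortical = 0L,
                                            postnatal_noncortical = 0L))
  sim <- simulate_expression(cfg, seed = 7L)
  expect_equal(sim$expected_abs_r, 0.9)
  mod1 <- sim$modules$gene[sim$modules$module == 1L]
  r <- cor(t(sim$expr[mod1, ]))
  mean_abs_r <- mean(abs(r[upper.tri(r)]))
  expect_lt(abs(mean_abs_r - 0.9), 0.05)
  # no latent factor: |r| > 0.7 edges are (near) absent
  cfg0 <- simulation_config(n_genes = 100L, loading = 0,
                            expr_samples = c(postnatal_cortical = 100L,
                                             prenatal_cortical = 0L,
                                             postnatal_noncortical = 0L))
  sim0 <- simulate_expression(cfg0, seed = 7L)
  g0 <- coexpression_edges(sim0$expr, 0.7)
  expect_lt(igraph::ecount(g0), 3)
  # metadata filter leaves exactly the configured postnatal cortical count
  cfg2 <- simulation_config(n_genes = 20L)
  sim2 <- simulate_expression(cfg2, seed = 1L)
  kept <- select_postnatal_cortical(sim2$expr, sim2$metadata)
  expect_identical(ncol(kept), 60L)
})

test_that("PPI scores concentrate above threshold within modules only", {
  cfg <- simulation_config(n_genes = 100L, n_modules = 2L, module_size = 20L)
  modules <- simulate_expression(cfg, seed = 3L)$modules
  ppi <- simulate_ppi(cfg, modules, seed = 3L)
  g <- ppi_edges(ppi, 0.45)
  el <- igraph::as_edgelist(g)
  mod <- modules$module[match(el, modules$gene)]
  dim(mod) <- dim(el)
  within <- mod[, 1] > 0 & mod[, 1] == mod[, 2]
  # most retained edges are within-module; within-module retained density
  # near the configured edge probability times P(score >= 0.45)
  expect_gt(mean(within), 0.8)
  n_within_pairs <- 2 * choose(20, 2)
  keep_prob <- cfg$ppi_within_prob * (1 - pbeta(0.45, 8, 2))
  expect_lt(abs(sum(within) / n_within_pairs - keep_prob), 0.1)
  # background-only configuration gives a near-empty thresholded graph
  cfg0 <- simulation_config(n_genes = 100L, ppi_within_prob = 0,
                            ppi_background_prob = 0.01)
  ppi0 <- simulate_ppi(cfg0, modules, seed = 3L)
  g0 <- ppi_edges(ppi0, 0.45)
  expect_lt(igraph::ecount(g0), 0.05 * choose(100, 2))
})

test_that("generated tables round-trip through the TSV readers", {
  cfg <- simulation_config(n_genes = 25L, n_trios = 60L)
  ch <- simulate_cohort(cfg, seed = 6L)
  dir <- withr::local_tempdir()
  vp <- file.path(dir, "variants.tsv")
  write.table(ch$variants, vp, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  back <- read_variant_table(vp)
  expect_equal(back$reve, ch$variants$reve)
  expect_identical(back$gt_father, ch$variants$gt_father)
  sel <- select_potential_functional(ch$variants)
  counts <- tabulate_gene_counts(sel, ch$n_trios, ch$n_cases, ch$n_controls,
                                 ch$control_variants,
                                 genes = ch$mutation_rates$gene)
  cp <- file.path(dir, "counts.tsv")
  write_gene_counts(counts, cp)
  counts2 <- read_gene_counts(cp)
  expect_equal(counts2$x_dn_PTV, counts$x_dn_PTV)
  expect_identical(attr(counts2, "n_trios"), attr(counts, "n_trios"))
  ep <- file.path(dir, "expr.tsv")
  sim <- simulate_expression(cfg, seed = 6L)
  write_expression_matrix(sim$expr, ep)
  expr2 <- read_expression_matrix(ep)
  expect_equal(expr2, sim$expr, tolerance = 1e-10)
})
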