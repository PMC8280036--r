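test_that("inheritance classification covers the definitional trio cases", {
  cases <- list(
    list("het", "hom_ref", "hom_ref", "de_novo"),
    list("het", "missing", "hom_ref", "unknown"),
    list("het", "hom_ref", "missing", "unknown"),
    list("het", "hom_ref", "het", "inherited_maternal"),
    list("het", "het", "hom_ref", "inherited_paternal"),
    list("het", "het", "het", "inherited_unphased"),
    list("hom_alt", "het", "hom_alt", "inherited_unphased"),
    list("hemi_alt", "hom_ref", "het", "inherited_maternal"),
    list("hemi_alt", "hom_ref", "hom_ref", "de_novo")
  )
  for (cs in cases) {
    expect_identical(classify_inheritance(cs[[1]], cs[[2]], cs[[3]]), cs[[4]])
  }
  expect_error(classify_inheritance("hom_ref", "hom_ref", "hom_ref"),
               "non-carrier proband")
  expect_error(classify_inheritance("missing", "hom_ref", "hom_ref"),
               "non-carrier proband")
})

test_that("functional classification applies the exclusive ReVe > 0.7 rule", {
  expect_identical(classify_function("frameshift"), "PTV")
  expect_identical(
    classify_function(c("stop_gain", "stop_loss", "splicing")),
    rep("PTV", 3))
  expect_identical(classify_function("missense", 0.70), "excluded")
  expect_identical(classify_function("missense", 0.71), "Dmis")
  expect_identical(classify_function("other"), "excluded")
  expect_warning(out <- classify_function("missense", NA_real_),
                 "missing ReVe")
  expect_identical(out, "excluded")
  expect_error(classify_function("missense", 1.2), "\\[0, 1\\]")
})

test_that("frequency filter requires every observed AF at or below the cutoff", {
  expect_true(passes_frequency_filter(0.0005, NA, 0))
  expect_false(passes_frequency_filter(0.002))
  expect_true(passes_frequency_filter(NA, NA, NA))
  expect_true(passes_frequency_filter(0.001))   # inclusive bound
  expect_false(passes_frequency_filter(0.0005, 0.002, 0))
  expect_error(passes_frequency_filter(-0.1), "\\[0, 1\\]")
})

test_that("potential-functional selection composes class and frequency rules", {
  v <- variant_table(
    make_variant(variant_id = "a", effect = "frameshift", reve = NA_real_),
    make_variant(variant_id = "b", effect = "missense", reve = 0.9),
    make_variant(variant_id = "c", effect = "missense", reve = 0.5),
    make_variant(variant_id = "d", effect = "stop_gain", reve = NA_real_,
                 af_gnomad = 0.01))
  out <- select_potential_functional(v)
  expect_identical(out$variant_id, c("a", "b"))
  expect_true(all(out$functional_class %in% c("PTV", "Dmis")))
  # partition: each retained row has exactly one class and one inheritance
  expect_false(any(is.na(out$inheritance)))
  expect_identical(nrow(select_potential_functional(v[0, ])), 0L)
})

test_that("X-linked hemizygous detection keeps maternal-het male transmissions only", {
  base <- make_variant(chrom = "chrX", gt_proband = "hemi_alt",
                       gt_mother = "het", gt_father = "hom_ref",
                       proband_sex = "male", effect = "frameshift",
                       reve = NA_real_)
  base$functional_class <- "PTV"
  dn_hemi <- base; dn_hemi$gt_mother <- "hom_ref"
  autosomal <- base; autosomal$chrom <- "7"
  female <- base; female$proband_sex <- "female"
  expect_identical(nrow(detect_xlinked_hemizygous(base)), 1L)
  expect_identical(nrow(detect_xlinked_hemizygous(dn_hemi)), 0L)
  expect_identical(nrow(detect_xlinked_hemizygous(autosomal)), 0L)
  expect_warning(out <- detect_xlinked_hemizygous(female), "inconsistent")
  expect_identical(nrow(out), 0L)
  # "chrX" and "X" spellings are equivalent
  alt <- base; alt$chrom <- "X"
  expect_identical(nrow(detect_xlinked_hemizygous(alt)), 1L)
})

test_that("gene-count tabulation conserves selected variants and fills panel zeros", {
  v <- variant_table(
    make_variant(variant_id = "1", gene = "GENE_A", family_id = "F1",
                 effect = "frameshift", reve = NA_real_),
    make_variant(variant_id = "2", gene = "GENE_A", family_id = "F2",
                 effect = "frameshift", reve = NA_real_),
    make_variant(variant_id = "3", gene = "GENE_B", effect = "missense",
                 reve = 0.95, gt_father = "het"),
    make_variant(variant_id = "4", gene = "GENE_B", effect = "missense",
                 reve = 0.95, gt_father = "missing", gt_mother = "missing"))
  sel <- select_potential_functional(v)
  counts <- tabulate_gene_counts(sel, n_trios = 10, n_cases = 12,
                                 n_controls = 30,
                                 control_variants = data.frame(
                                   gene = c("GENE_B", "GENE_B"),
                                   functional_class = c("PTV", "Dmis"),
                                   stringsAsFactors = FALSE),
                                 genes = c("GENE_A", "GENE_B", "GENE_C"))
  expect_identical(counts$gene, c("GENE_A", "GENE_B", "GENE_C"))
  expect_identical(counts$x_dn_PTV, c(2L, 0L, 0L))
  # inherited + unknown pool into the case arm
  expect_identical(counts$x_case_Dmis, c(0L, 2L, 0L))
  expect_identical(counts$x_ctrl_PTV, c(0L, 1L, 0L))
  expect_identical(counts$x_ctrl_Dmis, c(0L, 1L, 0L))
  expect_identical(unlist(counts[counts$gene == "GENE_C", -1], use.names = FALSE),
                   rep(0L, 6))
  # count conservation
  expect_identical(sum(counts$x_dn_PTV) + sum(counts$x_dn_Dmis),
                   sum(sel$inheritance == "de_novo"))
  expect_identical(attr(counts, "n_trios"), 10L)
  sel_bad <- sel
  sel_bad$gene[1] <- NA
  expect_warning(tabulate_gene_counts(sel_bad, 10, 12), "without a gene symbol")
})

test_that("multi-DNV gene table filters, sums and orders deterministically", {
  counts <- data.frame(gene = c("B", "A", "C", "D"),
                       x_dn_PTV = c(2L, 1L, 0L, 0L),
                       x_dn_Dmis = c(1L, 2L, 1L, 0L))
  out <- find_multi_dnv_genes(counts)
  expect_identical(out$gene, c("A", "B", "C")[1:2][c(1, 2)])
  expect_identical(out$total, c(3L, 3L))
  expect_identical(out$gene, c("A", "B"))   # tie broken by symbol
  all1 <- find_multi_dnv_genes(counts, min_total_dnv = 1L)
  expect_identical(all1$gene[order(all1$gene)], c("A", "B", "C"))
  expect_identical(nrow(find_multi_dnv_genes(
    data.frame(gene = "A", x_dn_PTV = 0L, x_dn_Dmis = 0L))), 0L)
})

test_that("determinism: identical variant input produces identical count tables", {
  ch <- simulate_cohort(simulation_config(n_genes = 40L, n_trios = 100L),
                        seed = 11L)
  sel <- select_potential_functional(ch$variants)
  c1 <- tabulate_gene_counts(sel, ch$n_trios, ch$n_cases, ch$n_controls,
                             ch$control_variants, genes = ch$mutation_rates$gene)
  c2 <- tabulate_gene_counts(sel, ch$n_trios, ch$n_cases, ch$n_controls,
                             ch$control_variants, genes = ch$mutation_rates$gene)
  expect_identical(c1, c2)
})
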