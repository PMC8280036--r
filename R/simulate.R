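#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. Defaults
#' describe a desk-scale targeted-sequencing study: 200 panel genes, 500
#' trios plus parent-less probands for a 600-proband case arm, 1500
#' controls, 5% planted risk genes with de novo relative risks 20 (PTV)
#' and 4.7 (Dmis) and case-control relative risk 2.3, log-normal per-gene
#' mutation rates centred at 5e-6, and Gamma(0.1, 200) qualifying-variant
#' frequencies. Expression data are generated from latent module factors
#' whose loading/noise ratio sets the expected within-module correlation;
#' PPI edges are dense within modules with confidence scores concentrated
#' above the 0.45 threshold and sparse elsewhere; constraint scores are
#' drawn intolerant (pLI near 1, negative RVIS) for risk genes.
#'
#' @param n_genes,n_trios,n_cases,n_controls cohort sizes.
#' @param risk_fraction planted fraction of risk genes.
#' @param gamma_ptv,gamma_dmis,gamma_cc planted relative risks.
#' @param mu_meanlog,mu_sdlog log-normal parameters of the per-gene PTV
#'   mutation rate; the Dmis rate is `mu_dmis_scale` times the PTV rate.
#' @param mu_dmis_scale multiplier for Dmis mutation rates.
#' @param q_rho,q_nu Gamma parameters of the qualifying-variant frequency.
#' @param singleton_frac fraction of inherited/case variant rows emitted
#'   with missing parental genotypes (parent-less probands).
#' @param n_noise_variants non-qualifying rows (low-ReVe missense, common
#'   variants) added to exercise the filters.
#' @param expr_samples named integer vector of expression sample counts by
#'   stratum (`postnatal_cortical`, `prenatal_cortical`,
#'   `postnatal_noncortical`).
#' @param n_modules,module_size co-expression module structure.
#' @param loading,noise_sd latent-factor loading and noise standard
#'   deviation; expected within-module absolute correlation is
#'   `loading^2 / (loading^2 + noise_sd^2)`.
#' @param ppi_within_prob,ppi_background_prob PPI edge probabilities.
#' @param ppi_within_beta,ppi_background_beta `c(shape1, shape2)` of the
#'   miscore Beta distributions.
#' @param constraint_effect multiplier (in \[0, 1\] upward) of the
#'   intolerance shift of risk genes; 0 removes the signal.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L, n_trios = 500L, n_cases = 600L,
                              n_controls = 1500L,
                              risk_fraction = 0.05,
                              gamma_ptv = 20, gamma_dmis = 4.7, gamma_cc = 2.3,
                              mu_meanlog = log(5e-6), mu_sdlog = 0.8,
                              mu_dmis_scale = 2,
                              q_rho = 0.1, q_nu = 200,
                              singleton_frac = 0.15,
                              n_noise_variants = 50L,
                              expr_samples = c(postnatal_cortical = 60L,
                                               prenatal_cortical = 20L,
                                               postnatal_noncortical = 20L),
                              n_modules = 5L,
                              module_size = min(20L, n_genes %/% n_modules),
                              loading = 3, noise_sd = 1,
                              ppi_within_prob = 0.6,
                              ppi_background_prob = 0.01,
                              ppi_within_beta = c(8, 2),
                              ppi_background_beta = c(2, 8),
                              constraint_effect = 1) {
  stopifnot(n_modules * module_size <= n_genes,
            risk_fraction >= 0, risk_fraction <= 1,
            singleton_frac >= 0, singleton_frac <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

.sim_gene_names <- function(n) sprintf("GENE%04d", seq_len(n))

#' Simulate a trio sequencing cohort
#'
#' Generates an annotated variant table, a control qualifying-variant
#' table, per-gene mutation rates, and planted-truth labels under the
#' generative model the gene-level association stage assumes: de novo
#' counts Poisson with rate 2 * n_trios * mu * gamma (gamma > 1 at risk
#' genes), and case/control counts Poisson around a Gamma-distributed
#' per-gene qualifying-variant frequency, with case rates inflated by the
#' case-control relative risk at risk genes. A configurable fraction of
#' inherited rows comes from parent-less probands (missing parental
#' genotypes, inheritance unresolvable) and non-qualifying noise rows are
#' appended to exercise the filters.
#'
#' @param cfg [simulation_config()].
#' @param seed integer seed (one RNG stream per call).
#' @return list with `variants` (annotated-variant data frame),
#'   `control_variants` (`gene`, `functional_class`), `mutation_rates`
#'   (`gene`, `mu_PTV`, `mu_Dmis`), `truth` (`gene`, `is_risk`, planted
#'   rates and risks), and the cohort sizes.
#' @export
simulate_cohort <- function(cfg = simulation_config(), seed = 1L) {
  with_seed(seed, {
    genes <- .sim_gene_names(cfg$n_genes)
    n_risk <- round(cfg$risk_fraction * cfg$n_genes)
    is_risk <- rep(FALSE, cfg$n_genes)
    if (n_risk > 0) is_risk[sample.int(cfg$n_genes, n_risk)] <- TRUE
    mu_ptv <- rlnorm(cfg$n_genes, cfg$mu_meanlog, cfg$mu_sdlog)
    mu_dmis <- cfg$mu_dmis_scale * rlnorm(cfg$n_genes, cfg$mu_meanlog, cfg$mu_sdlog)
    g_ptv <- ifelse(is_risk, cfg$gamma_ptv, 1)
    g_dmis <- ifelse(is_risk, cfg$gamma_dmis, 1)
    g_cc <- ifelse(is_risk, cfg$gamma_cc, 1)
    q_ptv <- rgamma(cfg$n_genes, shape = cfg$q_rho, rate = cfg$q_nu)
    q_dmis <- rgamma(cfg$n_genes, shape = cfg$q_rho, rate = cfg$q_nu)

    x_dn_ptv <- rpois(cfg$n_genes, 2 * cfg$n_trios * mu_ptv * g_ptv)
    x_dn_dmis <- rpois(cfg$n_genes, 2 * cfg$n_trios * mu_dmis * g_dmis)
    x_case_ptv <- rpois(cfg$n_genes, cfg$n_cases * q_ptv * g_cc)
    x_case_dmis <- rpois(cfg$n_genes, cfg$n_cases * q_dmis * g_cc)
    x_ctrl_ptv <- rpois(cfg$n_genes, cfg$n_controls * q_ptv)
    x_ctrl_dmis <- rpois(cfg$n_genes, cfg$n_controls * q_dmis)

    row_id <- 0L
    mk_rows <- function(gene, n, class, kind) {
      if (n == 0L) return(NULL)
      singleton <- kind != "de_novo" & runif(n) < cfg$singleton_frac
      # inherited rows: transmitting parent chosen at random
      pat <- runif(n) < 0.5
      gt_fa <- ifelse(kind == "de_novo", "hom_ref",
                      ifelse(singleton, "missing", ifelse(pat, "het", "hom_ref")))
      gt_mo <- ifelse(kind == "de_novo", "hom_ref",
                      ifelse(singleton, "missing", ifelse(pat, "hom_ref", "het")))
      ids <- row_id + seq_len(n)
      row_id <<- row_id + n
      data.frame(
        variant_id = sprintf("var%06d", ids),
        family_id = sprintf("FAM%04d", sample.int(cfg$n_trios + 200L, n)),
        chrom = "1", pos = ids * 10L, ref = "A", alt = "T",
        gene = gene,
        effect = if (class == "PTV") sample(.PTV_EFFECTS, n, replace = TRUE)
                 else "missense",
        reve = if (class == "PTV") NA_real_ else runif(n, 0.71, 1),
        af_gnomad = ifelse(runif(n) < 0.5, NA_real_, runif(n, 0, 1e-4)),
        af_exac = NA_real_,
        af_inhouse = 0,
        gt_proband = "het", gt_father = gt_fa, gt_mother = gt_mo,
        proband_sex = sample(c("male", "female"), n, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    rows <- vector("list", 4L * cfg$n_genes)
    for (i in seq_len(cfg$n_genes)) {
      rows[[4L * i - 3L]] <- mk_rows(genes[i], x_dn_ptv[i], "PTV", "de_novo")
      rows[[4L * i - 2L]] <- mk_rows(genes[i], x_dn_dmis[i], "Dmis", "de_novo")
      rows[[4L * i - 1L]] <- mk_rows(genes[i], x_case_ptv[i], "PTV", "case")
      rows[[4L * i]] <- mk_rows(genes[i], x_case_dmis[i], "Dmis", "case")
    }
    variants <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(variants)) variants <- mk_rows(genes[1], 1L, "PTV", "de_novo")[0, ]

    if (cfg$n_noise_variants > 0L) {
      n <- cfg$n_noise_variants
      common <- runif(n) < 0.5
      noise <- data.frame(
        variant_id = sprintf("noise%05d", seq_len(n)),
        family_id = sprintf("FAM%04d", sample.int(cfg$n_trios, n, replace = TRUE)),
        chrom = "1", pos = 1e7 + seq_len(n), ref = "G", alt = "C",
        gene = sample(genes, n, replace = TRUE),
        effect = ifelse(common, "stop_gain", "missense"),
        reve = ifelse(common, NA_real_, runif(n, 0, 0.69)),
        af_gnomad = ifelse(common, runif(n, 0.005, 0.2), NA_real_),
        af_exac = NA_real_, af_inhouse = 0,
        gt_proband = "het", gt_father = "hom_ref", gt_mother = "het",
        proband_sex = sample(c("male", "female"), n, replace = TRUE),
        stringsAsFactors = FALSE)
      variants <- rbind(variants, noise)
    }

    ctrl <- data.frame(
      gene = rep(genes, times = x_ctrl_ptv + x_ctrl_dmis),
      functional_class = unlist(mapply(function(p, d) c(rep("PTV", p), rep("Dmis", d)),
                                       x_ctrl_ptv, x_ctrl_dmis, SIMPLIFY = FALSE),
                                use.names = FALSE),
      stringsAsFactors = FALSE)

    list(variants = variants,
         control_variants = ctrl,
         mutation_rates = data.frame(gene = genes, mu_PTV = mu_ptv,
                                     mu_Dmis = mu_dmis, stringsAsFactors = FALSE),
         truth = data.frame(gene = genes, is_risk = is_risk,
                            gamma_PTV = g_ptv, gamma_Dmis = g_dmis,
                            gamma_cc = g_cc, mu_PTV = mu_ptv, mu_Dmis = mu_dmis,
                            stringsAsFactors = FALSE),
         n_trios = cfg$n_trios, n_cases = cfg$n_cases,
         n_controls = cfg$n_controls)
  })
}

#' Simulate a brain expression matrix with planted co-expression modules
#'
#' Genes in the same module share a latent factor: for module m, gene g,
#' sample s, x = loading * f_m(s) + noise; genes outside modules are pure
#' noise. The expected within-module absolute Pearson correlation is
#' loading^2 / (loading^2 + noise_sd^2). Samples are labelled across
#' postnatal/prenatal and cortical/non-cortical strata so the metadata
#' filter has work to do; the module signal is present in all samples.
#'
#' @param cfg [simulation_config()].
#' @param seed integer seed.
#' @param genes gene names (default generated to match
#'   [simulate_cohort()]).
#' @return list with `expr` (genes x samples matrix), `metadata`
#'   (`sample`, `stage`, `region`, `cortical`), `modules` (`gene`,
#'   `module`; 0 = no module), and `expected_abs_r`.
#' @export
simulate_expression <- function(cfg = simulation_config(), seed = 1L,
                                genes = .sim_gene_names(cfg$n_genes)) {
  with_seed(seed, {
    ns <- cfg$expr_samples
    n_samples <- sum(ns)
    samples <- sprintf("S%03d", seq_len(n_samples))
    stage <- rep(c("postnatal", "prenatal", "postnatal"), times = ns)
    cortical <- rep(c(TRUE, TRUE, FALSE), times = ns)
    region <- ifelse(cortical, "cortex", "cerebellum")
    module <- rep(0L, length(genes))
    module[seq_len(cfg$n_modules * cfg$module_size)] <-
      rep(seq_len(cfg$n_modules), each = cfg$module_size)
    factors <- matrix(rnorm(cfg$n_modules * n_samples), cfg$n_modules)
    expr <- matrix(rnorm(length(genes) * n_samples, sd = cfg$noise_sd),
                   nrow = length(genes), dimnames = list(genes, samples))
    in_mod <- module > 0L
    expr[in_mod, ] <- expr[in_mod, ] + cfg$loading * factors[module[in_mod], ]
    list(expr = expr,
         metadata = data.frame(sample = samples, stage = stage,
                               region = region, cortical = cortical,
                               stringsAsFactors = FALSE),
         modules = data.frame(gene = genes, module = module,
                              stringsAsFactors = FALSE),
         expected_abs_r = cfg$loading^2 / (cfg$loading^2 + cfg$noise_sd^2))
  })
}

#' Simulate a scored protein-interaction edge list
#'
#' Gene pairs within the same co-expression module are connected with high
#' probability and confidence scores drawn from a Beta concentrated above
#' the 0.45 threshold; background pairs are sparse with scores mostly
#' below it.
#'
#' @param cfg [simulation_config()].
#' @param modules module map from [simulate_expression()] (`gene`,
#'   `module`).
#' @param seed integer seed.
#' @return data frame `gene_a`, `gene_b`, `miscore`.
#' @export
simulate_ppi <- function(cfg = simulation_config(),
                         modules = simulate_expression(cfg, seed = seed)$modules,
                         seed = 1L) {
  with_seed(seed + 1L, {
    genes <- modules$gene
    mod <- modules$module
    pairs <- which(upper.tri(matrix(0, length(genes), length(genes))),
                   arr.ind = TRUE)
    same <- mod[pairs[, 1L]] > 0L & mod[pairs[, 1L]] == mod[pairs[, 2L]]
    prob <- ifelse(same, cfg$ppi_within_prob, cfg$ppi_background_prob)
    keep <- runif(nrow(pairs)) < prob
    same <- same[keep]; pairs <- pairs[keep, , drop = FALSE]
    score <- numeric(nrow(pairs))
    score[same] <- rbeta(sum(same), cfg$ppi_within_beta[1], cfg$ppi_within_beta[2])
    score[!same] <- rbeta(sum(!same), cfg$ppi_background_beta[1],
                          cfg$ppi_background_beta[2])
    data.frame(gene_a = genes[pairs[, 1L]], gene_b = genes[pairs[, 2L]],
               miscore = score, stringsAsFactors = FALSE)
  })
}

#' Simulate gene constraint scores
#'
#' Risk genes are drawn from an intolerant score distribution (pLI
#' concentrated near 1, negative RVIS); null genes from a tolerant one.
#' `constraint_effect` scales the intolerance shift (0 = no signal).
#'
#' @param truth truth table from [simulate_cohort()] (`gene`, `is_risk`).
#' @param cfg [simulation_config()].
#' @param seed integer seed.
#' @return data frame `gene`, `pli`, `rvis`.
#' @export
simulate_constraint <- function(truth, cfg = simulation_config(), seed = 1L) {
  with_seed(seed + 2L, {
    n <- nrow(truth)
    eff <- cfg$constraint_effect
    risk <- truth$is_risk
    pli <- rbeta(n, shape1 = ifelse(risk, 1 + 8 * eff, 1),
                 shape2 = ifelse(risk, 3 - 2 * eff, 3))
    rvis <- rnorm(n, mean = ifelse(risk, -2 * eff, 0),
                  sd = ifelse(risk, 1 - 0.3 * eff, 1))
    data.frame(gene = truth$gene, pli = pli, rvis = rvis,
               stringsAsFactors = FALSE)
  })
}
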