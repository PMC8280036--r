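#' Pipeline configuration
#'
#' Collects the thresholds and sizes of the end-to-end analysis. Analysis
#' thresholds default to the study settings: ReVe > 0.7 for deleterious
#' missense, minor-allele frequency <= 0.1%, candidate FDR < 0.1 with a
#' 0.05 reporting stratum, |r| > 0.7 co-expression, interaction confidence
#' >= 0.45, and known-gene network inclusion at >= 2 novel connections.
#' `n_iter` defaults to 10,000 for desk-scale permutation runs; raise it
#' (the study scale is 1,000,000) for publication-grade p-values.
#'
#' @param seed integer master seed for every stochastic stage.
#' @param reve_threshold,max_af,fdr_threshold,fdr_strata,coexpr_threshold,
#'   miscore_threshold,min_novel_connections,percentile_cutoff analysis
#'   thresholds (see the stage functions).
#' @param n_iter permutation iterations.
#' @param sim [simulation_config()] used when no inputs are supplied.
#' @param hyperparams [tada_hyperparams()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            reve_threshold = 0.7, max_af = 0.001,
                            fdr_threshold = 0.1, fdr_strata = c(0.05, 0.1),
                            coexpr_threshold = 0.7,
                            miscore_threshold = 0.45,
                            min_novel_connections = 2L,
                            percentile_cutoff = 50,
                            n_iter = 10000L,
                            sim = simulation_config(),
                            hyperparams = tada_hyperparams()) {
  stopifnot(reve_threshold > 0, reve_threshold < 1,
            max_af >= 0, max_af <= 1,
            fdr_threshold > 0, fdr_threshold < 1,
            coexpr_threshold > 0, coexpr_threshold < 1,
            miscore_threshold >= 0, miscore_threshold <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full prioritization pipeline
#'
#' Executes the analysis end to end: variant filtering and counting,
#' gene-level Bayesian prioritization, known/novel cataloguing,
#' co-expression permutation testing, functional network construction, and
#' constraint-percentile comparison. When `inputs` is `NULL` a complete
#' synthetic workspace is generated from `config$sim` (with a demo
#' evidence table marking a coin-flip half of the planted risk genes as
#' known). All outputs are written as TSV/JSON/GraphML under `out_dir`
#' together with a machine-readable run report carrying the seed and a
#' config hash; a rerun with an identical config and seed is
#' byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param config [pipeline_config()].
#' @param inputs optional named list with elements `variants`,
#'   `control_variants`, `mutation_rates`, `expr`, `metadata`, `ppi`,
#'   `constraint`, `evidence`, `n_trios`, `n_cases`, `n_controls`
#'   (data frames / matrix as produced by the readers); defaults to a
#'   simulated workspace.
#' @return invisible list with every stage result (`counts`, `multi_dnv`,
#'   `tada`, `catalog`, `permutation`, `network`, `novel_degrees`,
#'   `constraint`, `constraint_test`, `report`).
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(), inputs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  if (is.null(inputs)) {
    inputs <- .stage("simulate", {
      cohort <- simulate_cohort(config$sim, seed = seed)
      exprs <- simulate_expression(config$sim, seed = seed + 1L)
      ppi <- simulate_ppi(config$sim, exprs$modules, seed = seed + 2L)
      constraint <- simulate_constraint(cohort$truth, config$sim,
                                        seed = seed + 3L)
      evidence <- with_seed(seed + 4L, {
        risk <- cohort$truth$gene[cohort$truth$is_risk]
        known <- risk[runif(length(risk)) < 0.5]
        data.frame(gene = cohort$truth$gene,
                   publications = ifelse(cohort$truth$gene %in% known,
                                         "cohort_study_1", ""),
                   omim_ndd = FALSE, sfari_category = "none",
                   pubmed_support = FALSE, stringsAsFactors = FALSE)
      })
      c(cohort[c("variants", "control_variants", "mutation_rates",
                 "n_trios", "n_cases", "n_controls")],
        list(expr = exprs$expr, metadata = exprs$metadata, ppi = ppi,
             constraint = constraint, evidence = evidence,
             truth = cohort$truth, modules = exprs$modules))
    })
  }
  for (nm in c("variants", "mutation_rates", "expr", "metadata", "ppi",
               "constraint", "n_trios", "n_cases")) {
    if (is.null(inputs[[nm]])) {
      stop(sprintf("pipeline stage 'inputs' failed: missing input '%s'", nm),
           call. = FALSE)
    }
  }

  selected <- .stage("filter", select_potential_functional(
    inputs$variants, config$reve_threshold, config$max_af))
  xlinked <- .stage("filter", detect_xlinked_hemizygous(selected))
  counts <- .stage("counts", tabulate_gene_counts(
    selected, inputs$n_trios, inputs$n_cases,
    n_controls = if (is.null(inputs$n_controls)) 0L else inputs$n_controls,
    control_variants = inputs$control_variants,
    genes = inputs$mutation_rates$gene))
  multi_dnv <- .stage("counts", find_multi_dnv_genes(counts))

  tada <- .stage("tada", tada_prioritize(
    counts, inputs$mutation_rates, config$hyperparams,
    fdr_threshold = config$fdr_threshold))

  catalog <- .stage("catalog", merge_candidates(
    tada, unique(xlinked$gene), inputs$evidence,
    fdr_strata = config$fdr_strata))
  novel <- catalog$gene[catalog$status == "novel"]
  known <- catalog$gene[catalog$status == "known"]

  coexpr <- .stage("coexpr", {
    postnatal <- select_postnatal_cortical(inputs$expr, inputs$metadata)
    coexpression_edges(postnatal, config$coexpr_threshold)
  })
  permutation <- .stage("coexpr", {
    if (length(novel) && length(known)) {
      coexpression_permutation(coexpr, novel, known,
                               n_iter = config$n_iter, seed = seed + 10L)
    } else NULL
  })

  network <- .stage("network", {
    ppi_graph <- ppi_edges(inputs$ppi, config$miscore_threshold)
    build_functional_network(novel, known, coexpr, ppi_graph,
                             min_novel_connections = config$min_novel_connections)
  })
  novel_degrees <- .stage("network", novel_degree_table(network))

  constraint <- .stage("constraint", percentile_ranks(inputs$constraint))
  constraint_test <- .stage("constraint", {
    cand <- constraint$gene %in% catalog$gene
    if (any(cand) && any(!cand)) {
      list(
        pli = rank_sum_test(constraint$pli_percentile[cand],
                            constraint$pli_percentile[!cand]),
        rvis = rank_sum_test(constraint$rvis_percentile[cand],
                             constraint$rvis_percentile[!cand]),
        top_fraction = top_fraction_count(constraint[cand, , drop = FALSE],
                                          config$percentile_cutoff))
    } else NULL
  })

  # ---- serialize ----
  out <- function(f) file.path(out_dir, f)
  write_gene_counts(counts, out("gene_counts.tsv"))
  .write_tsv(multi_dnv, out("multi_dnv_genes.tsv"))
  .write_tsv(tada, out("tada_results.tsv"))
  .write_tsv(catalog, out("gene_catalog.tsv"))
  if (!is.null(permutation)) {
    jsonlite::write_json(
      list(observed = as.list(permutation$observed),
           p = as.list(permutation$p),
           n_iter = permutation$n_iter, seed = permutation$seed,
           dropped = permutation$dropped),
      out("permutation.json"), auto_unbox = TRUE, digits = NA)
  }
  write_network_graphml(network, out("functional_network.graphml"))
  .write_tsv(novel_degrees, out("novel_degree_table.tsv"))
  .write_tsv(constraint, out("constraint_percentiles.tsv"))
  if (!is.null(constraint_test)) {
    jsonlite::write_json(constraint_test, out("constraint_test.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  cfg_path <- out("config.yaml")
  yaml::write_yaml(.config_serializable(config), cfg_path)
  report <- list(seed = seed,
                 config_md5 = unname(tools::md5sum(cfg_path)),
                 n_selected_variants = nrow(selected),
                 n_xlinked_hemizygous = nrow(xlinked),
                 n_candidates = nrow(catalog),
                 n_novel = length(novel), n_known = length(known),
                 n_network_genes = igraph::vcount(network),
                 outputs = sort(list.files(out_dir)))
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(selected = selected, xlinked = xlinked, counts = counts,
                 multi_dnv = multi_dnv, tada = tada, catalog = catalog,
                 coexpr = coexpr, permutation = permutation,
                 network = network, novel_degrees = novel_degrees,
                 constraint = constraint, constraint_test = constraint_test,
                 report = report, inputs = inputs))
}

.config_serializable <- function(config) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$hyperparams <- lapply(unclass(x$hyperparams), function(v)
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v)
  x
}
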