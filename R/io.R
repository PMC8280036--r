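#' @name ndprio-io
#' @title Tab-separated readers and writers
#' @description All module inputs and outputs are plain TSV with `.` as the
#'   missing-value marker. Readers validate the column contract of the
#'   corresponding module; writers are byte-stable for identical inputs.
NULL

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

.read_tsv <- function(path, required, numeric_cols = character(0),
                      logical_cols = character(0)) {
  df <- read.delim(path, sep = "\t", na.strings = c(".", "NA", ""),
                   stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (cl in intersect(numeric_cols, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in intersect(logical_cols, names(df))) {
    df[[cl]] <- as.logical(df[[cl]]) |
      (tolower(as.character(df[[cl]])) %in% c("true", "t", "1", "yes"))
  }
  df
}

#' Read an annotated variant table
#'
#' One row per variant call per proband; columns `family_id`, `chrom`,
#' `pos`, `ref`, `alt`, `gene`, `effect`, `reve`, `af_gnomad`, `af_exac`,
#' `af_inhouse`, `gt_proband`, `gt_father`, `gt_mother`, `proband_sex`
#' (plus optional `variant_id`, `sample_role`); `.` denotes missing.
#'
#' @param path TSV file.
#' @return data frame.
#' @export
read_variant_table <- function(path) {
  df <- .read_tsv(path,
                  required = c("family_id", "chrom", "pos", "ref", "alt",
                               "gene", "effect", "reve", "af_gnomad",
                               "af_exac", "af_inhouse", "gt_proband",
                               "gt_father", "gt_mother", "proband_sex"),
                  numeric_cols = c("pos", "reve", "af_gnomad", "af_exac",
                                   "af_inhouse"))
  .assert_in(df$effect, .EFFECT_LEVELS, "effect")
  for (cl in c("gt_proband", "gt_father", "gt_mother")) {
    df[[cl]][is.na(df[[cl]])] <- "missing"
    .assert_in(df[[cl]], .GT_LEVELS, cl)
  }
  if (any(!is.na(df$pos) & df$pos < 1)) stop("pos must be >= 1", call. = FALSE)
  if (any(!is.na(df$ref) & !is.na(df$alt) & df$ref == df$alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  df
}

#' Write / read a gene-count table
#'
#' The cohort sizes travel as `# key=value` header comments so the table
#' round-trips losslessly.
#'
#' @param counts gene-count table from [tabulate_gene_counts()].
#' @param path TSV file.
#' @return `write_gene_counts`: the path, invisibly. `read_gene_counts`:
#'   the table with cohort-size attributes restored.
#' @export
write_gene_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("n_trios", "n_cases", "n_controls")) {
    writeLines(sprintf("# %s=%d", key, attr(counts, key)), con)
  }
  write.table(counts, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' @rdname write_gene_counts
#' @export
read_gene_counts <- function(path) {
  header <- grep("^# ", readLines(path, n = 10L), value = TRUE)
  df <- .read_tsv(path,
                  required = c("gene", "x_dn_PTV", "x_dn_Dmis", "x_case_PTV",
                               "x_case_Dmis", "x_ctrl_PTV", "x_ctrl_Dmis"),
                  numeric_cols = c("x_dn_PTV", "x_dn_Dmis", "x_case_PTV",
                                   "x_case_Dmis", "x_ctrl_PTV", "x_ctrl_Dmis"))
  for (line in header) {
    kv <- strsplit(sub("^# ", "", line), "=", fixed = TRUE)[[1]]
    attr(df, kv[1]) <- as.integer(kv[2])
  }
  df
}

#' Read a mutation-rate table (`gene`, `mu_PTV`, `mu_Dmis`)
#' @param path TSV file.
#' @return data frame.
#' @export
read_mutation_rates <- function(path) {
  df <- .read_tsv(path, required = c("gene", "mu_PTV", "mu_Dmis"),
                  numeric_cols = c("mu_PTV", "mu_Dmis"))
  if (any(df$mu_PTV < 0, na.rm = TRUE) || any(df$mu_Dmis < 0, na.rm = TRUE)) {
    stop("mutation rates must be >= 0", call. = FALSE)
  }
  df
}

#' Read an expression matrix (first column gene, remaining columns samples)
#' @param path TSV file.
#' @return numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", na.strings = c(".", "NA"),
                   stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  m
}

#' Write an expression matrix as TSV
#' @param expr genes x samples matrix.
#' @param path TSV file.
#' @return the path, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read expression sample metadata (`sample`, `stage`, `region`,
#' `cortical`)
#' @param path TSV file.
#' @return data frame.
#' @export
read_sample_metadata <- function(path) {
  .read_tsv(path, required = c("sample", "stage", "cortical"),
            logical_cols = "cortical")
}

#' Read a scored interaction edge list (`gene_a`, `gene_b`, `miscore`)
#' @param path TSV file.
#' @return data frame.
#' @export
read_ppi_table <- function(path) {
  .read_tsv(path, required = c("gene_a", "gene_b", "miscore"),
            numeric_cols = "miscore")
}

#' Read a gene constraint table (`gene`, `pli`, `rvis`)
#' @param path TSV file.
#' @return data frame.
#' @export
read_constraint_table <- function(path) {
  .read_tsv(path, required = c("gene", "pli", "rvis"),
            numeric_cols = c("pli", "rvis"))
}

#' Read a known-gene evidence table
#'
#' Columns `gene`, `publications`, `omim_ndd`, `sfari_category`,
#' `pubmed_support`.
#' @param path TSV file.
#' @return data frame.
#' @export
read_evidence_table <- function(path) {
  .read_tsv(path, required = c("gene", "publications", "omim_ndd",
                               "sfari_category", "pubmed_support"),
            logical_cols = c("omim_ndd", "pubmed_support"))
}

#' Read / write a gene-set file (one symbol per line)
#' @param path text file.
#' @param genes character vector.
#' @return `read_gene_set`: character vector. `write_gene_set`: the path,
#'   invisibly.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_gene_set
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Export a functional network as GraphML
#'
#' Vertex attribute `label` (novel/known) and edge attribute `provenance`
#' are preserved.
#' @param network [build_functional_network()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}

#' Reported multi-DNV gene table
#'
#' Observed values from a published targeted-sequencing cohort of 935
#' neurodevelopmental-disorder trios: the 21 genes carrying two or more de
#' novo variants, with per-class de novo counts and genome-wide pLI/RVIS
#' constraint scores and percentiles (missing scores as `NA`). Shipped as
#' a worked example and regression anchor for [find_multi_dnv_genes()] and
#' [top_fraction_count()].
#'
#' @return data frame `gene`, `x_dn_PTV`, `x_dn_Dmis`, `rvis`,
#'   `rvis_percentile`, `pli`, `pli_percentile`.
#' @export
reported_multi_dnv_genes <- function() {
  .read_tsv(system.file("extdata", "reported_multi_dnv_genes.tsv",
                        package = "ndprio", mustWork = TRUE),
            required = c("gene", "x_dn_PTV", "x_dn_Dmis"),
            numeric_cols = c("x_dn_PTV", "x_dn_Dmis", "rvis",
                             "rvis_percentile", "pli", "pli_percentile"))
}

#' Reported novel candidate genes and their combined-analysis FDR values
#'
#' The 16 novel candidate genes prioritized by the gene-level Bayesian
#' analysis of the same cohort combined with public de novo data, with
#' their reported q-values (FDR). Shipped as a worked example for the FDR
#' stratum partition used in candidate cataloguing.
#'
#' @return data frame `gene`, `fdr`.
#' @export
reported_novel_candidates <- function() {
  .read_tsv(system.file("extdata", "reported_novel_candidates.tsv",
                        package = "ndprio", mustWork = TRUE),
            required = c("gene", "fdr"), numeric_cols = "fdr")
}
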