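#' Known-gene evidence classification
#'
#' A gene counts as a *known* candidate when any of three evidence rules
#' fires: it is named a risk gene in at least one of the curated
#' large-scale sequencing publications, it is recorded as an NDD gene in
#' OMIM, or it is a SFARI syndromic / category-1 / category-2 gene.
#'
#' @param evidence data frame with columns `gene`, `publications`
#'   (comma-separated identifiers, `""` or `NA` when none), `omim_ndd`
#'   (logical) and `sfari_category` (`"syndromic"`, `"1"`, `"2"`, `"3"`,
#'   `"other"`, `"none"`).
#' @return character vector, `"known"` or `"not_known"`, one per row.
#' @export
classify_gene_evidence <- function(evidence) {
  pubs <- evidence$publications
  has_pub <- !is.na(pubs) & nzchar(trimws(as.character(pubs))) &
    trimws(as.character(pubs)) != "."
  omim <- !is.na(evidence$omim_ndd) & as.logical(evidence$omim_ndd)
  sfari <- !is.na(evidence$sfari_category) &
    as.character(evidence$sfari_category) %in% c("syndromic", "1", "2")
  ifelse(has_pub | omim | sfari, "known", "not_known")
}

#' Merge TADA candidates with X-linked hemizygous genes into the catalog
#'
#' Forms the final candidate set as the union of TADA candidates (q-value
#' below the FDR threshold) and genes carrying inherited X-linked
#' hemizygous variants, deduplicated. Each candidate is labelled `known`
#' when an evidence rule fires ([classify_gene_evidence()]) or manual
#' PubMed support is flagged; otherwise `novel`. All sources a gene
#' qualifies under are recorded (`sources`, semicolon-joined); the
#' first-listed one is reported as `source`, with the FDR strata taking
#' precedence over the X-linked route.
#'
#' @param tada TADA result table from [tada_prioritize()] (columns `gene`,
#'   `qvalue`, `candidate`).
#' @param xlinked_genes character vector of genes with inherited X-linked
#'   hemizygous variants.
#' @param evidence evidence data frame (see [classify_gene_evidence()]);
#'   column `pubmed_support` (logical) marks manual literature support.
#'   Genes absent from the table are treated as evidence-free.
#' @param fdr_strata two increasing cutoffs splitting the TADA candidates
#'   into reporting strata (default `c(0.05, 0.1)`).
#' @return data frame `gene`, `status`, `source`, `sources`, `qvalue`,
#'   one row per candidate, sorted by gene symbol.
#' @export
merge_candidates <- function(tada, xlinked_genes = character(0),
                             evidence = NULL, fdr_strata = c(0.05, 0.1)) {
  stopifnot(length(fdr_strata) == 2L, fdr_strata[1] < fdr_strata[2])
  tada_cand <- tada[!is.na(tada$candidate) & tada$candidate, , drop = FALSE]
  genes <- sort(unique(c(tada_cand$gene, xlinked_genes)))
  if (!length(genes)) {
    return(data.frame(gene = character(0), status = character(0),
                      source = character(0), sources = character(0),
                      qvalue = numeric(0), stringsAsFactors = FALSE))
  }
  q <- tada_cand$qvalue[match(genes, tada_cand$gene)]
  src_list <- lapply(seq_along(genes), function(i) {
    s <- character(0)
    if (!is.na(q[i]) && q[i] < fdr_strata[1]) s <- c(s, "tada_fdr_lt_0.05")
    if (!is.na(q[i]) && q[i] >= fdr_strata[1] && q[i] < fdr_strata[2]) {
      s <- c(s, "tada_fdr_0.05_to_0.1")
    }
    if (genes[i] %in% xlinked_genes) s <- c(s, "xlinked_hemizygous")
    s
  })

  if (is.null(evidence) || nrow(evidence) == 0L) {
    known <- rep(FALSE, length(genes))
    pubmed <- rep(FALSE, length(genes))
  } else {
    idx <- match(genes, evidence$gene)
    ev_status <- classify_gene_evidence(evidence)
    known <- !is.na(idx) & ev_status[idx] == "known"
    pm <- if ("pubmed_support" %in% names(evidence)) evidence$pubmed_support else
      rep(FALSE, nrow(evidence))
    pubmed <- !is.na(idx) & !is.na(pm[idx]) & as.logical(pm[idx])
  }
  status <- ifelse(known | pubmed, "known", "novel")
  data.frame(gene = genes,
             status = status,
             source = vapply(src_list, `[`, character(1), 1L),
             sources = vapply(src_list, paste, character(1), collapse = ";"),
             qvalue = q,
             stringsAsFactors = FALSE)
}
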