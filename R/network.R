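#' Protein-protein interaction graph from scored records
#'
#' Builds the PPI graph from (gene_a, gene_b, miscore) records, keeping
#' pairs whose interaction confidence score reaches the threshold
#' (inclusive). Self-interactions are dropped; duplicate pairs (in either
#' orientation) are collapsed keeping the maximum score.
#'
#' @param records data frame with columns `gene_a`, `gene_b`, `miscore`.
#' @param threshold minimum confidence score (default 0.45, inclusive).
#' @return undirected [igraph::graph] with edge attribute `miscore`.
#' @export
ppi_edges <- function(records, threshold = 0.45) {
  bad <- is.na(records$gene_a) | is.na(records$gene_b) |
    !nzchar(records$gene_a) | !nzchar(records$gene_b) |
    is.na(records$miscore) | records$miscore < 0 | records$miscore > 1
  if (any(bad)) {
    stop(sprintf("%d malformed PPI record(s): missing gene or score outside [0, 1]",
                 sum(bad)), call. = FALSE)
  }
  a <- pmin(records$gene_a, records$gene_b)
  b <- pmax(records$gene_a, records$gene_b)
  keep <- a != b
  key <- paste(a[keep], b[keep], sep = "\r")
  score <- tapply(records$miscore[keep], key, max)
  pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  sel <- as.numeric(score) >= threshold
  genes <- sort(unique(c(pairs[sel, 1L], pairs[sel, 2L])))
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (any(sel)) {
    g <- igraph::add_edges(g, rbind(match(pairs[sel, 1L], genes),
                                    match(pairs[sel, 2L], genes)),
                           attr = list(miscore = as.numeric(score)[sel]))
  }
  g
}

# edge data frame (a, b, provenance) for edges of g among `genes`,
# pair-normalized so a < b
.edges_among <- function(g, genes, provenance) {
  if (is.null(g)) return(NULL)
  keep <- intersect(igraph::V(g)$name, genes)
  sub <- igraph::induced_subgraph(g, keep)
  el <- igraph::as_edgelist(sub)
  if (!nrow(el)) return(NULL)
  data.frame(a = pmin(el[, 1L], el[, 2L]), b = pmax(el[, 1L], el[, 2L]),
             provenance = provenance, stringsAsFactors = FALSE)
}

#' Seed-gene functional network
#'
#' Builds the functional network seeded by novel candidate genes from the
#' union of co-expression and PPI evidence. Known candidate genes enter
#' only when directly connected to at least two novel genes in the
#' evidence graph; novel genes enter when they have at least one evidence
#' edge to another novel gene or to an included known gene. Network edges
#' are all evidence edges among included nodes (optionally restricted to
#' edges incident to a novel gene); each edge carries its provenance
#' (`"coexpr"`, `"ppi"`, or `"both"`). Nodes left without any network edge
#' are dropped, so every retained novel gene is connected.
#'
#' @param novel,known disjoint character vectors of gene symbols.
#' @param coexpr co-expression graph ([coexpression_edges()]), or NULL.
#' @param ppi PPI graph ([ppi_edges()]), or NULL.
#' @param min_novel_connections known-gene inclusion rule (default 2).
#' @param include_known_known keep known-known edges among included nodes
#'   (default TRUE); when FALSE only edges incident to a novel gene are
#'   retained.
#' @return undirected [igraph::graph] with vertex attribute `label`
#'   (`"novel"`/`"known"`) and edge attribute `provenance`; vertices and
#'   edges in deterministic (alphabetical) order.
#' @export
build_functional_network <- function(novel, known, coexpr = NULL, ppi = NULL,
                                     min_novel_connections = 2L,
                                     include_known_known = TRUE) {
  if (length(intersect(novel, known))) {
    stop("novel and known gene sets must be disjoint", call. = FALSE)
  }
  cand <- c(novel, known)
  ev <- rbind(.edges_among(coexpr, cand, "coexpr"),
              .edges_among(ppi, cand, "ppi"))
  empty <- function() {
    igraph::make_empty_graph(n = 0, directed = FALSE)
  }
  if (is.null(ev) || !nrow(ev)) return(empty())
  key <- paste(ev$a, ev$b, sep = "\r")
  prov <- tapply(ev$provenance, key, function(p) {
    if (length(unique(p)) > 1L) "both" else p[[1L]]
  })
  pairs <- do.call(rbind, strsplit(names(prov), "\r", fixed = TRUE))
  a <- pairs[, 1L]; b <- pairs[, 2L]

  # known genes need >= min_novel_connections distinct novel evidence-neighbors
  novel_nbr_of <- function(g) {
    unique(c(b[a == g & b %in% novel], a[b == g & a %in% novel]))
  }
  known_in <- known[vapply(known, function(g)
    length(novel_nbr_of(g)) >= min_novel_connections, logical(1))]
  # novel genes need >= 1 evidence edge to another novel gene or included known
  allowed <- c(novel, known_in)
  novel_in <- novel[vapply(novel, function(g) {
    nb <- c(b[a == g], a[b == g])
    any(nb %in% setdiff(allowed, g))
  }, logical(1))]

  nodes <- sort(c(novel_in, known_in))
  keep_e <- a %in% nodes & b %in% nodes
  if (!include_known_known) keep_e <- keep_e & (a %in% novel_in | b %in% novel_in)
  a <- a[keep_e]; b <- b[keep_e]; prov <- as.character(prov)[keep_e]
  # drop isolated nodes (e.g. novel genes whose only neighbors were excluded)
  nodes <- sort(intersect(nodes, c(a, b)))
  keep_e <- a %in% nodes & b %in% nodes
  a <- a[keep_e]; b <- b[keep_e]; prov <- prov[keep_e]
  if (!length(nodes)) return(empty())
  ord <- order(a, b)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  g <- igraph::set_vertex_attr(g, "label", value = ifelse(nodes %in% novel,
                                                          "novel", "known"))
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(match(a[ord], nodes), match(b[ord], nodes)),
                           attr = list(provenance = prov[ord]))
  }
  g
}

#' Known-neighbor counts of novel network genes
#'
#' Counts, for every novel gene retained in the functional network, how
#' many known candidate genes it is directly connected to, sorted by count
#' (descending) then gene symbol.
#'
#' @param network functional network from [build_functional_network()].
#' @return data frame `gene`, `n_known_neighbors`.
#' @export
novel_degree_table <- function(network) {
  vs <- igraph::V(network)
  if (!length(vs)) {
    return(data.frame(gene = character(0), n_known_neighbors = integer(0),
                      stringsAsFactors = FALSE))
  }
  labels <- igraph::vertex_attr(network, "label")
  novel <- vs$name[labels == "novel"]
  cnt <- vapply(novel, function(g) {
    nb <- igraph::neighbors(network, g)$name
    sum(labels[match(nb, vs$name)] == "known")
  }, integer(1))
  out <- data.frame(gene = novel, n_known_neighbors = unname(cnt),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_known_neighbors, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-set over-representation (hypergeometric test)
#'
#' One-sided upper-tail hypergeometric (Fisher's exact) test of overlap
#' between a gene set of interest and an annotated set within a common
#' background. The odds ratio is computed from the 2x2 table, with the
#' Haldane correction (0.5 added to every cell) when any cell is zero.
#'
#' @param genes,annotated_set character vectors, both subsets of
#'   `background`.
#' @param background character vector defining the gene universe.
#' @param name label for the annotated set (default
#'   `deparse(substitute(annotated_set))`-free `"set"`).
#' @return data frame `set`, `overlap`, `n_genes`, `n_annotated`,
#'   `n_background`, `odds_ratio`, `p`.
#' @export
overrepresentation <- function(genes, annotated_set, background,
                               name = "set") {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  genes <- unique(genes)
  annotated_set <- unique(annotated_set)
  if (!all(genes %in% background) || !all(annotated_set %in% background)) {
    stop("gene sets must be subsets of the background", call. = FALSE)
  }
  N <- length(background)
  K <- length(annotated_set)
  n <- length(genes)
  k <- length(intersect(genes, annotated_set))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tab <- c(k, n - k, K - k, N - K - n + k)
  if (any(tab == 0)) tab <- tab + 0.5
  or <- (tab[1] * tab[4]) / (tab[2] * tab[3])
  data.frame(set = name, overlap = k, n_genes = n, n_annotated = K,
             n_background = N, odds_ratio = or, p = p,
             stringsAsFactors = FALSE)
}
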