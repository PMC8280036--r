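#' Select postnatal cortical expression samples
#'
#' Restricts an expression matrix to the samples used for brain
#' co-expression: postnatal developmental stage and cortical region.
#' Prenatal (fetal) samples and non-cortical regions are removed; the gene
#' set is unchanged. Idempotent on an already-filtered matrix.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param metadata data frame with columns `sample`, `stage`
#'   (`"prenatal"`/`"postnatal"`), `cortical` (logical); every column of
#'   `expr` must be described.
#' @return the column-subset matrix.
#' @export
select_postnatal_cortical <- function(expr, metadata) {
  idx <- match(colnames(expr), metadata$sample)
  if (any(is.na(idx))) {
    stop("metadata missing for sample(s): ",
         paste(colnames(expr)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  keep <- metadata$stage[idx] == "postnatal" &
    as.logical(metadata$cortical[idx])
  out <- expr[, keep, drop = FALSE]
  if (ncol(out) < 3L) {
    stop("insufficient samples for correlation: need >= 3 postnatal cortical samples, have ",
         ncol(out), call. = FALSE)
  }
  out
}

#' Brain co-expression graph
#'
#' Computes all pairwise Pearson correlations between gene expression
#' profiles and connects gene pairs with `|r|` strictly above the
#' threshold. Genes with zero variance across samples have undefined
#' correlations and participate in no edges (reported via a message).
#' Every gene of the matrix is a vertex, so the graph also defines the
#' background gene universe for the permutation test.
#'
#' @param expr numeric matrix, genes in rows, at least 3 samples.
#' @param threshold absolute-correlation cutoff in (0, 1), default 0.7
#'   (exclusive).
#' @return undirected [igraph::graph] with edge attribute `r`.
#' @export
coexpression_edges <- function(expr, threshold = 0.7) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3L, threshold > 0, threshold < 1)
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  }
  sds <- apply(expr, 1L, function(x) stats::sd(x))
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    message(sum(flat), " zero-variance gene(s) excluded from co-expression edges")
  }
  r <- suppressWarnings(cor(t(expr), method = "pearson"))
  r[is.na(r)] <- 0
  hit <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(expr), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(expr))
  if (nrow(hit)) {
    g <- igraph::add_edges(g, rbind(hit[, 1L], hit[, 2L]),
                           attr = list(r = r[hit]))
  }
  g
}

#' Permutation test of novel-to-known co-expression connectivity
#'
#' Tests whether a set of novel candidate genes is more connected to the
#' known candidate genes in a co-expression graph than random gene sets of
#' the same size. Three statistics are computed on the observed sets and on
#' each null draw: (a) the number of novel genes with at least one
#' co-expression edge to a known gene, (b) the number of known genes with
#' at least one edge to a novel gene, and (c) the total number of
#' novel-known edges. All three share the same null draws; the per-statistic
#' p-value uses the add-one rule p = (#\{null >= observed\} + 1) /
#' (n_iter + 1), so p is never exactly 0.
#'
#' Genes absent from the graph are dropped from the sets before testing and
#' reported in the result. The null redraws the novel set uniformly without
#' replacement from `background` minus the known set.
#'
#' @param graph co-expression graph from [coexpression_edges()].
#' @param novel,known disjoint character vectors of gene symbols.
#' @param background character vector of candidate replacement genes;
#'   default all graph genes not in `known`.
#' @param n_iter number of null draws (default 1e6).
#' @param seed integer seed for the single RNG stream used by the draws.
#' @return object of class `permutation_result`: list with `observed`
#'   (named vector of the three statistics), `p` (named vector of
#'   p-values), `n_iter`, `seed`, and `dropped` (genes absent from the
#'   graph).
#' @export
coexpression_permutation <- function(graph, novel, known, background = NULL,
                                     n_iter = 1e6, seed = NULL) {
  if (length(intersect(novel, known))) {
    stop("novel and known gene sets must be disjoint", call. = FALSE)
  }
  vs <- igraph::V(graph)$name
  dropped <- setdiff(union(novel, known), vs)
  novel_g <- intersect(novel, vs)
  known_g <- intersect(known, vs)
  if (is.null(background)) background <- setdiff(vs, known_g)
  background <- setdiff(intersect(background, vs), known_g)
  if (!all(novel_g %in% background)) {
    stop("novel genes must be contained in the background after restriction to graph genes",
         call. = FALSE)
  }
  if (length(background) < length(novel_g)) {
    stop("background smaller than the novel set", call. = FALSE)
  }
  adj <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  kn_idx <- match(known_g, vs)
  bg_idx <- match(background, vs)
  # for each background gene: which known genes it touches
  sub <- adj[kn_idx, bg_idx, drop = FALSE]
  nbrs <- lapply(seq_along(bg_idx), function(j) which(sub[, j] != 0))
  kdeg <- lengths(nbrs)

  stat3 <- function(sel) {
    hit <- unlist(nbrs[sel], use.names = FALSE)
    c(novel_connected = sum(kdeg[sel] > 0L),
      known_connected = length(unique(hit)),
      connections = length(hit))
  }
  obs_sel <- match(novel_g, background)
  observed <- stat3(obs_sel)

  nb <- length(background)
  k <- length(novel_g)
  ge <- c(0L, 0L, 0L)
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      ge <- ge + (stat3(sample.int(nb, k)) >= observed)
    }
  })
  p <- (ge + 1) / (n_iter + 1)
  names(p) <- names(observed)
  structure(list(observed = observed, p = p, n_iter = as.integer(n_iter),
                 seed = seed, dropped = dropped),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Co-expression permutation test (", x$n_iter, " iterations)\n", sep = "")
  for (nm in names(x$observed)) {
    cat(sprintf("  %-16s observed = %d, p = %.3g\n", nm,
                x$observed[[nm]], x$p[[nm]]))
  }
  if (length(x$dropped)) {
    cat("  dropped (not in expression matrix):",
        paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}
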