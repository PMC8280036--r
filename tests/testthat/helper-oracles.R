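# Independent numerical oracles and small fixture builders used across the
# test files. Oracles deliberately take a different computational route than
# the package code they check.

# de novo Bayes factor by 1-D quadrature of the Gamma-mixed Poisson marginal,
# integrating over the prior via its inverse CDF (exact prior weight)
oracle_dn_bf <- function(x, n_trios, mu, gamma_bar, beta) {
  lambda <- 2 * n_trios * mu
  alpha <- gamma_bar * beta
  num <- integrate(function(u) dpois(x, lambda * qgamma(u, alpha, beta)),
                   0, 1, rel.tol = 1e-12, abs.tol = 0)$value
  num / dpois(x, lambda)
}

# case-control Bayes factor by nested 2-D quadrature over (q, gamma), both
# via inverse-CDF substitution; the package integrates q analytically instead
oracle_cc_bf <- function(x_case, x_ctrl, n_case, n_ctrl, gamma_bar, beta,
                         rho, nu) {
  marg_given_gamma <- function(g) {
    vapply(g, function(gg) {
      integrate(function(u) {
        q <- qgamma(u, rho, nu)
        dpois(x_ctrl, n_ctrl * q) * dpois(x_case, n_case * q * gg)
      }, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value
    }, numeric(1))
  }
  num <- integrate(function(u) marg_given_gamma(qgamma(u, gamma_bar * beta, beta)),
                   0, 1, rel.tol = 1e-9, abs.tol = 0)$value
  num / marg_given_gamma(1)
}

# hypergeometric upper-tail P(X >= k) by direct enumeration of the pmf
oracle_hyper_tail <- function(k, N, K, n) {
  kk <- max(0, k):min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# one annotated-variant row with overridable fields
make_variant <- function(...) {
  row <- list(variant_id = "v1", family_id = "FAM1", chrom = "1", pos = 100L,
              ref = "A", alt = "T", gene = "GENE_A", effect = "missense",
              reve = 0.9, af_gnomad = NA_real_, af_exac = NA_real_,
              af_inhouse = NA_real_, gt_proband = "het",
              gt_father = "hom_ref", gt_mother = "hom_ref",
              proband_sex = "male")
  over <- list(...)
  row[names(over)] <- over
  as.data.frame(row, stringsAsFactors = FALSE)
}

variant_table <- function(...) do.call(rbind, list(...))

# tiny co-expression graph from explicit edges over a vertex set
graph_from_pairs <- function(vertices, pairs) {
  g <- igraph::make_empty_graph(n = length(vertices), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vertices)
  if (length(pairs)) {
    idx <- vapply(pairs, function(p) match(p, vertices), integer(2))
    g <- igraph::add_edges(g, as.vector(idx))
  }
  g
}
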