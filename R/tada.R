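#' TADA hyperparameters
#'
#' Constructs the hyperparameter block for the gene-level Bayesian
#' association model. Each per-class entry is a named vector over the two
#' variant classes `PTV` and `Dmis`; scalars are recycled to both classes.
#'
#' Under the alternative, a risk gene's de novo relative risk gamma follows
#' Gamma(gamma_bar * beta, beta), so `gamma_bar` is the prior mean relative
#' risk and `beta` controls its spread. The case-control arm places
#' Gamma(rho, nu) on the per-gene qualifying-variant frequency q and an
#' analogous Gamma prior on its relative risk. `pi` is the prior fraction
#' of risk genes.
#'
#' Defaults follow magnitudes conventional in the TADA literature: strong
#' mean relative risk for de novo PTVs (20), moderate for Dmis (4.7), a
#' modest case-control risk (2.3), and a sparse prior q with mean
#' rho/nu = 5e-4 per person.
#'
#' @param gamma_bar_dn,beta_dn de novo prior mean relative risk and rate.
#' @param gamma_bar_cc,beta_cc case-control analogues.
#' @param rho,nu Gamma prior shape/rate for the qualifying-variant
#'   frequency q.
#' @param pi prior probability that a gene is a risk gene, in (0, 1).
#' @return list of class `tada_hyperparams`.
#' @export
tada_hyperparams <- function(gamma_bar_dn = c(PTV = 20, Dmis = 4.7),
                             beta_dn = c(PTV = 1, Dmis = 1),
                             gamma_bar_cc = c(PTV = 2.3, Dmis = 2.3),
                             beta_cc = c(PTV = 4, Dmis = 4),
                             rho = c(PTV = 0.1, Dmis = 0.1),
                             nu = c(PTV = 200, Dmis = 200),
                             pi = 0.05) {
  expand <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x))) x <- c(PTV = unname(x), Dmis = unname(x))
    if (!all(c("PTV", "Dmis") %in% names(x))) {
      stop(sprintf("%s must be named over classes PTV and Dmis", nm), call. = FALSE)
    }
    x <- x[c("PTV", "Dmis")]
    if (any(!is.finite(x) | x <= 0)) stop(sprintf("%s must be positive", nm), call. = FALSE)
    x
  }
  stopifnot(is.numeric(pi), length(pi) == 1L, pi > 0, pi < 1)
  structure(list(
    gamma_bar_dn = expand(gamma_bar_dn, "gamma_bar_dn"),
    beta_dn = expand(beta_dn, "beta_dn"),
    gamma_bar_cc = expand(gamma_bar_cc, "gamma_bar_cc"),
    beta_cc = expand(beta_cc, "beta_cc"),
    rho = expand(rho, "rho"),
    nu = expand(nu, "nu"),
    pi = pi
  ), class = "tada_hyperparams")
}

#' De novo Bayes factor
#'
#' Bayes factor contrasting a Gamma-mixed Poisson model of de novo counts
#' (relative risk gamma ~ Gamma(gamma_bar*beta, beta)) against the null
#' Poisson with rate lambda = 2 * n_trios * mu. With alpha =
#' gamma_bar * beta the marginal ratio has the closed form
#'
#'   BF = exp(lambda) * beta^alpha * Gamma(x + alpha) /
#'        (Gamma(alpha) * (lambda + beta)^(x + alpha))
#'
#' evaluated in log space. When mu = 0 the BF is 1 for x = 0 and an error
#' for x > 0 (a count impossible under the null).
#'
#' @param x non-negative integer de novo count(s).
#' @param n_trios number of trios.
#' @param mu per-gene per-chromosome de novo mutation rate(s).
#' @param gamma_bar prior mean relative risk (> 0).
#' @param beta prior rate (> 0).
#' @param log return the log Bayes factor.
#' @return numeric vector of (log) Bayes factors.
#' @export
dn_bayes_factor <- function(x, n_trios, mu, gamma_bar, beta, log = FALSE) {
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("de novo counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(all(mu >= 0), n_trios > 0, gamma_bar > 0, beta > 0)
  if (any(mu == 0 & x > 0)) {
    stop("impossible count under null: x > 0 with mu = 0", call. = FALSE)
  }
  lambda <- 2 * n_trios * mu
  alpha <- gamma_bar * beta
  lbf <- lambda + alpha * base::log(beta) + lgamma(x + alpha) -
    lgamma(alpha) - (x + alpha) * base::log(lambda + beta)
  lbf[mu == 0] <- 0
  if (log) lbf else exp(lbf)
}

# log joint of (x_case, x_ctrl) given relative risk g, with the
# qualifying-variant frequency q integrated out analytically
# (Gamma-Poisson conjugacy); constant terms independent of g are dropped
.cc_log_marginal_given_gamma <- function(g, x_case, x_ctrl, n_case, n_ctrl,
                                         rho, nu) {
  x_case * base::log(g) -
    (x_case + x_ctrl + rho) * base::log(n_ctrl + n_case * g + nu)
}

#' Case-control Bayes factor
#'
#' Bayes factor for inherited/case-control qualifying-variant counts under
#' the model x_ctrl ~ Poisson(n_ctrl * q), x_case ~ Poisson(n_case * q *
#' gamma), q ~ Gamma(rho, nu); under the alternative gamma ~
#' Gamma(gamma_bar * beta, beta), under the null gamma = 1. q is
#' integrated analytically, gamma by deterministic quadrature on
#' (0, gamma_bar + 10 * sqrt(gamma_bar / beta)).
#'
#' @param x_case,x_ctrl non-negative integer counts (vectors allowed).
#' @param n_case,n_ctrl cohort sizes (> 0).
#' @param gamma_bar,beta prior mean relative risk and rate under the
#'   alternative.
#' @param rho,nu Gamma prior on the qualifying-variant frequency q.
#' @param log return the log Bayes factor.
#' @return numeric vector of (log) Bayes factors.
#' @export
cc_bayes_factor <- function(x_case, x_ctrl, n_case, n_ctrl,
                            gamma_bar, beta, rho, nu, log = FALSE) {
  if (any(c(x_case, x_ctrl) < 0) || any(c(x_case, x_ctrl) != round(c(x_case, x_ctrl)))) {
    stop("case/control counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(n_case > 0, n_ctrl > 0, gamma_bar > 0, beta > 0, rho > 0, nu > 0)
  n <- max(length(x_case), length(x_ctrl))
  x_case <- rep_len(x_case, n)
  x_ctrl <- rep_len(x_ctrl, n)
  shape <- gamma_bar * beta
  upper <- gamma_bar + 10 * sqrt(gamma_bar / beta)
  vapply(seq_len(n), function(i) {
    l0 <- .cc_log_marginal_given_gamma(1, x_case[i], x_ctrl[i], n_case, n_ctrl,
                                       rho, nu)
    f <- function(g) {
      exp(.cc_log_marginal_given_gamma(g, x_case[i], x_ctrl[i], n_case, n_ctrl,
                                       rho, nu) - l0) *
        dgamma(g, shape = shape, rate = beta)
    }
    val <- tryCatch(
      integrate(f, lower = 0, upper = upper, abs.tol = 1e-10,
                rel.tol = 1e-10, subdivisions = 400L),
      error = function(e) stop(sprintf(
        "case-control Bayes factor quadrature failed (x_case=%d, x_ctrl=%d): %s",
        x_case[i], x_ctrl[i], conditionMessage(e)), call. = FALSE))
    # renormalize for the truncated prior mass (upper tail is negligible by
    # construction but kept exact)
    bf <- val$value / pgamma(upper, shape = shape, rate = beta)
    if (log) base::log(bf) else bf
  }, numeric(1))
}

#' Combine per-class Bayes factors
#'
#' Total evidence for a gene is the product of its per-class de novo and
#' case-control Bayes factors; absent arms (NA) contribute a factor of 1.
#' Computed in log space.
#'
#' @param ... numeric vectors of Bayes factors (recycled to a common
#'   length); `NA` entries mean "no evidence for this arm".
#' @return numeric vector of combined Bayes factors.
#' @export
combine_evidence <- function(...) {
  arms <- list(...)
  if (!length(arms)) return(numeric(0))
  n <- max(vapply(arms, length, integer(1)))
  lbf <- rep(0, n)
  for (a in arms) {
    a <- rep_len(a, n)
    if (any(!is.na(a) & a < 0)) stop("Bayes factors must be >= 0", call. = FALSE)
    la <- base::log(a)
    la[is.na(la)] <- 0
    lbf <- lbf + la
  }
  exp(lbf)
}

#' Posterior probabilities and Bayesian q-values
#'
#' Converts combined Bayes factors to posterior probabilities of
#' association, pp = pi*BF / (pi*BF + 1 - pi), and to Bayesian FDR
#' q-values: genes are ranked by decreasing BF (ties broken by gene
#' symbol), the q-value at rank k is the running mean of (1 - pp) over the
#' top k genes, made monotone non-decreasing down the ranking by cumulative
#' maximum.
#'
#' @param bf numeric vector of combined Bayes factors.
#' @param pi prior risk-gene fraction in (0, 1).
#' @param genes optional gene symbols used for deterministic tie-breaking
#'   and output naming.
#' @return data frame `gene`, `bf`, `pp`, `qvalue` in the input order.
#' @export
bayesian_qvalues <- function(bf, pi, genes = NULL) {
  stopifnot(pi > 0, pi < 1, all(bf >= 0 | is.infinite(bf)))
  n <- length(bf)
  if (is.null(genes)) genes <- sprintf("gene_%04d", seq_len(n))
  pp <- ifelse(is.infinite(bf), 1, pi * bf / (pi * bf + 1 - pi))
  ord <- order(-bf, genes)
  q_sorted <- cummax(cumsum(1 - pp[ord]) / seq_len(n))
  qvalue <- numeric(n)
  qvalue[ord] <- q_sorted
  data.frame(gene = genes, bf = bf, pp = pp, qvalue = qvalue,
             stringsAsFactors = FALSE)
}

#' Gene-level Bayesian prioritization
#'
#' Runs the full TADA-style analysis on a gene-count table: per-class de
#' novo and (when a control cohort is present) case-control Bayes factors,
#' combined evidence, posterior probabilities, Bayesian q-values, and the
#' candidate call at an FDR threshold.
#'
#' @param counts gene-count table from [tabulate_gene_counts()] (or with
#'   the same columns plus `n_trios`/`n_cases`/`n_controls` attributes or
#'   arguments).
#' @param mutation_rates data frame `gene`, `mu_PTV`, `mu_Dmis`; every
#'   counted gene must be present.
#' @param params [tada_hyperparams()] block.
#' @param fdr_threshold candidate call threshold on the q-value
#'   (default 0.1).
#' @param n_trios,n_cases,n_controls cohort sizes; default to the
#'   attributes carried by `counts`.
#' @return data frame with per-class Bayes factors (`bf_dn_PTV`,
#'   `bf_dn_Dmis`, `bf_cc_PTV`, `bf_cc_Dmis`), `bf_total`, `pp`, `qvalue`
#'   and `candidate`, ordered by q-value then gene symbol.
#' @export
tada_prioritize <- function(counts, mutation_rates,
                            params = tada_hyperparams(),
                            fdr_threshold = 0.1,
                            n_trios = attr(counts, "n_trios"),
                            n_cases = attr(counts, "n_cases"),
                            n_controls = attr(counts, "n_controls")) {
  if (is.null(n_trios)) stop("n_trios must be supplied", call. = FALSE)
  if (is.null(n_controls)) n_controls <- 0L
  missing_mu <- setdiff(counts$gene, mutation_rates$gene)
  if (length(missing_mu)) {
    stop("genes missing from the mutation-rate table: ",
         paste(missing_mu, collapse = ", "), call. = FALSE)
  }
  mu <- mutation_rates[match(counts$gene, mutation_rates$gene), , drop = FALSE]

  use_cc <- !is.null(n_cases) && n_controls > 0
  per_class <- function(cls) {
    bf_dn <- dn_bayes_factor(counts[[paste0("x_dn_", cls)]], n_trios,
                             mu[[paste0("mu_", cls)]],
                             params$gamma_bar_dn[[cls]], params$beta_dn[[cls]])
    bf_cc <- if (use_cc) {
      cc_bayes_factor(counts[[paste0("x_case_", cls)]],
                      counts[[paste0("x_ctrl_", cls)]],
                      n_cases, n_controls,
                      params$gamma_bar_cc[[cls]], params$beta_cc[[cls]],
                      params$rho[[cls]], params$nu[[cls]])
    } else rep(NA_real_, nrow(counts))
    list(dn = bf_dn, cc = bf_cc)
  }
  ptv <- per_class("PTV")
  dmis <- per_class("Dmis")
  bf_total <- combine_evidence(ptv$dn, ptv$cc, dmis$dn, dmis$cc)
  pq <- bayesian_qvalues(bf_total, params$pi, counts$gene)
  out <- data.frame(gene = counts$gene,
                    bf_dn_PTV = ptv$dn, bf_dn_Dmis = dmis$dn,
                    bf_cc_PTV = ptv$cc, bf_cc_Dmis = dmis$cc,
                    bf_total = bf_total, pp = pq$pp, qvalue = pq$qvalue,
                    candidate = pq$qvalue < fdr_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$qvalue, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
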