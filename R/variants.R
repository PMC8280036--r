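#' Classify trio inheritance of proband variant calls
#'
#' Determines, for each variant carried by a proband, whether it arose de
#' novo, was transmitted from one parent, is carried by both parents
#' (unphased), or cannot be resolved because a parental genotype is missing.
#' De novo status requires both parents genotyped and homozygous reference.
#'
#' @param gt_proband,gt_father,gt_mother character vectors of genotype calls,
#'   one of `"hom_ref"`, `"het"`, `"hom_alt"`, `"hemi_alt"`, `"missing"`.
#'   `NA` is treated as `"missing"`.
#' @return character vector with values `"de_novo"`, `"inherited_paternal"`,
#'   `"inherited_maternal"`, `"inherited_unphased"` or `"unknown"`.
#' @examples
#' classify_inheritance("het", "hom_ref", "hom_ref")   # de_novo
#' classify_inheritance("het", "hom_ref", "het")       # inherited_maternal
#' classify_inheritance("het", "missing", "hom_ref")   # unknown
#' @export
classify_inheritance <- function(gt_proband, gt_father, gt_mother) {
  n <- length(gt_proband)
  stopifnot(length(gt_father) == n, length(gt_mother) == n)
  .assert_in(gt_proband, .GT_LEVELS, "proband genotype")
  .assert_in(gt_father, .GT_LEVELS, "father genotype")
  .assert_in(gt_mother, .GT_LEVELS, "mother genotype")
  if (any(.gt_missing(gt_proband) | !.gt_carrier(gt_proband))) {
    stop("non-carrier proband: proband genotype must carry the alternate allele",
         call. = FALSE)
  }
  fa_na <- .gt_missing(gt_father)
  mo_na <- .gt_missing(gt_mother)
  fa <- .gt_carrier(gt_father)
  mo <- .gt_carrier(gt_mother)
  out <- rep("unknown", n)
  known <- !fa_na & !mo_na
  out[known & !fa & !mo] <- "de_novo"
  out[known & fa & !mo] <- "inherited_paternal"
  out[known & !fa & mo] <- "inherited_maternal"
  out[known & fa & mo] <- "inherited_unphased"
  out
}

#' Classify variant functional class (PTV / Dmis)
#'
#' Protein-truncating variants (stop-gain, stop-loss, frameshift, splicing)
#' are classed `"PTV"`. Missense variants with a ReVe deleteriousness score
#' strictly above `reve_threshold` are classed `"Dmis"`; all other variants
#' (including missense at or below the threshold, and missense with a
#' missing score) are `"excluded"`.
#'
#' @param effect character vector of effect annotations.
#' @param reve numeric vector of ReVe scores in `[0, 1]`; `NA` when not a
#'   scored missense variant.
#' @param reve_threshold Dmis cutoff; the default 0.7 is exclusive
#'   (a score of exactly 0.7 is excluded).
#' @return character vector with values `"PTV"`, `"Dmis"`, `"excluded"`.
#' @export
classify_function <- function(effect, reve = rep(NA_real_, length(effect)),
                              reve_threshold = 0.7) {
  stopifnot(length(reve) == length(effect))
  .assert_in(effect, .EFFECT_LEVELS, "effect")
  if (any(!is.na(reve) & (reve < 0 | reve > 1))) {
    stop("ReVe scores must lie in [0, 1]", call. = FALSE)
  }
  out <- rep("excluded", length(effect))
  out[effect %in% .PTV_EFFECTS] <- "PTV"
  mis <- !is.na(effect) & effect == "missense"
  if (any(mis & is.na(reve))) {
    warning(sprintf("%d missense variant(s) with missing ReVe score excluded",
                    sum(mis & is.na(reve))), call. = FALSE)
  }
  out[mis & !is.na(reve) & reve > reve_threshold] <- "Dmis"
  out
}

#' Population allele-frequency filter
#'
#' A variant passes when every *observed* allele frequency (gnomAD, ExAC,
#' in-house) is at most `max_af`. Frequencies absent from all databases
#' pass: rare panel variants are typically unobserved in population
#' references, so absence is treated as evidence of rarity.
#'
#' @param af_gnomad,af_exac,af_inhouse numeric vectors of allele
#'   frequencies in `[0, 1]`; `NA` = not observed.
#' @param max_af maximum tolerated minor-allele frequency (default 0.001,
#'   i.e. 0.1%); the bound is inclusive.
#' @return logical vector.
#' @export
passes_frequency_filter <- function(af_gnomad = NA_real_, af_exac = NA_real_,
                                    af_inhouse = NA_real_, max_af = 0.001) {
  af <- cbind(af_gnomad, af_exac, af_inhouse)
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  apply(af, 1L, function(row) all(is.na(row) | row <= max_af))
}

#' Select potential functional variants
#'
#' Applies the functional-class and allele-frequency filters to an annotated
#' variant table and annotates retained rows with their functional class and
#' (where trio genotypes allow) inheritance status. This is the qualifying
#' set fed to gene-count tabulation.
#'
#' @param variants data frame in the annotated-variant layout (see
#'   [read_variant_table()]). Must contain `effect`; `reve`, allele
#'   frequency and genotype columns are used when present.
#' @param reve_threshold,max_af filter thresholds, see
#'   [classify_function()] and [passes_frequency_filter()].
#' @return the retained rows with added columns `functional_class` and
#'   (when genotype columns are present) `inheritance`.
#' @export
select_potential_functional <- function(variants, reve_threshold = 0.7,
                                        max_af = 0.001) {
  if (nrow(variants) == 0L) {
    variants$functional_class <- character(0)
    return(variants)
  }
  reve <- if ("reve" %in% names(variants)) variants$reve else NA_real_
  fclass <- classify_function(variants$effect, reve, reve_threshold)
  af_col <- function(nm) if (nm %in% names(variants)) variants[[nm]] else
    rep(NA_real_, nrow(variants))
  freq_ok <- passes_frequency_filter(af_col("af_gnomad"), af_col("af_exac"),
                                     af_col("af_inhouse"), max_af)
  keep <- fclass %in% c("PTV", "Dmis") & freq_ok
  out <- variants[keep, , drop = FALSE]
  out$functional_class <- fclass[keep]
  if (all(c("gt_proband", "gt_father", "gt_mother") %in% names(out))) {
    out$inheritance <- if (nrow(out)) {
      classify_inheritance(out$gt_proband, out$gt_father, out$gt_mother)
    } else character(0)
  }
  rownames(out) <- NULL
  out
}

#' Detect inherited X-linked hemizygous variants
#'
#' Returns chrX variants called hemizygous-alternate in male probands with a
#' heterozygous-carrier mother and a non-carrier father, i.e. maternally
#' transmitted hemizygous variants. De novo hemizygous calls (mother
#' homozygous reference) are not returned here; they belong with the de novo
#' counts. Hemizygous calls recorded in female probands are inconsistent and
#' dropped with a warning.
#'
#' @param variants data frame of selected variants (output of
#'   [select_potential_functional()]) with `chrom`, `proband_sex` and
#'   genotype columns.
#' @return the subset of maternally inherited X-linked hemizygous rows.
#' @export
detect_xlinked_hemizygous <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  chrom <- normalize_chrom(variants$chrom)
  hemi <- !.gt_missing(variants$gt_proband) & variants$gt_proband == "hemi_alt"
  bad_sex <- hemi & chrom == "X" & !is.na(variants$proband_sex) &
    variants$proband_sex == "female"
  if (any(bad_sex)) {
    warning(sprintf(
      "%d chrX hemizygous call(s) in probands recorded as female excluded as inconsistent",
      sum(bad_sex)), call. = FALSE)
  }
  keep <- chrom == "X" &
    !is.na(variants$proband_sex) & variants$proband_sex == "male" &
    hemi &
    !.gt_missing(variants$gt_mother) & variants$gt_mother == "het" &
    !.gt_missing(variants$gt_father) & !.gt_carrier(variants$gt_father)
  out <- variants[keep & !bad_sex, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tabulate per-gene qualifying-variant counts
#'
#' Builds the gene-by-class count table consumed by the TADA stage: de novo
#' PTV/Dmis counts over trio probands, "case" counts pooling inherited and
#' inheritance-unknown qualifying variants over all probands (trios plus
#' parent-less singletons), and control counts from an independently
#' filtered control variant set.
#'
#' @param selected data frame of qualifying proband variants with `gene`,
#'   `functional_class` and `inheritance` columns (see
#'   [select_potential_functional()]).
#' @param n_trios,n_cases,n_controls cohort sizes recorded on the output as
#'   attributes (`n_cases` = number of probands contributing to the
#'   inherited/unknown arm).
#' @param control_variants optional data frame of qualifying control
#'   variants with `gene` and `functional_class` columns.
#' @param genes optional character vector of panel genes guaranteed a row
#'   (zero counts when unobserved).
#' @return data frame with columns `gene`, `x_dn_PTV`, `x_dn_Dmis`,
#'   `x_case_PTV`, `x_case_Dmis`, `x_ctrl_PTV`, `x_ctrl_Dmis`, sorted by
#'   gene symbol, with cohort sizes as attributes.
#' @export
tabulate_gene_counts <- function(selected, n_trios, n_cases, n_controls = 0L,
                                 control_variants = NULL, genes = NULL) {
  drop_unnamed <- function(df, what) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    bad <- is.na(df$gene) | df$gene == ""
    if (any(bad)) {
      warning(sprintf("%d %s variant(s) without a gene symbol skipped",
                      sum(bad), what), call. = FALSE)
    }
    df[!bad, , drop = FALSE]
  }
  selected <- drop_unnamed(selected, "proband")
  control_variants <- drop_unnamed(control_variants, "control")

  all_genes <- sort(unique(c(genes, selected$gene,
                             if (!is.null(control_variants)) control_variants$gene)))
  count <- function(df, cond) {
    if (is.null(df) || nrow(df) == 0L) return(setNames(integer(length(all_genes)), all_genes))
    sub <- df[cond(df), , drop = FALSE]
    tab <- table(factor(sub$gene, levels = all_genes))
    setNames(as.integer(tab), all_genes)
  }
  dn <- function(cls) count(selected, function(d)
    d$inheritance == "de_novo" & d$functional_class == cls)
  cs <- function(cls) count(selected, function(d)
    d$inheritance != "de_novo" & d$functional_class == cls)
  ct <- function(cls) count(control_variants, function(d)
    d$functional_class == cls)

  out <- data.frame(
    gene = all_genes,
    x_dn_PTV = dn("PTV"), x_dn_Dmis = dn("Dmis"),
    x_case_PTV = cs("PTV"), x_case_Dmis = cs("Dmis"),
    x_ctrl_PTV = ct("PTV"), x_ctrl_Dmis = ct("Dmis"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_trios") <- as.integer(n_trios)
  attr(out, "n_cases") <- as.integer(n_cases)
  attr(out, "n_controls") <- as.integer(n_controls)
  out
}

#' Genes carrying multiple de novo variants
#'
#' Filters the gene-count table to genes whose de novo PTV + Dmis total
#' reaches `min_total_dnv`, ordered by total (descending) then gene symbol.
#'
#' @param counts gene-count table (columns `gene`, `x_dn_PTV`, `x_dn_Dmis`).
#' @param min_total_dnv minimum number of de novo variants (default 2).
#' @return data frame `gene`, `x_dn_PTV`, `x_dn_Dmis`, `total`.
#' @export
find_multi_dnv_genes <- function(counts, min_total_dnv = 2L) {
  total <- counts$x_dn_PTV + counts$x_dn_Dmis
  keep <- total >= min_total_dnv
  out <- data.frame(gene = counts$gene[keep],
                    x_dn_PTV = counts$x_dn_PTV[keep],
                    x_dn_Dmis = counts$x_dn_Dmis[keep],
                    total = total[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
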