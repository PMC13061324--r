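#' Simes combination of two p-values
#'
#' Omnibus p-value for the intersection null of the CN-naive and CN-aware
#' hypotheses: `pS = min(2 * min(pN, pA), max(pN, pA))`. Symmetric in its
#' arguments and valid for the global null under the Simes inequality.
#'
#' @param p_naive,p_aware Vectors of raw p-values in \[0, 1\] (recycled).
#' @return Vector of combined p-values.
#' @export
simes_combine <- function(p_naive, p_aware) {
  ok <- is.na(p_naive) | is.na(p_aware) |
    (p_naive >= 0 & p_naive <= 1 & p_aware >= 0 & p_aware <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  ps <- pmin(2 * pmin(p_naive, p_aware), pmax(p_naive, p_aware))
  ifelse(is.na(p_naive) | is.na(p_aware), NA_real_, ps)
}

#' Benjamini-Hochberg screening stage
#'
#' One BH pass over the Simes omnibus p-values at level `alpha`. Genes with
#' adjusted p below `alpha` pass screening. The level carried to the
#' confirmation stage is the BH-adjusted level `alpha * |R| / G` implied by
#' the screening rejections (`stage2 = "adjusted"`, the stage-wise testing
#' default), or `alpha` itself (`stage2 = "alpha"`).
#'
#' @param p_simes Vector of omnibus p-values (NAs allowed; excluded from the
#'   BH family).
#' @param alpha Screening FDR level in (0, 1).
#' @param stage2 Confirmation-level rule.
#' @return List with `screened` (logical), `padj` (BH-adjusted omnibus p),
#'   `stage2_level`, `n_rejected`, `n_family`.
#' @export
screen_bh <- function(p_simes, alpha = 0.05, stage2 = c("adjusted", "alpha")) {
  stage2 <- match.arg(stage2)
  stopifnot(alpha > 0, alpha < 1)
  padj <- rep(NA_real_, length(p_simes))
  fam <- !is.na(p_simes)
  padj[fam] <- stats::p.adjust(p_simes[fam], method = "BH")
  screened <- !is.na(padj) & padj < alpha
  n_rej <- sum(screened)
  n_fam <- sum(fam)
  level <- if (stage2 == "adjusted") {
    if (n_fam) alpha * n_rej / n_fam else 0
  } else alpha
  list(screened = screened, padj = padj, stage2_level = level,
       n_rejected = n_rej, n_family = n_fam)
}

#' Holm confirmation of the two component hypotheses
#'
#' For a screened gene, Holm's step-down over the CN-naive and CN-aware
#' p-values at level `t`: the smaller p-value is rejected if `<= t / 2`;
#' only then is the larger rejected if `<= t`.
#'
#' @param p_naive,p_aware Raw component p-values.
#' @param stage2_level Confirmation level `t`.
#' @return List with logical vectors `de_naive`, `de_aware`.
#' @export
confirm_holm <- function(p_naive, p_aware, stage2_level) {
  t <- stage2_level
  p_lo <- pmin(p_naive, p_aware)
  p_hi <- pmax(p_naive, p_aware)
  rej_lo <- p_lo <= t / 2
  rej_hi <- rej_lo & p_hi <= t
  naive_is_lo <- p_naive <= p_aware
  list(de_naive = ifelse(naive_is_lo, rej_lo, rej_hi),
       de_aware = ifelse(naive_is_lo, rej_hi, rej_lo))
}

.check_same_genes <- function(naive_table, aware_table) {
  if (!identical(naive_table$gene_id, aware_table$gene_id))
    stop("naive and aware tables must cover the same genes in the same order")
}

#' Stage-wise testing across the CN-naive and CN-aware models
#'
#' Combines the two per-model Wald p-values with the Simes omnibus test,
#' screens genes with a single BH pass at level `alpha`, and confirms the
#' component hypotheses of screened genes with a per-gene Holm procedure.
#' Genes failing screening (or with missing p-values from failed fits,
#' which are excluded from the BH family) get both decisions set to 0.
#'
#' @param naive_table,aware_table Per-gene tables from [run_dge()] (columns
#'   `gene_id`, `pvalue`, `lfc`), covering the same genes.
#' @param alpha Screening FDR level.
#' @param stage2 Confirmation-level rule, see [screen_bh()].
#' @return `data.frame` with `gene_id`, `p_naive`, `p_aware`, `p_simes`,
#'   `padj_screen`, `screened`, `confirmed_naive`, `confirmed_aware`,
#'   `lfc_naive`, `lfc_aware`; attribute `stage2_level`.
#' @export
stagewise_pipeline <- function(naive_table, aware_table, alpha = 0.05,
                               stage2 = c("adjusted", "alpha")) {
  .check_same_genes(naive_table, aware_table)
  pn <- naive_table$pvalue
  pa <- aware_table$pvalue
  ps <- simes_combine(pn, pa)
  sc <- screen_bh(ps, alpha = alpha, stage2 = stage2)
  hm <- confirm_holm(pn, pa, sc$stage2_level)
  out <- data.frame(
    gene_id = naive_table$gene_id,
    p_naive = pn, p_aware = pa, p_simes = ps,
    padj_screen = sc$padj,
    screened = sc$screened,
    confirmed_naive = sc$screened & !is.na(hm$de_naive) & hm$de_naive,
    confirmed_aware = sc$screened & !is.na(hm$de_aware) & hm$de_aware,
    lfc_naive = naive_table$lfc,
    lfc_aware = aware_table$lfc,
    stringsAsFactors = FALSE
  )
  attr(out, "stage2_level") <- sc$stage2_level
  attr(out, "mt_mode") <- "stagewise"
  out
}

#' Independent per-model BH correction (comparator mode)
#'
#' Legacy analysis applying BH separately to the CN-naive and CN-aware
#' p-value families, with no omnibus screening. Provided for comparison with
#' the stage-wise scheme; per-model families do not jointly control the
#' error rate over the combined decisions.
#'
#' @inheritParams stagewise_pipeline
#' @return Same shape as [stagewise_pipeline()]; `p_simes`/`padj_screen`
#'   report the per-model minimum adjusted p for reference, `screened` is
#'   `TRUE` wherever either model rejects.
#' @export
per_model_bh <- function(naive_table, aware_table, alpha = 0.05) {
  .check_same_genes(naive_table, aware_table)
  pn <- naive_table$pvalue
  pa <- aware_table$pvalue
  adj <- function(p) {
    out <- rep(NA_real_, length(p))
    out[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    out
  }
  qn <- adj(pn); qa <- adj(pa)
  de_n <- !is.na(qn) & qn < alpha
  de_a <- !is.na(qa) & qa < alpha
  out <- data.frame(
    gene_id = naive_table$gene_id,
    p_naive = pn, p_aware = pa,
    p_simes = NA_real_,
    padj_screen = pmin(qn, qa),
    screened = de_n | de_a,
    confirmed_naive = de_n,
    confirmed_aware = de_a,
    lfc_naive = naive_table$lfc,
    lfc_aware = aware_table$lfc,
    stringsAsFactors = FALSE
  )
  attr(out, "padj_naive") <- qn
  attr(out, "padj_aware") <- qa
  attr(out, "mt_mode") <- "per_model"
  out
}
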