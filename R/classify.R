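#' Final differential expression bit for one model
#'
#' A gene counts as DE under a model only if its confirmed test decision is
#' positive and its absolute shrunken log2 fold change strictly exceeds the
#' effect-size threshold. Missing fold changes yield 0.
#'
#' @param confirmed Logical/0-1 confirmed decision from the testing stage.
#' @param lfc Shrunken log2 fold change.
#' @param lfc_threshold Strict absolute threshold (default 1).
#' @return Integer 0/1 vector.
#' @export
de_bit <- function(confirmed, lfc, lfc_threshold = 1) {
  bit <- as.integer(confirmed & !is.na(lfc) & abs(lfc) > lfc_threshold)
  bit[is.na(confirmed)] <- 0L
  bit
}

#' Map joint DE decisions to a gene-dosage class
#'
#' `(naive, aware)` decision bits map to: (1,0) dosage-sensitive DSG,
#' (1,1) dosage-insensitive DIG, (0,1) dosage-compensated DCG,
#' (0,0) non-DE.
#'
#' @param de_naive,de_aware 0/1 decision bits.
#' @return Factor with levels DSG, DIG, DCG, nonDEG.
#' @export
classify_gene <- function(de_naive, de_aware) {
  stopifnot(all(de_naive %in% 0:1), all(de_aware %in% 0:1))
  cls <- ifelse(de_naive == 1 & de_aware == 0, "DSG",
         ifelse(de_naive == 1 & de_aware == 1, "DIG",
         ifelse(de_naive == 0 & de_aware == 1, "DCG", "nonDEG")))
  factor(cls, levels = c("DSG", "DIG", "DCG", "nonDEG"))
}

#' Classify all genes from stage-wise decisions
#'
#' Applies the effect-size gate to each model's confirmed decision and its
#' own shrunken log2 fold change, then maps the joint bits to the four
#' gene-dosage classes. Direction (up/down) is taken from the sign of the
#' CN-aware fold change for DIG/DCG genes and the CN-naive fold change for
#' DSGs.
#'
#' @param dual Stage-wise result table from [stagewise_pipeline()] or
#'   [per_model_bh()].
#' @param lfc_threshold Strict absolute log2 fold-change threshold.
#' @return List with `table` (`gene_id`, `de_naive`, `de_aware`,
#'   `dosage_class`, `direction`, `lfc_naive`, `lfc_aware`) and `summary`
#'   (per-class counts and percentages).
#' @export
classify_all <- function(dual, lfc_threshold = 1) {
  de_n <- de_bit(dual$confirmed_naive, dual$lfc_naive, lfc_threshold)
  de_a <- de_bit(dual$confirmed_aware, dual$lfc_aware, lfc_threshold)
  cls <- classify_gene(de_n, de_a)
  lfc_dir <- ifelse(cls == "DSG", dual$lfc_naive, dual$lfc_aware)
  direction <- ifelse(cls == "nonDEG", NA_character_,
                      ifelse(lfc_dir > 0, "up", "down"))
  tab <- data.frame(gene_id = dual$gene_id, de_naive = de_n, de_aware = de_a,
                    dosage_class = cls, direction = direction,
                    lfc_naive = dual$lfc_naive, lfc_aware = dual$lfc_aware,
                    stringsAsFactors = FALSE)
  counts <- table(cls)
  summary <- data.frame(dosage_class = names(counts),
                        n = as.integer(counts),
                        percent = 100 * as.integer(counts) / length(cls))
  list(table = tab, summary = summary)
}
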