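#' Confusion counts against simulation ground truth
#'
#' `de_detection`: positives are true DIGs (condition-driven DE) and
#' negatives are true DSGs and non-DE genes (CN-driven or null); true DCGs
#' are excluded from the counts and evaluated separately. `class_vs_class`:
#' one-vs-one discrimination restricted to genes whose truth is the
#' `positive` or `negative` class, with a predicted-class vector.
#'
#' @param truth Vector of true class labels (DSG/DIG/DCG/nonDEG).
#' @param predicted For `de_detection`: 0/1 DE calls; for `class_vs_class`:
#'   predicted class labels.
#' @param scheme Evaluation scheme.
#' @param positive,negative Classes contrasted in `class_vs_class` mode.
#' @return List of class `"confusion_counts"` with `tp`, `fp`, `tn`, `fn`,
#'   `n` (evaluated genes).
#' @export
confusion_from_truth <- function(truth, predicted,
                                 scheme = c("de_detection", "class_vs_class"),
                                 positive = "DCG", negative = "DSG") {
  scheme <- match.arg(scheme)
  truth <- as.character(truth)
  known <- c("DSG", "DIG", "DCG", "nonDEG")
  if (!all(truth %in% known))
    stop("unknown truth label: ", setdiff(truth, known)[1])
  stopifnot(length(truth) == length(predicted))
  if (scheme == "de_detection") {
    keep <- truth != "DCG"
    truth <- truth[keep]
    called <- as.logical(predicted[keep])
    pos <- truth == "DIG"
  } else {
    keep <- truth %in% c(positive, negative)
    truth <- truth[keep]
    called <- as.character(predicted[keep]) == positive
    pos <- truth == positive
  }
  structure(list(tp = sum(pos & called), fp = sum(!pos & called),
                 tn = sum(!pos & !called), fn = sum(pos & !called),
                 n = length(truth)),
            class = "confusion_counts")
}

#' Binary classification metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1, and
#' the Matthews correlation coefficient. Ratios with zero denominators are
#' returned as `NA`.
#'
#' @param counts `"confusion_counts"` object or list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @return Named list with `precision`, `recall`, `f1`, `mcc`.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

#' Effect-size estimation accuracy
#'
#' Mean squared error and squared Pearson correlation between estimated and
#' reference log2 fold changes; the raw (signed) correlation is also
#' returned. Pairs with missing values are dropped.
#'
#' @param true_lfc,estimated_lfc Aligned numeric vectors (length >= 3 after
#'   removing missing pairs).
#' @return List with `mse`, `pearson_r2`, `pearson_r`, `n`.
#' @export
lfc_accuracy <- function(true_lfc, estimated_lfc) {
  stopifnot(length(true_lfc) == length(estimated_lfc))
  ok <- !is.na(true_lfc) & !is.na(estimated_lfc)
  x <- true_lfc[ok]; y <- estimated_lfc[ok]
  if (length(x) < 3) stop("need at least 3 paired values")
  mse <- mean((y - x)^2)
  r <- if (stats::sd(x) > 0 && stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  list(mse = mse, pearson_r2 = r^2, pearson_r = r, n = length(x))
}

#' Jaccard index of two gene sets
#'
#' `|A intersect B| / |A union B|`; two empty sets have identical membership
#' and return 1.
#'
#' @param set_a,set_b Vectors of gene identifiers.
#' @return Number in \[0, 1\].
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(1)
  length(intersect(set_a, set_b)) / u
}

# Run the paired naive/aware pipeline on a simulated dataset and return the
# per-gene decision table plus classes, restricted to the analysis gene set
# (low-expression filter applied as in real analyses).
.run_dual_sim <- function(dataset, alpha = 0.05, lfc_threshold = 1,
                          mt_mode = "stagewise", cn = NULL) {
  res <- dosage_analysis(dataset$counts,
                         if (is.null(cn)) dataset$cn else cn,
                         dataset$design,
                         alpha = alpha, lfc_threshold = lfc_threshold,
                         mt_mode = mt_mode)
  tab <- res$results
  truth <- dataset$truth[match(tab$gene_id, dataset$truth$gene_id), ]
  tab$truth_class <- as.character(truth$class)
  tab$true_lfc <- truth$true_lfc
  tab
}

#' Simulation benchmark of DE detection under CN confounding
#'
#' For each sample size and replicate: simulate a dataset, run the CN-aware
#' and CN-naive pipelines with stage-wise testing, and score each method's
#' final DE calls against the ground truth (true DIGs as positives, true
#' DSGs and non-DE genes as negatives), together with effect-size accuracy
#' of the shrunken log2 fold changes against the true biological effects.
#'
#' @param config Base [sim_config()]; its seed is the master seed.
#' @param sample_sizes Per-condition sample sizes (default 10, 20, 40, 60).
#' @param n_replicates Replicates per size (default 5).
#' @param alpha,lfc_threshold,mt_mode Pipeline settings.
#' @param verbose Print progress.
#' @return List with `per_replicate` (tidy `data.frame`: method,
#'   sample_size, replicate, precision, recall, f1, mcc, mse, pearson_r2)
#'   and `aggregate` (mean and sd per method and size).
#' @export
de_benchmark <- function(config, sample_sizes = c(10, 20, 40, 60),
                         n_replicates = 5, alpha = 0.05, lfc_threshold = 1,
                         mt_mode = "stagewise", verbose = FALSE) {
  grid <- replicate_grid(config, sample_sizes, n_replicates)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    if (verbose) message(sprintf("de_benchmark: n=%d rep=%d",
                                 grid$sample_size[i], grid$replicate[i]))
    d <- simulate_dataset(grid$config[[i]])
    tab <- .run_dual_sim(d, alpha, lfc_threshold, mt_mode)
    for (method in c("aware", "naive")) {
      bits <- if (method == "aware") tab$de_aware else tab$de_naive
      lfc <- if (method == "aware") tab$lfc_aware else tab$lfc_naive
      cm <- classification_metrics(
        confusion_from_truth(tab$truth_class, bits, "de_detection"))
      keep <- tab$truth_class != "DCG"
      acc <- lfc_accuracy(tab$true_lfc[keep], lfc[keep])
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, sample_size = grid$sample_size[i],
        replicate = grid$replicate[i],
        precision = cm$precision, recall = cm$recall, f1 = cm$f1,
        mcc = cm$mcc, mse = acc$mse, pearson_r2 = acc$pearson_r2,
        stringsAsFactors = FALSE)
    }
  }
  per_replicate <- do.call(rbind, rows)
  list(per_replicate = per_replicate,
       aggregate = .aggregate_benchmark(per_replicate, c("method", "sample_size")))
}

.aggregate_benchmark <- function(df, by) {
  metrics <- setdiff(names(df), c(by, "replicate"))
  agg_mean <- stats::aggregate(df[metrics], df[by], mean, na.rm = TRUE)
  agg_sd <- stats::aggregate(df[metrics], df[by], stats::sd, na.rm = TRUE)
  names(agg_sd)[-seq_along(by)] <- paste0(metrics, "_sd")
  merge(agg_mean, agg_sd, by = by)
}

#' Gene-dosage classification benchmark
#'
#' Evaluates discrimination of dosage-compensated genes from
#' dosage-sensitive and dosage-insensitive genes on simulated data with all
#' four classes present, across sample sizes and CN signal strengths.
#' Also emits one-vs-rest metrics per class.
#'
#' @param config Base [sim_config()]; must allocate a positive DCG fraction.
#' @param sample_sizes,n_replicates Grid settings.
#' @param cn_signal Signal strengths to evaluate.
#' @param alpha,lfc_threshold,mt_mode Pipeline settings.
#' @param verbose Print progress.
#' @return List with `pairwise` (task = DCG_vs_DSG / DCG_vs_DIG),
#'   `one_vs_rest` (per-class), and aggregates of both.
#' @export
classification_benchmark <- function(config, sample_sizes = c(10, 20, 40, 60),
                                     n_replicates = 5,
                                     cn_signal = c("strong", "weak"),
                                     alpha = 0.05, lfc_threshold = 1,
                                     mt_mode = "stagewise", verbose = FALSE) {
  if (config$class_proportions[["DCG"]] <= 0)
    stop("classification benchmark needs a positive DCG proportion")
  pair_rows <- list(); ovr_rows <- list()
  for (sig in cn_signal) {
    cfg <- config
    cfg$cn_signal <- sig
    grid <- replicate_grid(cfg, sample_sizes, n_replicates)
    for (i in seq_len(nrow(grid))) {
      if (verbose) message(sprintf("classification_benchmark: %s n=%d rep=%d",
                                   sig, grid$sample_size[i], grid$replicate[i]))
      d <- simulate_dataset(grid$config[[i]])
      tab <- .run_dual_sim(d, alpha, lfc_threshold, mt_mode)
      pred <- as.character(classify_gene(tab$de_naive, tab$de_aware))
      for (neg in c("DSG", "DIG")) {
        cm <- classification_metrics(
          confusion_from_truth(tab$truth_class, pred, "class_vs_class",
                               positive = "DCG", negative = neg))
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          task = paste0("DCG_vs_", neg), cn_signal = sig,
          sample_size = grid$sample_size[i], replicate = grid$replicate[i],
          precision = cm$precision, recall = cm$recall, f1 = cm$f1,
          mcc = cm$mcc, stringsAsFactors = FALSE)
      }
      for (cls in c("DSG", "DIG", "DCG")) {
        pos <- tab$truth_class == cls
        called <- pred == cls
        cm <- classification_metrics(list(tp = sum(pos & called),
                                          fp = sum(!pos & called),
                                          tn = sum(!pos & !called),
                                          fn = sum(pos & !called)))
        ovr_rows[[length(ovr_rows) + 1L]] <- data.frame(
          class = cls, cn_signal = sig, sample_size = grid$sample_size[i],
          replicate = grid$replicate[i], precision = cm$precision,
          recall = cm$recall, f1 = cm$f1, mcc = cm$mcc,
          stringsAsFactors = FALSE)
      }
    }
  }
  pairwise <- do.call(rbind, pair_rows)
  one_vs_rest <- do.call(rbind, ovr_rows)
  list(pairwise = pairwise, one_vs_rest = one_vs_rest,
       pairwise_aggregate = .aggregate_benchmark(
         pairwise, c("task", "cn_signal", "sample_size")),
       one_vs_rest_aggregate = .aggregate_benchmark(
         one_vs_rest, c("class", "cn_signal", "sample_size")))
}

#' Robustness of the pipeline to copy-number noise
#'
#' For each sample size and replicate, runs the clean pipeline, then
#' re-runs the CN-aware arm after perturbing the tumor CN entries with
#' [inject_cn_noise()] at each noise fraction (normal-sample CN is an
#' assumption, not an estimate, and is left untouched; the CN-naive arm
#' never sees the CN matrix). Stability is summarized per dosage class by
#' the Jaccard index of clean vs noisy memberships, the squared Pearson
#' correlation of clean vs noisy CN-aware log2 fold changes, and the
#' squared Spearman correlation of screening-adjusted p-values.
#'
#' @param config Base [sim_config()].
#' @param sample_sizes,noise_fractions,n_replicates Grid settings.
#' @param alpha,lfc_threshold,mt_mode Pipeline settings.
#' @param verbose Print progress.
#' @return List with `per_replicate` (class, sample_size, noise_fraction,
#'   replicate, jaccard, lfc_r2, fdr_spearman_r2) and `aggregate`.
#' @export
robustness_suite <- function(config, sample_sizes = c(10, 20, 40, 60),
                             noise_fractions = c(0.05, 0.10, 0.15, 0.20),
                             n_replicates = 3, alpha = 0.05,
                             lfc_threshold = 1, mt_mode = "stagewise",
                             verbose = FALSE) {
  grid <- replicate_grid(config, sample_sizes, n_replicates)
  rows <- list()
  classes <- c("DSG", "DIG", "DCG", "nonDEG")
  for (i in seq_len(nrow(grid))) {
    if (verbose) message(sprintf("robustness_suite: n=%d rep=%d",
                                 grid$sample_size[i], grid$replicate[i]))
    d <- simulate_dataset(grid$config[[i]])
    clean <- .run_dual_sim(d, alpha, lfc_threshold, mt_mode)
    clean_cls <- as.character(classify_gene(clean$de_naive, clean$de_aware))
    tumor_cols <- d$design$sample_id[d$design$condition == 1]
    for (nf in noise_fractions) {
      cn_noisy <- d$cn
      cn_noisy[, tumor_cols] <- inject_cn_noise(
        d$cn[, tumor_cols, drop = FALSE], nf,
        seed = (grid$seed[i] + round(1e4 * nf)) %% .Machine$integer.max)
      noisy <- .run_dual_sim(d, alpha, lfc_threshold, mt_mode, cn = cn_noisy)
      noisy_cls <- as.character(classify_gene(noisy$de_naive, noisy$de_aware))
      stopifnot(identical(clean$gene_id, noisy$gene_id))
      usable <- !is.na(clean$lfc_aware) & !is.na(noisy$lfc_aware)
      for (cls in classes) {
        in_cls <- clean_cls == cls & usable
        jac <- jaccard(clean$gene_id[clean_cls == cls],
                       noisy$gene_id[noisy_cls == cls])
        lfc_r2 <- if (sum(in_cls) >= 3)
          lfc_accuracy(clean$lfc_aware[in_cls], noisy$lfc_aware[in_cls])$pearson_r2
          else NA_real_
        sp <- if (sum(in_cls) >= 3)
          suppressWarnings(stats::cor(clean$padj_screen[in_cls],
                                      noisy$padj_screen[in_cls],
                                      method = "spearman",
                                      use = "complete.obs"))^2 else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, sample_size = grid$sample_size[i],
          noise_fraction = nf, replicate = grid$replicate[i],
          jaccard = jac, lfc_r2 = lfc_r2, fdr_spearman_r2 = sp,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_replicate <- do.call(rbind, rows)
  list(per_replicate = per_replicate,
       aggregate = .aggregate_benchmark(
         per_replicate, c("class", "sample_size", "noise_fraction")))
}
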