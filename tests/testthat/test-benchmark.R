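test_that("confusion counting maps dosage classes to the DE benchmark roles", {
  cc <- confusion_from_truth(c("DIG", "DIG", "DSG", "nonDEG"), c(1, 0, 1, 0),
                             "de_detection")
  expect_identical(unlist(cc[c("tp", "fp", "tn", "fn")]),
                   c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))

  perfect <- confusion_from_truth(c("DIG", "DSG", "nonDEG"), c(1, 0, 0),
                                  "de_detection")
  expect_identical(perfect$fp + perfect$fn, 0L)

  # DCGs are excluded from the binary DE benchmark
  with_dcg <- confusion_from_truth(c("DIG", "DCG", "DCG", "nonDEG"),
                                   c(1, 1, 0, 0), "de_detection")
  expect_identical(with_dcg$n, 2L)
  expect_identical(with_dcg$fp, 0L)

  expect_error(confusion_from_truth(c("DIG", "weird"), c(1, 0)), "unknown truth")

  # one-vs-one scheme restricted to the two contrasted classes
  cc2 <- confusion_from_truth(c("DCG", "DCG", "DSG", "DIG"),
                              c("DCG", "DSG", "DCG", "DCG"),
                              "class_vs_class", positive = "DCG",
                              negative = "DSG")
  expect_identical(unlist(cc2[c("tp", "fp", "tn", "fn")]),
                   c(tp = 1L, fp = 1L, tn = 0L, fn = 1L))
})

test_that("metrics match hand values and an independent correlation oracle", {
  m <- classification_metrics(list(tp = 3, fp = 1, tn = 5, fn = 1))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, 14 / 24)

  degen <- classification_metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(degen$precision) && is.na(degen$recall) && is.na(degen$mcc))

  perfect <- classification_metrics(list(tp = 5, fp = 0, tn = 5, fn = 0))
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1, mcc = 1))

  # MCC equals the Pearson correlation of the binary label vectors
  set.seed(47)
  for (i in 1:200) {
    tab <- as.list(rmultinom(1, sample(10:200, 1), runif(4, 0.05, 1))[, 1])
    names(tab) <- c("tp", "fp", "tn", "fn")
    m <- classification_metrics(tab)
    truth <- rep(c(1, 0, 0, 1), unlist(tab))
    pred  <- rep(c(1, 1, 0, 0), unlist(tab))
    oracle <- suppressWarnings(cor(truth, pred))
    if (!is.na(oracle)) expect_equal(m$mcc, oracle, tolerance = 1e-12)
    if (tab$tp + tab$fp > 0) expect_equal(m$precision, mean(truth[pred == 1]))
    if (tab$tp + tab$fn > 0) expect_equal(m$recall, mean(pred[truth == 1]))
  }
})

test_that("effect-size accuracy separates bias from correlation", {
  x <- c(0, 1, 2, 3, -1)
  expect_equal(lfc_accuracy(x, x), list(mse = 0, pearson_r2 = 1,
                                        pearson_r = 1, n = 5L))
  shifted <- lfc_accuracy(x, x + 0.5)
  expect_equal(shifted$mse, 0.25)
  expect_equal(shifted$pearson_r2, 1)
  flipped <- lfc_accuracy(x, -x)
  expect_equal(flipped$pearson_r2, 1)
  expect_equal(flipped$pearson_r, -1)
  expect_true(is.na(lfc_accuracy(x, rep(1, 5))$pearson_r2))
  expect_error(lfc_accuracy(c(1, 2), c(1, 2)), "at least 3")
})

test_that("Jaccard index satisfies its identities", {
  expect_equal(jaccard(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard(letters[1:4], letters[1:4]), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(character(0), character(0)), 1)
  set.seed(53)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(0:15, 1))
    expect_equal(jaccard(a, b), jaccard(b, a))
    expect_gte(jaccard(a, b), 0)
    expect_lte(jaccard(a, b), 1)
  }
})

test_that("the DE benchmark produces a complete, deterministic report", {
  cfg <- sim_config(n_genes = 400, seed = 101)
  bm1 <- de_benchmark(cfg, sample_sizes = c(10, 20), n_replicates = 3)
  bm2 <- de_benchmark(cfg, sample_sizes = c(10, 20), n_replicates = 3)
  expect_identical(bm1, bm2)
  expect_identical(nrow(bm1$per_replicate), 12L)  # 2 sizes x 3 reps x 2 methods
  expect_identical(nrow(bm1$aggregate), 4L)
  expect_true(all(bm1$per_replicate$precision >= 0 &
                    bm1$per_replicate$precision <= 1, na.rm = TRUE))
  expect_true(all(bm1$per_replicate$mcc >= -1 &
                    bm1$per_replicate$mcc <= 1, na.rm = TRUE))
  # the CN-aware arm beats the naive arm on F1 in most replicates
  wide <- merge(
    bm1$per_replicate[bm1$per_replicate$method == "aware",
                      c("sample_size", "replicate", "f1")],
    bm1$per_replicate[bm1$per_replicate$method == "naive",
                      c("sample_size", "replicate", "f1")],
    by = c("sample_size", "replicate"), suffixes = c("_aware", "_naive"))
  expect_gte(mean(wide$f1_aware >= wide$f1_naive), 0.8)
})

test_that("the classification benchmark needs DCGs and favors the DSG contrast", {
  cfg0 <- sim_config(n_genes = 200, seed = 1)  # zero DCG fraction
  expect_error(classification_benchmark(cfg0), "DCG proportion")

  cfg <- sim_config(n_genes = 600,
                    class_proportions = c(DSG = 0.10, DIG = 0.30,
                                          DCG = 0.10, nonDEG = 0.50),
                    seed = 103)
  cb <- classification_benchmark(cfg, sample_sizes = 40, n_replicates = 2,
                                 cn_signal = "strong")
  agg <- cb$pairwise_aggregate
  expect_identical(sort(unique(agg$task)), c("DCG_vs_DIG", "DCG_vs_DSG"))
  p_dsg <- agg$precision[agg$task == "DCG_vs_DSG"]
  p_dig <- agg$precision[agg$task == "DCG_vs_DIG"]
  expect_gte(p_dsg, p_dig - 0.05)
  expect_identical(nrow(cb$one_vs_rest), 6L)  # 3 classes x 2 reps
})

test_that("the robustness suite reports stability that degrades with noise", {
  cfg <- sim_config(n_genes = 500, seed = 107)
  rb <- robustness_suite(cfg, sample_sizes = 20,
                         noise_fractions = c(0, 0.2), n_replicates = 2)
  agg <- rb$aggregate
  clean <- agg[agg$noise_fraction == 0, ]
  expect_true(all(clean$jaccard == 1))
  expect_true(all(abs(clean$lfc_r2 - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(clean$fdr_spearman_r2 - 1) < 1e-12, na.rm = TRUE))
  noisy <- agg[agg$noise_fraction == 0.2, ]
  dig_j <- noisy$jaccard[noisy$class == "DIG"]
  dsg_j <- noisy$jaccard[noisy$class == "DSG"]
  expect_gte(dig_j, dsg_j)   # DIG membership is the more CN-robust set
})
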