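test_that("size factors match the median-of-ratios definition", {
  # two samples, second column doubled: s = (1/sqrt(2), sqrt(2))
  m <- tiny_counts(c(10, 20, 30, 20, 40, 60), genes = c("a", "b", "c"))
  expect_equal(unname(estimate_size_factors(m)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  # identical columns give unit factors
  m2 <- tiny_counts(rep(c(5, 9, 14), 4), genes = c("a", "b", "c"),
                    samples = paste0("s", 1:4))
  expect_equal(unname(estimate_size_factors(m2)), rep(1, 4))

  # ratios to the per-gene geometric mean are unchanged by global rescaling
  expect_equal(estimate_size_factors(3 * m), estimate_size_factors(m))

  # exact agreement with the DESeq2 implementation on random matrices
  skip_if_not_installed("DESeq2")
  set.seed(11)
  r <- matrix(rnbinom(300, mu = 80, size = 2), 30,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  expect_equal(estimate_size_factors(r),
               DESeq2::estimateSizeFactorsForMatrix(r), tolerance = 1e-12)

  allzero <- tiny_counts(c(0, 5, 3, 0), genes = c("a", "b"))
  expect_error(estimate_size_factors(allzero), "pseudo")
  expect_true(all(estimate_size_factors(allzero, pseudo_count = 0.5) > 0))
})

test_that("offset factors encode size factor times CN dosage", {
  cn <- tiny_counts(c(2, 4, 1, 0), genes = c("a", "b"))
  s <- c(s1 = 1, s2 = 1)
  O <- build_offsets(s, cn, "aware")
  expect_equal(exp(O["a", "s1"]), 1)    # CN = 2 leaves expression unaltered
  expect_equal(exp(O["b", "s1"]), 2)    # CN = 4 doubles it
  expect_equal(exp(O["a", "s2"]), 0.5)  # CN = 1 halves it
  expect_equal(exp(O["b", "s2"]), 0.05) # CN 0 floored at 0.1
  expect_true(all(is.finite(O)))
  # naive mode ignores CN entirely
  expect_equal(build_offsets(c(s1 = 2, s2 = 0.5), cn, "naive"),
               matrix(log(c(2, 2, 0.5, 0.5)), 2,
                      dimnames = dimnames(cn)))
})

test_that("NB log-likelihood matches a direct log-gamma oracle", {
  set.seed(3)
  for (i in 1:25) {
    theta <- runif(1, 0.01, 2)
    mu <- runif(5, 0.5, 500)
    y <- rnbinom(5, mu = mu, size = 1 / theta)
    expect_equal(nb_loglik(y, mu, theta),
                 sum(dnbinom(y, size = 1 / theta, mu = mu, log = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("intercept-only NB MLE recovers the sample mean", {
  y <- matrix(c(4, 6, 5, 5), 1, dimnames = list("g", paste0("s", 1:4)))
  X <- matrix(1, 4, 1, dimnames = list(NULL, "intercept"))
  O <- matrix(0, 1, 4)
  fit <- fit_glm(y, X, O, dispersions = 0.1)
  expect_equal(exp(fit$beta[1, 1]), 5, tolerance = 1e-6)
})

test_that("doubling a gene's tumor offsets shifts its condition MLE by -ln 2", {
  d <- nb_two_group(40, 12, mu_normal = rep(150, 40),
                    mu_tumor = rep(300, 40), seed = 5)
  dm <- design_matrix(d$design)
  sf <- rep(1, 24)
  O1 <- matrix(0, 40, 24, dimnames = dimnames(d$counts))
  O2 <- O1
  O2[, d$design$condition == 1] <- log(2)
  disp <- rep(0.05, 40)
  f1 <- fit_glm(d$counts, dm$X, O1, disp)
  f2 <- fit_glm(d$counts, dm$X, O2, disp)
  expect_equal(f2$beta[, 2], f1$beta[, 2] - log(2), tolerance = 1e-6)
  expect_equal(f2$beta[, 1], f1$beta[, 1], tolerance = 1e-6)
})

test_that("dispersion estimation recovers a known dispersion and floors at the bound", {
  set.seed(21)
  G <- 500; n <- 20
  mu <- rep(200, G)
  d <- nb_two_group(G, n, mu, mu, dispersion = 0.1, seed = 21)
  dm <- design_matrix(d$design)
  O <- matrix(0, G, 2 * n)
  disp <- estimate_dispersions(d$counts, dm$X, O)
  expect_gt(mean(disp$dispersion), 0.05)
  expect_lt(mean(disp$dispersion), 0.2)
  expect_true(all(disp$dispersion > 0))

  # Poisson counts: estimates collapse to the lower bound region
  pois <- matrix(rpois(200 * 10, 100), 200,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:10)))
  Xp <- matrix(1, 10, 1, dimnames = list(NULL, "intercept"))
  dp <- estimate_dispersions(pois, Xp, matrix(0, 200, 10))
  expect_true(all(dp$genewise >= 1e-8))
  expect_lt(median(dp$genewise), 1e-2)

  # constant counts equal to the fitted mean: MLE driven to the floor
  const <- matrix(50, 1, 8, dimnames = list("g", paste0("s", 1:8)))
  dc <- estimate_dispersions(const, matrix(1, 8, 1), matrix(0, 1, 8))
  expect_lt(dc$genewise[1], 1e-6)
})

test_that("Wald test follows the normal reference", {
  # z = 0 gives p = 1; z = 1.959964 gives p ~= 0.05
  expect_equal(2 * pnorm(-abs(1.959964)), 0.05, tolerance = 1e-6)
  d <- nb_two_group(30, 10, rep(100, 30), rep(100, 30), seed = 9)
  dm <- design_matrix(d$design)
  fit <- fit_glm(d$counts, dm$X, matrix(0, 30, 20), rep(0.05, 30))
  wt <- wald_test(fit)
  expect_equal(wt$pvalue, 2 * pnorm(-abs(wt$stat)), tolerance = 1e-12)
  expect_true(all(wt$pvalue > 0 & wt$pvalue <= 1))
  # direct formula: z = c'beta / se
  expect_equal(wt$stat, wt$estimate / wt$se)
})

test_that("shrinkage pulls weak estimates toward zero but spares strong ones", {
  # high information: shrunken lfc within 0.1 of the MLE
  G <- 60
  d <- nb_two_group(G, 60, rep(500, G), rep(2000, G), dispersion = 0.05,
                    seed = 31)
  res <- run_dge(d$counts, d$cn, d$design, "naive")
  expect_true(all(abs(res$lfc - res$lfc_mle) < 0.1))

  # low information, weak noisy signal: posterior mode closer to zero
  d2 <- nb_two_group(200, 3, rep(30, 200), rep(40, 200), dispersion = 0.4,
                     seed = 32)
  r2 <- run_dge(d2$counts, d2$cn, d2$design, "naive")
  shrunk <- abs(r2$lfc) <= abs(r2$lfc_mle) + 1e-8
  expect_gt(mean(shrunk, na.rm = TRUE), 0.95)
  expect_lt(mean(abs(r2$lfc), na.rm = TRUE), mean(abs(r2$lfc_mle), na.rm = TRUE))
})

test_that("aware mode with diploid CN reproduces naive mode exactly", {
  d <- nb_two_group(80, 8, runif(80, 20, 400), runif(80, 20, 400),
                    dispersion = 0.1, seed = 41)
  a <- run_dge(d$counts, d$cn, d$design, "aware")
  n <- run_dge(d$counts, d$cn, d$design, "naive")
  expect_equal(a$lfc, n$lfc, tolerance = 1e-10)
  expect_equal(a$se, n$se, tolerance = 1e-10)
  expect_equal(a$pvalue, n$pvalue, tolerance = 1e-10)
})

test_that("uniform tumor CN scaling shifts the aware MLE lfc by -log2(k)", {
  G <- 50
  d <- nb_two_group(G, 10, rep(200, G), rep(400, G), dispersion = 0.05,
                    seed = 51)
  cn2 <- d$cn
  cn4 <- d$cn
  cn4[, d$design$condition == 1] <- 4  # doubled tumor CN
  a2 <- run_dge(d$counts, cn2, d$design, "aware", shrink = FALSE)
  a4 <- run_dge(d$counts, cn4, d$design, "aware", shrink = FALSE)
  expect_equal(a4$lfc_mle, a2$lfc_mle - 1, tolerance = 1e-6)
})

test_that("run_dge is deterministic and flags degenerate genes", {
  d <- nb_two_group(30, 6, rep(50, 30), rep(60, 30), seed = 61)
  d$counts[3, ] <- 0
  r1 <- run_dge(d$counts, d$cn, d$design, "aware")
  r2 <- run_dge(d$counts, d$cn, d$design, "aware")
  expect_identical(r1, r2)
  expect_identical(r1$status[3], "zero")
  expect_true(is.na(r1$pvalue[3]))
})

test_that("naive mode agrees with DESeq2 on a shared fixture", {
  skip_if_not_installed("DESeq2")
  d <- nb_two_group(120, 10, runif(120, 30, 800),
                    runif(120, 30, 800) * sample(c(1, 4), 120, TRUE),
                    dispersion = 0.08, seed = 71)
  mine <- run_dge(d$counts, d$cn, d$design, "naive", shrink = FALSE)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    d$counts, data.frame(condition = factor(d$design$condition)), ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- DESeq2::results(dds)
  ok <- !is.na(ref$pvalue) & !is.na(mine$pvalue)
  expect_gt(cor(mine$lfc_mle[ok], ref$log2FoldChange[ok]), 0.999)
  expect_lt(median(abs(mine$lfc_mle[ok] - ref$log2FoldChange[ok])), 0.01)
  expect_gt(cor(log10(mine$pvalue[ok]), log10(ref$pvalue[ok])), 0.995)
})
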