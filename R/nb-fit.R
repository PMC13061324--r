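#' Negative-binomial log-likelihood
#'
#' Log-likelihood of counts under NB(mu, theta) with variance
#' `mu + theta * mu^2`, evaluated through log-gamma functions.
#'
#' @param y Vector of counts.
#' @param mu Vector of means (recycled against `y`).
#' @param theta Dispersion (scalar or vector).
#' @param include_constant Include the `-lgamma(y + 1)` data constant so the
#'   value is a proper log-density.
#' @return Sum of log-likelihood contributions.
#' @export
nb_loglik <- function(y, mu, theta, include_constant = TRUE) {
  r <- 1 / theta
  ll <- lgamma(y + r) - lgamma(r) + r * log(r / (r + mu)) +
    ifelse(y > 0, y * log(mu / (r + mu)), 0)
  if (include_constant) ll <- ll - lgamma(y + 1)
  sum(ll)
}

# Row-wise NB log-likelihood for a genes x samples matrix; r is the per-gene
# NB size (1/dispersion). Data-constant terms are dropped (they cancel in all
# comparisons over mu or theta at fixed theta-grid evaluation).
.nb_ll_rows <- function(Y, MU, r, include_lgamma = TRUE) {
  ll <- r * log(r / (r + MU)) + Y * log(MU / (r + MU))
  ll[Y == 0 & MU == 0] <- 0
  out <- rowSums(ll)
  if (include_lgamma) out <- out + rowSums(lgamma(Y + r) - lgamma(r))
  out
}

#' Median-of-ratios size factors
#'
#' Sequencing-depth normalization factors: each sample's median ratio of its
#' counts to the per-gene geometric mean, computed over a reference set of
#' genes with positive counts in every sample.
#'
#' @param counts Count matrix (genes x samples).
#' @param pseudo_count Optional positive constant added to every count before
#'   estimation; fallback for datasets where no gene is positive everywhere.
#' @return Named vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(counts, pseudo_count = NULL) {
  m <- counts
  if (!is.null(pseudo_count)) {
    stopifnot(pseudo_count > 0)
    m <- m + pseudo_count
  }
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    stop("no gene has positive counts in every sample; ",
         "re-run with pseudo_count (e.g. 0.5) to use a pseudo-reference")
  }
  lm_ <- log(m[ref, , drop = FALSE])
  lg <- rowMeans(lm_)
  s <- exp(apply(lm_ - lg, 2, stats::median))
  names(s) <- colnames(counts)
  s
}

#' Build the offset matrix for a fit mode
#'
#' The model mean is `mu = s_n * (CN/2) * exp(X beta)`; the known factor
#' `s_n * CN/2` enters the log-link GLM as an offset. In naive mode the CN
#' term is dropped (equivalent to CN = 2 everywhere). CN values below
#' `cn_floor` are floored so homozygous deletions do not produce a -Inf
#' offset.
#'
#' @param size_factors Positive per-sample size factors.
#' @param cn Copy-number matrix aligned to the counts (also supplies the
#'   dimensions and dimnames in naive mode).
#' @param mode `"aware"` (CN dosage offsets) or `"naive"` (size factors only).
#' @param cn_floor Lower bound applied to CN before forming CN/2.
#' @return Matrix of natural-log offsets, genes x samples.
#' @export
build_offsets <- function(size_factors, cn, mode = c("aware", "naive"), cn_floor = 0.1) {
  mode <- match.arg(mode)
  stopifnot(all(size_factors > 0), length(size_factors) == ncol(cn))
  O <- matrix(log(size_factors), nrow(cn), ncol(cn), byrow = TRUE,
              dimnames = dimnames(cn))
  if (mode == "aware") O <- O + log(pmax(cn, cn_floor) / 2)
  O
}

# Vectorized golden-section maximization of a per-gene unimodal function of a
# scalar (here: log-dispersion). f maps a length-G vector of points to a
# length-G vector of objective values; all genes share the bracket [lo, hi].
.golden_max <- function(f, G, lo, hi, iters = 40L) {
  gr <- (sqrt(5) - 1) / 2
  a <- rep(lo, G); b <- rep(hi, G)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(iters)) {
    left <- f1 >= f2
    b[left] <- x2[left]; x2[left] <- x1[left]; f2[left] <- f1[left]
    x1[left] <- b[left] - gr * (b[left] - a[left])
    a[!left] <- x1[!left]; x1[!left] <- x2[!left]; f1[!left] <- f2[!left]
    x2[!left] <- a[!left] + gr * (b[!left] - a[!left])
    xnew <- ifelse(left, x1, x2)
    fnew <- f(xnew)
    f1[left] <- fnew[left]; f2[!left] <- fnew[!left]
  }
  (a + b) / 2
}

.as_model_matrix <- function(design) {
  if (is.matrix(design)) {
    list(X = design, contrast = as.numeric(colnames(design) == "condition"))
  } else {
    design_matrix(design)
  }
}

# Iteratively reweighted least squares for per-gene NB GLMs with log link and
# fixed log-offsets, vectorized across genes. For the common intercept +
# condition design the 2x2 normal equations are solved in closed form; larger
# designs fall back to a per-gene solve.
.irls_nb <- function(Y, X, O, alpha, tol = 1e-8, maxit = 100L, ridge = 1e-6,
                     beta_init = NULL) {
  G <- nrow(Y); f <- ncol(X)
  Xcross <- X[, rep(seq_len(f), each = f), drop = FALSE] *
            X[, rep(seq_len(f), times = f), drop = FALSE]  # N x f^2
  if (is.null(beta_init)) {
    Z0 <- log(Y + 0.5) - O
    beta <- t(solve(crossprod(X) + diag(ridge, f), t(Z0 %*% X)))
  } else {
    beta <- beta_init
  }
  maxdelta <- rep(Inf, G)
  iters <- 0L
  for (it in seq_len(maxit)) {
    iters <- it
    eta <- pmin(pmax(tcrossprod(beta, X) + O, -30), 30)
    mu <- exp(eta)
    W <- mu / (1 + alpha * mu)
    A <- W %*% Xcross                       # G x f^2, row-major (j, k) blocks
    B <- (W * (eta - O) + (Y - mu) / (1 + alpha * mu)) %*% X  # G x f (W * working response)
    if (f == 2L) {
      a11 <- A[, 1L] + ridge; a12 <- A[, 2L]; a22 <- A[, 4L] + ridge
      det <- a11 * a22 - a12 * a12
      bn <- cbind((a22 * B[, 1L] - a12 * B[, 2L]) / det,
                  (a11 * B[, 2L] - a12 * B[, 1L]) / det)
    } else {
      bn <- beta
      for (g in seq_len(G)) {
        Ag <- matrix(A[g, ], f, f) + diag(ridge, f)
        bn[g, ] <- solve(Ag, B[g, ])
      }
    }
    bn <- pmin(pmax(bn, -30), 30)
    maxdelta <- apply(abs(bn - beta), 1, max)
    beta <- bn
    if (max(maxdelta) < tol) break
  }
  eta <- pmin(pmax(tcrossprod(beta, X) + O, -30), 30)
  mu <- exp(eta)
  W <- mu / (1 + alpha * mu)
  A <- W %*% Xcross
  list(beta = beta, mu = mu, info = A, converged = maxdelta < tol,
       iter = iters, X = X)
}

# Standard error of a contrast c'beta from the per-gene Fisher information
# blocks stored as G x f^2 rows.
.se_contrast <- function(info, contrast) {
  f <- length(contrast)
  G <- nrow(info)
  if (f == 2L) {
    det <- info[, 1L] * info[, 4L] - info[, 2L]^2
    v <- (contrast[1]^2 * info[, 4L] - 2 * contrast[1] * contrast[2] * info[, 2L] +
          contrast[2]^2 * info[, 1L]) / det
  } else {
    v <- numeric(G)
    for (g in seq_len(G)) {
      Ag <- matrix(info[g, ], f, f)
      v[g] <- tryCatch(drop(t(contrast) %*% solve(Ag, contrast)),
                       error = function(e) NA_real_)
    }
  }
  v[!is.na(v) & v < 0] <- NA_real_
  sqrt(v)
}

#' Empirical-Bayes dispersion estimation
#'
#' Three-stage estimator in the DESeq2 tradition: (i) per-gene maximum
#' likelihood of the dispersion given fitted means from a preliminary GLM
#' fit; (ii) a parametric mean-dispersion trend `a0 + a1 / mu` fitted by a
#' gamma GLM with iterative outlier exclusion; (iii) maximum a posteriori
#' shrinkage of the log-dispersion toward the trend, with the prior variance
#' estimated from the residual spread of the gene-wise estimates around the
#' trend. Genes whose gene-wise estimate sits far above the trend (more than
#' two residual SDs) keep their gene-wise value (dispersion outliers).
#'
#' @param counts Count matrix (genes x samples).
#' @param design Design `data.frame` or model matrix.
#' @param offsets Log-offset matrix from [build_offsets()].
#' @param min_disp,max_disp Bounds of the dispersion search (defaults 1e-8, 30).
#' @param trend_min_disp Gene-wise estimates at or below this value are
#'   excluded from the trend fit.
#' @return List with `dispersion` (final per-gene values), `genewise`,
#'   `trend`, `map`, `trend_coef` (a0, a1), `prior_var`, `base_mean`,
#'   `outlier`, `zero` (all-zero gene flags).
#' @export
estimate_dispersions <- function(counts, design, offsets, min_disp = 1e-8,
                                 max_disp = 30, trend_min_disp = 1e-6) {
  dm <- .as_model_matrix(design)
  X <- dm$X
  Y <- counts
  G <- nrow(Y); N <- ncol(Y); f <- ncol(X)
  stopifnot(N >= 2L)
  zero <- rowSums(Y) == 0
  K <- Y / exp(offsets)
  base_mean <- rowMeans(K)
  v <- apply(K, 1, stats::var)
  a_init <- pmin(pmax((v - base_mean) / base_mean^2, min_disp), max_disp)
  a_init[zero] <- 0.1
  fit0 <- .irls_nb(Y, X, offsets, a_init, tol = 1e-6, maxit = 50L)
  mu <- pmax(fit0$mu, 1e-10)
  obj_gw <- function(la) .nb_ll_rows(Y, mu, 1 / exp(la))
  genewise <- exp(.golden_max(obj_gw, G, log(min_disp), log(max_disp)))
  genewise[zero] <- NA_real_

  ok <- !zero & genewise > trend_min_disp & base_mean > 0
  trend_coef <- c(a0 = stats::median(genewise[!zero], na.rm = TRUE), a1 = 0)
  if (sum(ok) >= 10) {
    d <- genewise[ok]; m <- base_mean[ok]
    use <- rep(TRUE, length(d))
    for (it in 1:10) {
      fitg <- tryCatch(
        stats::glm(d[use] ~ I(1 / m[use]),
                   family = stats::Gamma(link = "identity"),
                   start = c(0.1, 1)),
        error = function(e) NULL)
      if (is.null(fitg)) break
      co <- stats::coef(fitg)
      if (any(!is.finite(co)) || co[1] <= 0) co[1] <- 1e-6
      if (co[2] < 0) co[2] <- 0
      trend_coef <- c(a0 = unname(co[1]), a1 = unname(co[2]))
      pred <- trend_coef[1] + trend_coef[2] / m
      ratio <- d / pred
      use_new <- ratio > 1e-4 & ratio < 15
      if (all(use_new == use)) break
      use <- use_new
    }
  }
  trend <- pmin(pmax(trend_coef[1] + trend_coef[2] / base_mean, min_disp), max_disp)

  lr <- log(genewise) - log(trend)
  s_lr <- stats::mad(lr[ok], na.rm = TRUE)
  exp_var <- trigamma(max((N - f) / 2, 0.5))
  prior_var <- max(s_lr^2 - exp_var, 0.25)

  lt <- log(trend)
  obj_map <- function(la) .nb_ll_rows(Y, mu, 1 / exp(la)) - (la - lt)^2 / (2 * prior_var)
  map <- exp(.golden_max(obj_map, G, log(min_disp), log(max_disp)))
  map[zero] <- NA_real_

  outlier <- !zero & !is.na(lr) & lr > 2 * max(s_lr, 0.01)
  dispersion <- map
  dispersion[outlier] <- genewise[outlier]
  list(dispersion = dispersion, genewise = genewise, trend = trend, map = map,
       trend_coef = trend_coef, prior_var = prior_var, base_mean = base_mean,
       outlier = outlier, zero = zero)
}

#' Fit per-gene NB GLMs by maximum likelihood
#'
#' IRLS with log link and fixed log-offsets, one GLM per gene with a shared
#' design. Coefficients are on the natural-log scale; the reported
#' `lfc_mle` is the contrast coefficient divided by `ln 2`.
#'
#' @param counts Count matrix.
#' @param design Design `data.frame` or model matrix.
#' @param offsets Log-offset matrix.
#' @param dispersions Per-gene dispersion vector (e.g.
#'   `estimate_dispersions(...)$dispersion`).
#' @param tol,maxit,ridge IRLS controls: coefficient convergence tolerance,
#'   iteration cap, ridge stabilizer added to the normal equations.
#' @return An object of class `"nb_fit"`: list with `beta` (G x f, natural
#'   log), `mu`, `info` (Fisher information blocks), `converged`,
#'   `dispersion`, `base_mean`, `X`, `contrast`, `offsets`, `counts`.
#' @export
fit_glm <- function(counts, design, offsets, dispersions, tol = 1e-8,
                    maxit = 100L, ridge = 1e-6) {
  dm <- .as_model_matrix(design)
  X <- dm$X
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full rank")
  alpha <- pmax(dispersions, 1e-8)
  alpha[is.na(alpha)] <- 0.1
  fit <- .irls_nb(counts, X, offsets, alpha, tol = tol, maxit = maxit, ridge = ridge)
  structure(list(beta = fit$beta, mu = fit$mu, info = fit$info,
                 converged = fit$converged, dispersion = dispersions,
                 base_mean = rowMeans(counts / exp(offsets)),
                 X = X, contrast = dm$contrast, offsets = offsets,
                 counts = counts, iter = fit$iter),
            class = "nb_fit")
}

#' Wald test for a coefficient contrast
#'
#' `z = c'beta / se(c'beta)` with the standard error from the observed Fisher
#' information of the maximum-likelihood fit; two-sided p-value from the
#' standard normal.
#'
#' @param fit `"nb_fit"` object from [fit_glm()].
#' @param contrast Numeric contrast vector of length `ncol(X)`; defaults to
#'   the fit's condition contrast.
#' @param beta Optional coefficient matrix overriding the fit's MLE (used for
#'   Wald-on-MAP mode).
#' @return `data.frame` with `estimate` (natural log), `se`, `stat`, `pvalue`.
#' @export
wald_test <- function(fit, contrast = NULL, beta = NULL) {
  if (is.null(contrast)) contrast <- fit$contrast
  stopifnot(length(contrast) == ncol(fit$X))
  if (is.null(beta)) beta <- fit$beta
  est <- drop(beta %*% contrast)
  se <- .se_contrast(fit$info, contrast)
  bad <- is.na(se) | se == 0
  z <- ifelse(bad, NA_real_, est / se)
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1]
  data.frame(estimate = est, se = se, stat = z, pvalue = p)
}
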