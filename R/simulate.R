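#' Simulation configuration
#'
#' Parameters of the synthetic tumor-vs-normal RNA-seq generator. Baseline
#' means are log-normal; dispersions follow the trend `a0 + a1 / mu` with
#' log-normal jitter, giving the decreasing mean-dispersion relationship
#' typical of bulk RNA-seq. Class proportions must sum to 1.
#'
#' @param n_genes Number of genes.
#' @param n_per_condition Samples per condition (normal and tumor).
#' @param class_proportions Named fractions for DSG, DIG, DCG, nonDEG.
#' @param cn_signal `"strong"`: altered genes carry tumor CN 4 or 5 (gains)
#'   or 1 (losses) in every tumor sample; `"weak"`: CN 3 (or 1) in 60% of
#'   tumor samples.
#' @param lfc_range Range of absolute biological log2 effects for DIGs.
#' @param mean_log_mu,sd_log_mu Natural-log mean and sd of baseline means.
#' @param dispersion_a0,dispersion_a1 Dispersion trend parameters.
#' @param dispersion_jitter_sd Log-normal jitter sd around the trend.
#' @param gain_fraction Fraction of CN-altered genes that are gains (the
#'   remainder are losses).
#' @param weak_altered_fraction Fraction of tumor samples carrying the
#'   alteration under weak CN signal.
#' @param buffering Residual dosage exponent for DCGs: tumor mean is
#'   `mu0 * (CN/2)^buffering`; 0 = full compensation (default).
#' @param seed Integer seed driving all randomness.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 5000, n_per_condition = 20,
                       class_proportions = c(DSG = 0.10, DIG = 0.40,
                                             DCG = 0, nonDEG = 0.50),
                       cn_signal = c("strong", "weak"),
                       lfc_range = c(1.2, 3.0),
                       mean_log_mu = 5, sd_log_mu = 1.5,
                       dispersion_a0 = 0.05, dispersion_a1 = 5,
                       dispersion_jitter_sd = 0.3,
                       gain_fraction = 0.8, weak_altered_fraction = 0.6,
                       buffering = 0, seed = NULL) {
  cn_signal <- match.arg(cn_signal)
  stopifnot(n_genes > 0, n_per_condition >= 2,
            length(lfc_range) == 2, lfc_range[1] <= lfc_range[2],
            gain_fraction >= 0, gain_fraction <= 1,
            buffering >= 0, buffering <= 1)
  cp <- class_proportions[c("DSG", "DIG", "DCG", "nonDEG")]
  if (anyNA(cp)) stop("class_proportions must name DSG, DIG, DCG, nonDEG")
  if (abs(sum(cp) - 1) > 1e-9) stop("class proportions must sum to 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_condition = as.integer(n_per_condition),
                 class_proportions = cp, cn_signal = cn_signal,
                 lfc_range = lfc_range, mean_log_mu = mean_log_mu,
                 sd_log_mu = sd_log_mu, dispersion_a0 = dispersion_a0,
                 dispersion_a1 = dispersion_a1,
                 dispersion_jitter_sd = dispersion_jitter_sd,
                 gain_fraction = gain_fraction,
                 weak_altered_fraction = weak_altered_fraction,
                 buffering = buffering, seed = seed),
            class = "sim_config")
}

# Largest-remainder apportionment of G genes to the class proportions.
.class_counts <- function(proportions, G) {
  raw <- proportions * G
  counts <- floor(raw)
  rem <- G - sum(counts)
  if (rem > 0) {
    frac <- raw - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}

#' Simulate a matched counts / copy-number / design dataset
#'
#' Generates NB counts for `n` normal and `n` tumor samples with per-gene
#' ground truth. Class mechanisms: non-DE genes keep the baseline mean and
#' diploid CN; DIGs change their tumor mean by a biological factor `2^beta`
#' at diploid CN; DSGs keep `beta = 0` but their tumor mean scales with the
#' altered CN as `mu0 * CN/2`; DCGs carry the same CN alterations while
#' their tumor mean stays buffered at `mu0 * (CN/2)^buffering`, so the
#' CN-aware model attributes `-(1 - buffering) * log2(CN/2)` of regulation
#' to them. Normal samples are diploid (CN = 2) throughout.
#'
#' @param config A [sim_config()] object.
#' @return List of class `"simulated_dataset"`: `counts`, `cn`, `design`,
#'   `truth` (`gene_id`, `class`, `true_lfc`, `tumor_cn`, `frac_altered`,
#'   `mu0`, `dispersion`), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  G <- config$n_genes
  n <- config$n_per_condition
  N <- 2L * n

  counts_per_class <- .class_counts(config$class_proportions, G)
  classes <- sample(rep(names(counts_per_class), counts_per_class))

  mu0 <- stats::rlnorm(G, config$mean_log_mu, config$sd_log_mu)
  disp <- (config$dispersion_a0 + config$dispersion_a1 / mu0) *
    exp(stats::rnorm(G, 0, config$dispersion_jitter_sd))

  gene_id <- sprintf("gene_%05d", seq_len(G))
  sample_id <- c(sprintf("normal_%02d", seq_len(n)),
                 sprintf("tumor_%02d", seq_len(n)))
  tumor_cols <- (n + 1L):N

  cn <- matrix(2, G, N, dimnames = list(gene_id, sample_id))
  altered <- classes %in% c("DSG", "DCG")
  is_gain <- rep(FALSE, G)
  is_gain[altered] <- stats::runif(sum(altered)) < config$gain_fraction
  tumor_cn <- rep(2, G)
  frac_altered <- rep(0, G)
  if (any(altered)) {
    if (config$cn_signal == "strong") {
      tumor_cn[altered & is_gain] <- sample(c(4, 5), sum(altered & is_gain),
                                            replace = TRUE)
      tumor_cn[altered & !is_gain] <- 1
      cn[altered, tumor_cols] <- tumor_cn[altered]
      frac_altered[altered] <- 1
    } else {
      tumor_cn[altered & is_gain] <- 3
      tumor_cn[altered & !is_gain] <- 1
      frac_altered[altered] <- config$weak_altered_fraction
      for (g in which(altered)) {
        carriers <- stats::runif(n) < config$weak_altered_fraction
        cn[g, tumor_cols[carriers]] <- tumor_cn[g]
      }
    }
  }

  beta <- rep(0, G)
  dig <- classes == "DIG"
  if (any(dig)) {
    mag <- stats::runif(sum(dig), config$lfc_range[1], config$lfc_range[2])
    beta[dig] <- mag * sample(c(-1, 1), sum(dig), replace = TRUE)
  }

  # Per-sample tumor means by class mechanism
  MU <- matrix(mu0, G, N)
  dosage <- cn[, tumor_cols, drop = FALSE] / 2
  tum <- matrix(mu0, G, n)
  tum[dig, ] <- tum[dig, , drop = FALSE] * 2^beta[dig]
  dsg <- classes == "DSG"
  tum[dsg, ] <- tum[dsg, , drop = FALSE] * dosage[dsg, , drop = FALSE]
  dcg <- classes == "DCG"
  if (any(dcg)) {
    tum[dcg, ] <- tum[dcg, , drop = FALSE] *
      dosage[dcg, , drop = FALSE]^config$buffering
  }
  MU[, tumor_cols] <- tum

  counts <- matrix(stats::rnbinom(G * N, mu = MU, size = 1 / disp), G, N,
                   dimnames = list(gene_id, sample_id))

  # Biological (CN-adjusted) log2 effect: what the CN-aware model estimates.
  true_lfc <- beta
  if (any(dcg)) {
    true_lfc[dcg] <- -(1 - config$buffering) * frac_altered[dcg] *
      log2(tumor_cn[dcg] / 2)
  }

  design <- data.frame(sample_id = sample_id,
                       condition = rep(c(0L, 1L), each = n),
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gene_id,
                      class = factor(classes, levels = c("DSG", "DIG", "DCG", "nonDEG")),
                      true_lfc = true_lfc, tumor_cn = tumor_cn,
                      frac_altered = frac_altered, mu0 = mu0,
                      dispersion = disp, stringsAsFactors = FALSE)
  structure(list(counts = counts, cn = cn, design = design, truth = truth,
                 config = config),
            class = "simulated_dataset")
}

#' Inject discrete noise into a copy-number matrix
#'
#' Perturbs exactly `round(fraction * length(cn))` uniformly chosen entries
#' with additive discrete noise drawn from
#' \{-2, -1, 0, +1, +2\} with weights \{5, 30, 30, 30, 5\}%, mimicking
#' CN-caller errors where moderate deviations dominate. Results are floored
#' at 0.
#'
#' @param cn Copy-number matrix.
#' @param fraction Fraction of entries to perturb, in \[0, 1\].
#' @param seed Optional seed.
#' @return Perturbed matrix of the same shape.
#' @export
inject_cn_noise <- function(cn, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- round(fraction * length(cn))
  if (k == 0) return(cn)
  idx <- sample.int(length(cn), k)
  noise <- sample(c(-2, -1, 0, 1, 2), k, replace = TRUE,
                  prob = c(0.05, 0.30, 0.30, 0.30, 0.05))
  cn[idx] <- pmax(cn[idx] + noise, 0)
  cn
}

#' Configuration grid over sample sizes and replicates
#'
#' Derives one [sim_config()] per (sample size, replicate) cell with a
#' distinct seed drawn deterministically from the master seed, so datasets
#' can be generated lazily and reproducibly with [simulate_dataset()].
#'
#' @param config Base [sim_config()]; its `seed` is the master seed.
#' @param sample_sizes Vector of per-condition sample sizes.
#' @param n_replicates Replicates per sample size.
#' @return `data.frame` with columns `sample_size`, `replicate`, `seed`, and
#'   a list-column `config`.
#' @export
replicate_grid <- function(config, sample_sizes, n_replicates) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  master <- if (is.null(config$seed)) 1L else config$seed
  set.seed(master)
  cells <- expand.grid(replicate = seq_len(n_replicates),
                       sample_size = sample_sizes)[, 2:1]
  seeds <- sample.int(.Machine$integer.max, nrow(cells))
  cells$seed <- seeds
  cells$config <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- config
    cfg$n_per_condition <- as.integer(cells$sample_size[i])
    cfg$seed <- cells$seed[i]
    cfg
  })
  cells
}
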