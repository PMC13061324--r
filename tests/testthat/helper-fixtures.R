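# Small fixture builders shared across test files.

# A tiny counts matrix with named dims.
tiny_counts <- function(values, genes = NULL, samples = NULL) {
  nr <- if (!is.null(genes)) length(genes)
        else if (!is.null(samples)) length(values) / length(samples)
        else length(values) / 2
  m <- matrix(values, nrow = nr)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# Balanced two-group design: first n normal, next n tumor.
two_group_design <- function(n_normal, n_tumor = n_normal,
                             samples = NULL) {
  ids <- if (is.null(samples)) {
    c(paste0("n", seq_len(n_normal)), paste0("t", seq_len(n_tumor)))
  } else samples
  data.frame(sample_id = ids,
             condition = rep(c(0L, 1L), c(n_normal, n_tumor)),
             stringsAsFactors = FALSE)
}

# NB dataset with known per-gene means in each group and common dispersion;
# diploid CN unless a cn matrix is supplied.
nb_two_group <- function(n_genes, n_per_group, mu_normal, mu_tumor,
                         dispersion = 0.05, seed = 1, cn = NULL) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  design <- two_group_design(n_per_group)
  mu <- cbind(matrix(rep(mu_normal, n_per_group), n_genes),
              matrix(rep(mu_tumor, n_per_group), n_genes))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, dimnames = list(genes, design$sample_id))
  if (is.null(cn)) {
    cn <- matrix(2, n_genes, 2 * n_per_group,
                 dimnames = dimnames(counts))
  }
  list(counts = counts, cn = cn, design = design)
}

# Brute-force Benjamini-Hochberg step-up: reject the i smallest p-values
# where i is the largest index with p_(i) <= i * alpha / m.
bh_bruteforce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * alpha / m)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

# Brute-force Holm over k hypotheses at level t.
holm_bruteforce <- function(p, t) {
  k <- length(p)
  o <- order(p)
  rej <- logical(k)
  for (i in seq_len(k)) {
    if (p[o[i]] <= t / (k - i + 1)) rej[o[i]] <- TRUE else break
  }
  rej
}
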