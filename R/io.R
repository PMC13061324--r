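#' Read a counts or copy-number matrix from delimited text
#'
#' Reads a gene x sample matrix from TSV or CSV (delimiter auto-detected from
#' the file extension; `.csv` is comma, anything else tab). The first column
#' must hold gene identifiers and the header row sample identifiers. Counts
#' are validated as non-negative integers; copy numbers as non-negative reals
#' (segmented absolute CN may be fractional).
#'
#' @param path Path to a delimited text file.
#' @param kind `"counts"` for raw read counts, `"cn"` for absolute copy
#'   numbers.
#' @param genes_in_rows If `FALSE`, the file is transposed after reading
#'   (samples in rows).
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("counts", "cn"), genes_in_rows = TRUE) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("matrix file needs an id column plus >=1 data column: ", path)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad)) {
      stop(sprintf("non-numeric entry at gene '%s', sample '%s' in %s",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path))
    }
    stop("non-numeric matrix in ", path)
  }
  if (kind == "counts") validate_counts(m) else validate_cn(m)
}

#' Validate a raw count matrix
#'
#' Checks the count-matrix invariants: unique non-empty gene and sample ids,
#' all entries finite, non-negative and integral (within 1e-8, then coerced).
#'
#' @param m Numeric matrix, genes in rows.
#' @return The validated matrix (integral values, storage mode double).
#' @export
validate_counts <- function(m) {
  .check_ids(m)
  if (anyNA(m) || any(!is.finite(m))) stop("counts contain missing or non-finite values")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(abs(m - round(m)) > 1e-8)) stop("counts must be integral read counts")
  m[] <- round(m)
  m
}

#' Validate a copy-number matrix
#'
#' Checks non-negativity and id uniqueness. When `normal_samples` is given,
#' entries for those samples must equal the diploid reference CN = 2.
#'
#' @param m Numeric matrix of absolute copy numbers, genes in rows.
#' @param normal_samples Optional character vector of normal sample ids.
#' @return The validated matrix.
#' @export
validate_cn <- function(m, normal_samples = NULL) {
  .check_ids(m)
  if (anyNA(m) || any(!is.finite(m))) stop("CN matrix contains missing or non-finite values")
  if (any(m < 0)) stop("CN values must be non-negative")
  if (!is.null(normal_samples)) {
    normal_samples <- intersect(normal_samples, colnames(m))
    if (length(normal_samples) && any(m[, normal_samples] != 2)) {
      stop("normal diploid samples must have CN = 2 everywhere; ",
           "use align_inputs(fix_normal_cn = TRUE) to assign it")
    }
  }
  m
}

.check_ids <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) stop("matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene id: ", rownames(m)[duplicated(rownames(m))][1])
  if (anyDuplicated(colnames(m))) stop("duplicate sample id: ", colnames(m)[duplicated(colnames(m))][1])
  if (!nrow(m) || !ncol(m)) stop("matrix is empty")
  invisible(m)
}

#' Read a design table
#'
#' The design CSV/TSV must contain columns `sample_id` and `condition`
#' (0 = normal, 1 = tumor); any further numeric columns are treated as
#' covariates.
#'
#' @param path Path to a delimited file.
#' @return A validated design `data.frame`.
#' @export
read_design <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  validate_design(d)
}

#' Validate a design table
#'
#' @param design `data.frame` with columns `sample_id`, `condition` and
#'   optional numeric covariates.
#' @return The design with `condition` coerced to integer 0/1.
#' @export
validate_design <- function(design) {
  if (!all(c("sample_id", "condition") %in% names(design)))
    stop("design needs columns 'sample_id' and 'condition'")
  design$sample_id <- as.character(design$sample_id)
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (!all(design$condition %in% c(0, 1))) stop("condition must be 0 (normal) or 1 (tumor)")
  design$condition <- as.integer(design$condition)
  if (!any(design$condition == 0) || !any(design$condition == 1))
    stop("design needs at least one sample per condition")
  extra <- setdiff(names(design), c("sample_id", "condition"))
  for (v in extra) if (!is.numeric(design[[v]])) stop("covariate '", v, "' must be numeric")
  design
}

#' Build the model matrix for a design table
#'
#' Intercept, condition indicator, then covariates, in that order. The
#' default contrast selects the condition coefficient.
#'
#' @param design Validated design `data.frame`.
#' @return List with `X` (n x f model matrix) and `contrast` (length-f
#'   vector selecting the condition coefficient).
#' @export
design_matrix <- function(design) {
  design <- validate_design(design)
  extra <- setdiff(names(design), c("sample_id", "condition"))
  X <- cbind(intercept = 1, condition = design$condition)
  if (length(extra)) X <- cbind(X, as.matrix(design[, extra, drop = FALSE]))
  rownames(X) <- design$sample_id
  contrast <- as.numeric(colnames(X) == "condition")
  list(X = X, contrast = contrast)
}

#' Align counts, copy numbers and design to shared genes and samples
#'
#' Restricts all three inputs to the intersection of gene and sample ids and
#' puts them in a single consistent order (gene order of `counts`, sample
#' order of `design`). Dropped ids are reported in the return value.
#'
#' Normal samples present in counts/design but absent from the CN matrix are
#' filled in with the diploid reference CN = 2 when `fix_normal_cn = TRUE`
#' (CN callers usually emit tumor profiles only); with the same flag, normal
#' columns present but deviating from 2 are overwritten with 2.
#'
#' @param counts Count matrix (genes x samples).
#' @param cn Copy-number matrix (genes x samples).
#' @param design Design `data.frame`.
#' @param fix_normal_cn Assign CN = 2 to normal samples (default `TRUE`).
#' @return List with elements `counts`, `cn`, `design`, and `dropped`
#'   (list of dropped gene/sample ids per input).
#' @export
align_inputs <- function(counts, cn, design, fix_normal_cn = TRUE) {
  design <- validate_design(design)
  normal_ids <- design$sample_id[design$condition == 0]
  if (fix_normal_cn) {
    missing_normals <- setdiff(intersect(normal_ids, colnames(counts)), colnames(cn))
    if (length(missing_normals)) {
      fill <- matrix(2, nrow(cn), length(missing_normals),
                     dimnames = list(rownames(cn), missing_normals))
      cn <- cbind(cn, fill)
    }
    present_normals <- intersect(normal_ids, colnames(cn))
    if (length(present_normals)) cn[, present_normals] <- 2
  }
  genes <- intersect(rownames(counts), rownames(cn))
  samples <- Reduce(intersect, list(design$sample_id, colnames(counts), colnames(cn)))
  if (!length(genes) || !length(samples))
    stop("no shared genes or samples between counts, CN and design")
  dropped <- list(
    genes_counts  = setdiff(rownames(counts), genes),
    genes_cn      = setdiff(rownames(cn), genes),
    samples_counts = setdiff(colnames(counts), samples),
    samples_cn     = setdiff(colnames(cn), samples),
    samples_design = setdiff(design$sample_id, samples)
  )
  if (length(dropped$samples_design))
    warning("design samples absent from the matrices were dropped: ",
            paste(dropped$samples_design, collapse = ", "))
  design <- design[design$sample_id %in% samples, , drop = FALSE]
  samples <- design$sample_id
  list(counts = counts[genes, samples, drop = FALSE],
       cn     = validate_cn(cn[genes, samples, drop = FALSE],
                            normal_samples = design$sample_id[design$condition == 0]),
       design = design,
       dropped = dropped)
}

#' Remove genes with low expression in reference samples
#'
#' Drops genes whose mean raw count across the reference samples (by default
#' the normal samples) is strictly below `min_mean`. Low counts in normal
#' tissue carry little information for tumor-vs-normal contrasts and inflate
#' dispersion estimates.
#'
#' @param counts Count matrix.
#' @param design Design `data.frame` aligned to `counts`.
#' @param min_mean Strict lower bound on the mean reference count (default 10).
#' @param samples Which samples define the filter mean: `"normal"`,
#'   `"tumor"`, or `"all"`.
#' @return List with `counts` (filtered matrix) and `removed` (dropped gene ids).
#' @export
filter_low_expression <- function(counts, design, min_mean = 10,
                                  samples = c("normal", "all", "tumor")) {
  samples <- match.arg(samples)
  design <- validate_design(design)
  ids <- switch(samples,
    normal = design$sample_id[design$condition == 0],
    tumor  = design$sample_id[design$condition == 1],
    all    = design$sample_id)
  ids <- intersect(ids, colnames(counts))
  if (!length(ids)) stop("no ", samples, " samples available; filter undefined")
  keep <- rowMeans(counts[, ids, drop = FALSE]) >= min_mean
  list(counts = counts[keep, , drop = FALSE], removed = rownames(counts)[!keep])
}

#' Annotate per-gene copy-number state in tumor samples
#'
#' Bins each gene by its mean tumor CN: neutral (mean > 1.7 and <= 2.5),
#' gain (> 2.5 and <= 3.5), amplification (> 3.5); means <= 1.7 also fall in
#' the loss bin. Genes with CN 0 or 1 in at least `loss_fraction` of tumor
#' samples are labelled loss regardless of their mean (frequently deleted
#' genes can keep a near-diploid mean).
#'
#' @param cn Copy-number matrix.
#' @param design Optional design; when given, only tumor columns are used.
#' @param loss_fraction Minimum fraction of tumor samples with CN <= 1 for
#'   the loss call (default 0.25).
#' @return Factor of per-gene states with levels loss/neutral/gain/amplification.
#' @export
annotate_cn_state <- function(cn, design = NULL, loss_fraction = 0.25) {
  if (!is.null(design)) {
    design <- validate_design(design)
    tumor <- intersect(design$sample_id[design$condition == 1], colnames(cn))
    if (!length(tumor)) stop("no tumor samples in CN matrix")
    cn <- cn[, tumor, drop = FALSE]
  }
  mu <- rowMeans(cn)
  state <- ifelse(mu > 3.5, "amplification",
           ifelse(mu > 2.5, "gain",
           ifelse(mu > 1.7, "neutral", "loss")))
  frac_low <- rowMeans(cn <= 1)
  state[frac_low >= loss_fraction] <- "loss"
  factor(state, levels = c("loss", "neutral", "gain", "amplification"))
}

.results_cols <- c("gene_id", "base_mean", "lfc_naive", "lfc_aware",
                   "p_naive", "p_aware", "p_simes", "padj_screen",
                   "de_naive", "de_aware", "dosage_class", "cn_state")

#' Write a per-gene results table
#'
#' Writes TSV with a fixed column order; numeric columns keep full double
#' precision so a round-trip read reproduces values exactly.
#'
#' @param table Results `data.frame` (see [read_results()] for the columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  cols <- intersect(.results_cols, names(table))
  table <- cbind(table[cols], table[setdiff(names(table), cols)])
  data.table::fwrite(table, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_results <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
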