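#' Counts per million
#'
#' Library-size-scaled expression, optionally using effective library
#' sizes (library size times TMM normalization factor).
#'
#' @param counts Nonnegative integer matrix, genes in rows, samples in
#'   columns.
#' @param norm_factors Optional per-sample normalization factors
#'   (e.g. from [tmm_factors()]). Defaults to 1 for every sample.
#' @param lib_sizes Optional per-sample library sizes; defaults to
#'   column sums.
#' @return Matrix of CPM values with the dimensions of `counts`.
#' @export
cpm <- function(counts, norm_factors = NULL, lib_sizes = NULL) {
  counts <- check_count_matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  eff <- lib_sizes * norm_factors
  if (any(eff <= 0)) stop("effective library sizes must be positive")
  sweep(counts, 2, eff, "/") * 1e6
}

#' Log2 counts per million
#'
#' @inheritParams cpm
#' @param prior Pseudo-count added on the CPM scale before taking logs.
#' @return Matrix of log2(CPM + prior) values.
#' @export
log_cpm <- function(counts, norm_factors = NULL, lib_sizes = NULL,
                    prior = 0.5) {
  log2(cpm(counts, norm_factors, lib_sizes) + prior)
}

#' Filter weakly expressed genes
#'
#' Keeps genes with CPM above `min_cpm` in at least `min_samples`
#' samples. Fold changes and exact-test p-values are unstable for genes
#' expressed in almost no library, so the pipeline drops them before
#' testing.
#'
#' @inheritParams cpm
#' @param min_cpm CPM threshold a sample must exceed to count.
#' @param min_samples Number of samples that must exceed `min_cpm`.
#' @return The row-subset count matrix.
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_samples = 2) {
  counts <- check_count_matrix(counts)
  keep <- rowSums(cpm(counts) > min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

# Validates gene x sample count input: nonnegative, integral, unique ids.
check_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (genes x samples)")
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be nonnegative and non-missing")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integral")
  if (!is.null(rownames(counts)) && anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in counts")
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in counts")
  counts
}

# Upper-quartile expression per library, used to pick the TMM reference.
quartile_depth <- function(counts, lib_sizes, p = 0.75) {
  apply(counts, 2, function(x) stats::quantile(x, p = p, names = FALSE)) /
    lib_sizes
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization for count
#' data. For each sample a weighted mean of gene-wise log2 expression
#' ratios (M-values) against a reference sample is computed after
#' trimming the most extreme 30% of M-values on each side and the most
#' extreme 5% of average log expression (A-values) on each side;
#' weights are inverse asymptotic variances of the M-values. Genes with
#' a zero count in either member of a pair are excluded from that
#' pair's mean. Factors are rescaled so that their geometric mean is 1:
#' a factor below 1 means the library is dominated by a few
#' high-abundance genes and its effective size is shrunk.
#'
#' @inheritParams cpm
#' @param reference Reference sample: a column name/index, or `NULL`
#'   to pick the sample whose upper-quartile expression is closest to
#'   the mean upper quartile.
#' @param logratio_trim Two-sided trim fraction applied to M-values.
#' @param sum_trim Two-sided trim fraction applied to A-values.
#' @param do_weighting Use inverse asymptotic-variance weights (the
#'   standard choice) rather than an unweighted trimmed mean.
#' @return Named numeric vector of positive per-sample factors with
#'   geometric mean 1.
#' @seealso [cpm()] for applying the factors.
#' @export
tmm_factors <- function(counts, reference = NULL, logratio_trim = 0.30,
                        sum_trim = 0.05, do_weighting = TRUE) {
  counts <- check_count_matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop("cannot normalize all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(reference)) {
    f75 <- quartile_depth(counts, lib)
    reference <- which.min(abs(f75 - mean(f75)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(counts))
    if (is.na(reference)) stop("reference sample not found in counts")
  }
  ref <- counts[, reference]
  n_ref <- lib[reference]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], ref, lib[j], n_ref,
             logratio_trim, sum_trim, do_weighting)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample against the reference: trimmed weighted mean of M-values.
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                     do_weighting) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & (a > -1e10)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  f <- if (do_weighting) {
    sum(m[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(m[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Negative-binomial exact conditional test for one gene
#'
#' Two-sided exact test of equal expected expression in two groups of
#' count libraries. Counts are first scaled to a common effective
#' library size (the geometric mean of the supplied effective sizes)
#' and summed within group; the p-value is then the total conditional
#' probability, given the overall sum, of all splits at most as likely
#' as the observed one. Under a common dispersion `phi` the group sums
#' are negative binomial with sizes n_a/phi and n_b/phi, so the
#' conditional distribution of the group-A sum is computed by direct
#' enumeration over all splits of the total. With `phi = 0` the
#' Poisson limit applies and the conditional distribution is binomial
#' with success probability n_a / (n_a + n_b).
#'
#' @param group_a_counts,group_b_counts Integer count vectors, one
#'   entry per sample in the group.
#' @param lib_a,lib_b Effective library sizes (library size times
#'   normalization factor) for the samples in each group.
#' @param dispersion Common negative-binomial dispersion phi >= 0
#'   (variance mu + phi mu^2).
#' @return A p-value in (0, 1].
#' @export
nb_exact_test <- function(group_a_counts, group_b_counts, lib_a, lib_b,
                          dispersion) {
  if (length(dispersion) != 1 || is.na(dispersion) || dispersion < 0)
    stop("dispersion must be a single nonnegative number")
  if (length(group_a_counts) < 1 || length(group_b_counts) < 1)
    stop("each group needs at least one sample")
  if (length(lib_a) != length(group_a_counts) ||
      length(lib_b) != length(group_b_counts))
    stop("library sizes must match counts")
  if (any(c(lib_a, lib_b) <= 0)) stop("library sizes must be positive")
  common <- exp(mean(log(c(lib_a, lib_b))))
  ya <- round(sum(group_a_counts * common / lib_a))
  yb <- round(sum(group_b_counts * common / lib_b))
  nb_split_pvalue(ya, yb, length(group_a_counts), length(group_b_counts),
                  dispersion)
}

# Exact conditional p for equalized group sums ya vs yb with n_a, n_b
# libraries per group and common dispersion phi. Enumerates the
# conditional pmf over all splits of the total and sums the
# probabilities of splits no more likely than the observed one.
nb_split_pvalue <- function(ya, yb, n_a, n_b, phi) {
  total <- ya + yb
  if (total == 0) return(1)
  y <- 0:total
  if (phi == 0) {
    logp <- stats::dbinom(y, size = total, prob = n_a / (n_a + n_b),
                          log = TRUE)
  } else {
    logp <- stats::dnbinom(y, size = n_a / phi, prob = 0.5, log = TRUE) +
      stats::dnbinom(total - y, size = n_b / phi, prob = 0.5, log = TRUE)
    logp <- logp - log_sum_exp(logp)
  }
  lobs <- logp[ya + 1]
  p <- sum(exp(logp[logp <= lobs + 1e-7]))
  min(p, 1)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Common dispersion by method of moments
#'
#' Estimates a single negative-binomial dispersion phi (variance
#' mu + phi mu^2) shared by all genes. Counts are scaled to a common
#' effective library size; within every replicated
#' (cell type, treatment) group the gene-wise sample mean m and
#' variance v are computed and pooled as
#' phi = sum(v - c m) / sum(m^2 - v / n), where c corrects the Poisson
#' part of the variance for the residual depth differences introduced
#' by the scaling, and n is the group size. The estimate is floored at
#' zero.
#'
#' @inheritParams cpm
#' @param design Data frame with columns `sample`, `cell_type`,
#'   `treatment` describing the columns of `counts`.
#' @param min_mean Genes with scaled group mean below this are skipped.
#' @return A single nonnegative dispersion estimate.
#' @export
estimate_dispersion <- function(counts, design, norm_factors = NULL,
                                min_mean = 1) {
  counts <- check_count_matrix(counts)
  design <- check_design(design, counts)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  eff <- colSums(counts) * norm_factors
  common <- exp(mean(log(eff)))
  scaled <- sweep(counts, 2, common / eff, "*")
  groups <- interaction(design$cell_type, design$treatment, drop = TRUE)
  num <- 0
  den <- 0
  seen_replicated <- FALSE
  for (g in levels(groups)) {
    idx <- which(groups == g)
    n <- length(idx)
    if (n < 2) next
    seen_replicated <- TRUE
    z <- scaled[, idx, drop = FALSE]
    m <- rowMeans(z)
    v <- apply(z, 1, stats::var)
    cbar <- mean(common / eff[idx])
    use <- m >= min_mean
    num <- num + sum(v[use] - cbar * m[use])
    den <- den + sum(m[use]^2 - v[use] / n)
  }
  if (!seen_replicated)
    stop("dispersion estimation needs at least one group with >= 2 replicates")
  if (den <= 0) return(0)
  max(0, num / den)
}

#' Signed fold change from log2 fold change
#'
#' Display convention for fold changes: the expression ratio itself
#' when it is at least 1, otherwise the negative reciprocal (a halving
#' is shown as -2 rather than 0.5).
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return Numeric vector with `abs(signed_fc) >= 1`.
#' @export
signed_fc <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Differential expression for one contrast
#'
#' Runs the full per-contrast analysis: TMM-normalized CPM means with a
#' pseudo-count for the fold change, the negative-binomial exact
#' conditional test for the p-value, Benjamini-Hochberg FDR, and the
#' DEG rule (|signed FC| strictly greater than `fc_thresh` and raw
#' p < `p_thresh`). Normalization factors and the common dispersion are
#' computed from the full matrix unless supplied.
#'
#' @inheritParams estimate_dispersion
#' @param cell_type Cell type whose samples form the contrast
#'   (e.g. `"M1"`).
#' @param numerator,denominator Treatment labels for the numerator and
#'   denominator groups (e.g. `"IFNL4"` vs `"NT"`).
#' @param fc_thresh,p_thresh DEG rule thresholds.
#' @param dispersion Optional common dispersion; estimated with
#'   [estimate_dispersion()] when `NULL`.
#' @param pseudo Pseudo-count added to group mean CPM before the log
#'   ratio.
#' @return A `contrast_result` data frame with columns `gene`,
#'   `log2FC`, `signed_fc`, `mean_cpm`, `p_value`, `fdr`, `is_deg`.
#' @export
run_contrast <- function(counts, design, cell_type, numerator, denominator,
                         fc_thresh = 1.5, p_thresh = 0.05,
                         norm_factors = NULL, dispersion = NULL,
                         pseudo = 0.5) {
  counts <- check_count_matrix(counts)
  design <- check_design(design, counts)
  if (!cell_type %in% design$cell_type)
    stop("unknown cell type: ", cell_type)
  for (tr in c(numerator, denominator))
    if (!tr %in% design$treatment) stop("unknown treatment: ", tr)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, design, norm_factors)
  idx_a <- which(design$cell_type == cell_type & design$treatment == numerator)
  idx_b <- which(design$cell_type == cell_type &
                   design$treatment == denominator)
  if (length(idx_a) == 0 || length(idx_b) == 0)
    stop("empty group for contrast ", numerator, " vs ", denominator,
         " in ", cell_type)
  eff <- colSums(counts) * norm_factors
  cpm_mat <- sweep(counts, 2, eff, "/") * 1e6
  mean_a <- rowMeans(cpm_mat[, idx_a, drop = FALSE])
  mean_b <- rowMeans(cpm_mat[, idx_b, drop = FALSE])
  log2fc <- log2((mean_a + pseudo) / (mean_b + pseudo))
  p <- vapply(seq_len(nrow(counts)), function(g) {
    nb_exact_test(counts[g, idx_a], counts[g, idx_b],
                  eff[idx_a], eff[idx_b], dispersion)
  }, numeric(1))
  fc <- signed_fc(log2fc)
  res <- data.frame(
    gene = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
           else rownames(counts),
    log2FC = log2fc,
    signed_fc = fc,
    mean_cpm = rowMeans(cpm_mat[, c(idx_a, idx_b), drop = FALSE]),
    p_value = p,
    fdr = bh_adjust(p),
    is_deg = abs(fc) > fc_thresh & p < p_thresh,
    row.names = NULL
  )
  attr(res, "cell_type") <- cell_type
  attr(res, "contrast") <- paste0(numerator, "_vs_", denominator)
  attr(res, "dispersion") <- dispersion
  attr(res, "thresholds") <- c(fc_thresh = fc_thresh, p_thresh = p_thresh)
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' The three standard contrasts for one cell type
#'
#' Computes IFN-lambda3 vs NT, IFN-lambda4 vs NT and IFN-lambda4 vs
#' IFN-lambda3 over a shared gene universe, with a single set of
#' normalization factors and a single common dispersion. The third
#' contrast is oriented with IFN-lambda4 as numerator, so a positive
#' fold change means higher expression under IFN-lambda4.
#'
#' @inheritParams run_contrast
#' @param treatments Named character vector mapping the roles `nt`,
#'   `l3`, `l4` to treatment labels in `design`.
#' @return A `contrast_triplet`: list with elements `cell_type`, `l3`
#'   (lambda3 vs NT), `l4` (lambda4 vs NT), `l4vl3` (lambda4 vs
#'   lambda3), all sharing gene order.
#' @export
run_triplet <- function(counts, design, cell_type,
                        fc_thresh = 1.5, p_thresh = 0.05,
                        norm_factors = NULL, dispersion = NULL,
                        treatments = c(nt = "NT", l3 = "IFNL3",
                                       l4 = "IFNL4")) {
  counts <- check_count_matrix(counts)
  design <- check_design(design, counts)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, design, norm_factors)
  run1 <- function(num, den) {
    run_contrast(counts, design, cell_type, num, den,
                 fc_thresh = fc_thresh, p_thresh = p_thresh,
                 norm_factors = norm_factors, dispersion = dispersion)
  }
  out <- list(
    cell_type = cell_type,
    l3 = run1(treatments[["l3"]], treatments[["nt"]]),
    l4 = run1(treatments[["l4"]], treatments[["nt"]]),
    l4vl3 = run1(treatments[["l4"]], treatments[["l3"]])
  )
  class(out) <- "contrast_triplet"
  out
}

#' Apply the DEG rule to a contrast result
#'
#' A gene is differentially expressed when its fold change is more than
#' `fc_thresh`-fold in either direction and its raw p-value is below
#' `p_thresh`. A gene at exactly the fold-change threshold is excluded.
#'
#' @param result A `contrast_result` (or any data frame with `gene`,
#'   `signed_fc`, `p_value` columns).
#' @param fc_thresh,p_thresh Positive thresholds.
#' @return Character vector of DEG gene identifiers.
#' @export
call_degs <- function(result, fc_thresh = 1.5, p_thresh = 0.05) {
  if (fc_thresh <= 0 || p_thresh <= 0) stop("thresholds must be positive")
  result$gene[abs(result$signed_fc) > fc_thresh &
                result$p_value < p_thresh]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; a thin validating wrapper around
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values, order-preserving in the p ranking.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# Validates the sample design table against a count matrix.
check_design <- function(design, counts = NULL) {
  if (!is.data.frame(design)) stop("design must be a data frame")
  needed <- c("sample", "cell_type", "treatment")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0)
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  design$sample <- as.character(design$sample)
  if (anyDuplicated(design$sample)) stop("duplicate sample ids in design")
  if (!is.null(counts) && !is.null(colnames(counts))) {
    if (!identical(sort(design$sample), sort(colnames(counts))))
      stop("design samples do not match count matrix columns")
    design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  }
  design
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("Contrast ", attr(x, "contrast"), " in ", attr(x, "cell_type"),
      ": ", nrow(x), " genes, ", sum(x$is_deg), " DEGs (common dispersion ",
      signif(attr(x, "dispersion"), 3), ")\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
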