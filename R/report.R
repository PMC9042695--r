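#' PCA coordinates of samples
#'
#' Principal-component scores of the samples based on log-CPM
#' expression of the most variable genes. The sample x gene matrix is
#' centered per gene and decomposed by SVD; for determinism each
#' component's sign is fixed so that its largest-magnitude gene loading
#' is positive.
#'
#' @param logcpm Genes x samples matrix of log-CPM values (see
#'   [log_cpm()]).
#' @param n_components Number of components to report.
#' @param n_top_genes Number of most-variable genes used (all genes if
#'   fewer).
#' @return List with `scores` (data frame: `sample`, `PC1`, `PC2`,
#'   ...) and `var_explained` (fraction of variance per reported
#'   component, nonincreasing).
#' @export
pca_coords <- function(logcpm, n_components = 2, n_top_genes = 500) {
  if (nrow(logcpm) < 2 || ncol(logcpm) < 2)
    stop("PCA needs at least 2 genes and 2 samples")
  rv <- apply(logcpm, 1, stats::var)
  if (all(rv < 1e-12)) stop("degenerate input: constant expression matrix")
  keep <- order(rv, decreasing = TRUE)[seq_len(min(n_top_genes,
                                                   nrow(logcpm)))]
  x <- t(logcpm[keep, , drop = FALSE])
  n_components <- min(n_components, ncol(x), nrow(x) - 1)
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    load <- fit$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  out <- data.frame(sample = rownames(x), scores, row.names = NULL)
  list(scores = out,
       var_explained = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(n_components)])
}

#' Scatter table of the two NT comparisons
#'
#' Per-gene fold changes of lambda4 vs NT against lambda3 vs NT with
#' the four-way significance class used in scatter displays.
#'
#' @param triplet A `contrast_triplet` from [run_triplet()].
#' @return Data frame with `gene`, `fc_l4`, `fc_l3`, `class` in
#'   `c("both", "l3_only", "l4_only", "neither")`.
#' @export
scatter_table <- function(triplet) {
  stopifnot(inherits(triplet, "contrast_triplet"))
  deg3 <- triplet$l3$is_deg
  deg4 <- triplet$l4$is_deg
  data.frame(
    gene = triplet$l3$gene,
    fc_l4 = triplet$l4$signed_fc,
    fc_l3 = triplet$l3$signed_fc,
    class = ifelse(deg3 & deg4, "both",
            ifelse(deg3, "l3_only",
            ifelse(deg4, "l4_only", "neither"))),
    row.names = NULL
  )
}

#' Top regulated genes of a contrast
#'
#' DEGs ranked by fold-change magnitude within one direction, with
#' p-value and gene id as deterministic tiebreaks.
#'
#' @param result A `contrast_result`.
#' @param n Maximum number of rows.
#' @param direction `"up"` or `"down"`.
#' @return The top rows of `result`, ranked.
#' @export
top_table <- function(result, n = 10, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (n < 1) stop("n must be >= 1")
  rows <- result[result$is_deg &
                   (if (direction == "up") result$signed_fc > 0
                    else result$signed_fc < 0), , drop = FALSE]
  rows <- rows[order(-abs(rows$signed_fc), rows$p_value, rows$gene), ,
               drop = FALSE]
  rows <- utils::head(rows, n)
  rownames(rows) <- NULL
  class(rows) <- "data.frame"
  rows
}

#' Clustered ordering for heat-map display
#'
#' Average-linkage hierarchical clustering on Euclidean distances of
#' z-scored log-CPM rows (and of samples on the same z-scored matrix).
#' The orderings, not a rendered image, are the reportable output.
#'
#' @param logcpm Genes x samples matrix of log-CPM values.
#' @return List with `gene_order` and `sample_order` (integer
#'   permutations).
#' @export
heatmap_order <- function(logcpm) {
  rv <- apply(logcpm, 1, stats::var)
  z <- (logcpm - rowMeans(logcpm)) / sqrt(pmax(rv, 1e-12))
  list(
    gene_order = stats::hclust(stats::dist(z), method = "average")$order,
    sample_order = stats::hclust(stats::dist(t(z)),
                                 method = "average")$order
  )
}

#' Pipeline configuration
#'
#' Bundles all stage parameters of [run_pipeline()]. Either supply
#' `counts` and `design`, or a [sim_config()] in `sim` to generate
#' them.
#'
#' @param counts,design Study inputs (see [read_counts()],
#'   [read_design()]).
#' @param sim Optional [sim_config()]; used when `counts` is `NULL`.
#' @param thresholds A [tier_thresholds()] object; its `fc_thresh` and
#'   `p_thresh` also drive the DEG rule.
#' @param min_cpm,min_samples Expression-filter parameters
#'   (see [filter_expressed()]).
#' @param collection Optional named list of gene sets for enrichment
#'   of the per-cell-type DEG unions.
#' @param ora_fdr FDR cutoff for the enrichment comparison labels.
#' @param n_top Rows per top-table direction.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, design = NULL, sim = NULL,
                            thresholds = tier_thresholds(),
                            min_cpm = 1, min_samples = 2,
                            collection = NULL, ora_fdr = 0.05,
                            n_top = 10) {
  if (is.null(counts) && is.null(sim))
    stop("provide counts + design or a sim config")
  if (!is.null(counts) && is.null(design))
    stop("design is required with counts")
  structure(list(counts = counts, design = design, sim = sim,
                 thresholds = thresholds, min_cpm = min_cpm,
                 min_samples = min_samples, collection = collection,
                 ora_fdr = ora_fdr, n_top = n_top),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage for both cell types: (optional) simulation,
#' expression filtering, TMM normalization, the three contrasts,
#' perturbation classification and its summary, PCA, scatter and top
#' tables, and (when a collection is supplied) over-representation
#' analysis of each contrast's DEGs with the three-way provenance
#' labels. All outputs are deterministic functions of the inputs and
#' the simulation seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all tables are
#'   written as tab-separated files plus a human-readable summary.
#' @return A list bundle with elements `counts`, `design`,
#'   `norm_factors`, `dispersion`, `triplets`, `classes`, `summary`,
#'   `pca`, `scatter`, `top_tables`, `enrichment`, `truth` (when
#'   simulated) and `params`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (is.null(config$counts)) {
    sim <- simulate_counts(config$sim)
    counts <- sim$counts; design <- sim$design; truth <- sim$truth
  } else {
    counts <- check_count_matrix(config$counts)
    design <- check_design(config$design, counts)
  }
  counts <- filter_expressed(counts, config$min_cpm, config$min_samples)
  design <- check_design(design, counts)
  nf <- tmm_factors(counts)
  disp <- estimate_dispersion(counts, design, nf)
  th <- config$thresholds
  cell_types <- unique(design$cell_type)

  triplets <- lapply(cell_types, function(ct) {
    run_triplet(counts, design, ct, fc_thresh = th$fc_thresh,
                p_thresh = th$p_thresh, norm_factors = nf,
                dispersion = disp)
  })
  names(triplets) <- cell_types
  classes <- do.call(rbind, lapply(triplets, function(tr) {
    classify_genes(triplet_table(tr), th)
  }))
  rownames(classes) <- NULL
  summary <- summarize_classes(classes)
  lc <- log_cpm(counts, nf)
  pca <- pca_coords(lc)
  scatter <- lapply(triplets, scatter_table)
  top_tables <- lapply(triplets, function(tr) {
    lapply(tr[c("l3", "l4", "l4vl3")], function(res) {
      list(up = top_table(res, config$n_top, "up"),
           down = top_table(res, config$n_top, "down"))
    })
  })
  enrichment <- NULL
  if (!is.null(config$collection)) {
    universe <- rownames(counts)
    enrichment <- lapply(triplets, function(tr) {
      oras <- lapply(tr[c("l3", "l4", "l4vl3")], function(res) {
        run_ora(call_degs(res, th$fc_thresh, th$p_thresh), universe,
                config$collection)
      })
      oras$labels <- compare_contrast_enrichments(
        oras$l3, oras$l4, oras$l4vl3, config$ora_fdr)
      oras
    })
  }
  bundle <- list(counts = counts, design = design, norm_factors = nf,
                 dispersion = disp, triplets = triplets,
                 classes = classes, summary = summary, pca = pca,
                 scatter = scatter, top_tables = top_tables,
                 enrichment = enrichment, truth = truth,
                 params = list(thresholds = th, min_cpm = config$min_cpm,
                               min_samples = config$min_samples,
                               seed = if (is.null(config$sim)) NA_integer_
                                      else config$sim$seed))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Writes the bundle's tables as tab-separated files plus a text summary.
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (ct in names(bundle$triplets)) {
    tr <- bundle$triplets[[ct]]
    for (cn in c("l3", "l4", "l4vl3"))
      w(as.data.frame(tr[[cn]]),
        sprintf("contrast_%s_%s.tsv", ct, cn))
  }
  w(bundle$classes, "classification.tsv")
  w(bundle$pca$scores, "pca_scores.tsv")
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con)
  print(bundle$summary)
  sink()
  close(con)
  invisible(out_dir)
}
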