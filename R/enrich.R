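#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) of drawing at least `k` members of
#' a size-`m` gene set when sampling `n` genes without replacement from
#' a universe of `N`.
#'
#' @param k Overlap between query and set.
#' @param m Set size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return A p-value in (0, 1].
#' @export
hypergeom_p <- function(k, m, n, N) {
  if (any(c(k, m, n, N) < 0) || k > min(m, n) || m > N || n > N)
    stop("need 0 <= k <= min(m, n) and m, n <= N")
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Read / write GMT gene-set collections
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' name, description, then member genes. Reading is delegated to
#' [fgsea::gmtPathways()].
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector (recycled) written to
#'   the description column.
#' @return `read_gmt` returns a named list of unique gene-id vectors.
#' @name gmt_io
NULL

#' @rdname gmt_io
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  if (any(lengths(sets) == 0)) stop("empty gene set in GMT")
  lapply(sets, unique)
}

#' @rdname gmt_io
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis of a gene list
#'
#' Tests every gene set in a collection for enrichment in a query list
#' with the one-sided hypergeometric test, restricting each set to the
#' analysis universe (all genes that passed the expression filter).
#' FDR is Benjamini-Hochberg across the tested sets. Rows are ordered
#' by p-value with the set name as deterministic tiebreak.
#'
#' @param query Character vector of gene ids; must be a subset of
#'   `universe`.
#' @param universe Character vector of gene ids.
#' @param collection Named list of gene-id vectors (see [read_gmt()]).
#' @param min_overlap Sets overlapping the query in fewer genes are
#'   dropped before testing.
#' @return Data frame with columns `set`, `k`, `m`, `n`, `N`,
#'   `p_value`, `fdr`, carrying the collection's set names as the
#'   `collection` attribute.
#' @export
run_ora <- function(query, universe, collection, min_overlap = 1) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(setdiff(query, universe)) > 0)
    stop("query contains genes outside the universe")
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("collection must be a named list with unique names")
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(collection[[nm]], universe)
    m <- length(s)
    if (m == 0) return(NULL)
    k <- length(intersect(query, s))
    if (k < min_overlap) return(NULL)
    data.frame(set = nm, k = k, m = m, n = n, N = N,
               p_value = hypergeom_p(k, m, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) == 0) {
    data.frame(set = character(), k = integer(), m = integer(),
               n = integer(), N = integer(), p_value = numeric(),
               fdr = numeric())
  } else {
    out <- do.call(rbind, rows)
    out$fdr <- bh_adjust(out$p_value)
    out[order(out$p_value, out$set), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "collection") <- sort(names(collection))
  out
}

#' Provenance of enriched sets across the three contrasts
#'
#' Labels every gene set significant in at least one of the three
#' enrichment results with the three-way scheme used for pathway
#' comparison: `both_vs_NT` when significant in both lambda3-vs-NT and
#' lambda4-vs-NT enrichments, `one_vs_NT` when significant in exactly
#' one of them (regardless of the lambda4-vs-lambda3 result), and
#' `unique_to_L4vL3` when significant only in the lambda4-vs-lambda3
#' enrichment.
#'
#' @param rows_l3,rows_l4,rows_l4vl3 Results of [run_ora()] over the
#'   same collection for the three contrasts.
#' @param fdr_thresh Significance cutoff on the BH FDR.
#' @return Data frame with columns `set`, `sig_l3`, `sig_l4`,
#'   `sig_l4vl3`, `label`; one row per set significant anywhere.
#' @export
compare_contrast_enrichments <- function(rows_l3, rows_l4, rows_l4vl3,
                                         fdr_thresh = 0.05) {
  colls <- list(attr(rows_l3, "collection"), attr(rows_l4, "collection"),
                attr(rows_l4vl3, "collection"))
  if (!identical(colls[[1]], colls[[2]]) ||
      !identical(colls[[1]], colls[[3]]))
    stop("enrichment results come from different collections")
  sig_sets <- function(rows) rows$set[rows$fdr < fdr_thresh]
  a <- sig_sets(rows_l3); b <- sig_sets(rows_l4); c3 <- sig_sets(rows_l4vl3)
  all_sets <- sort(union(union(a, b), c3))
  if (length(all_sets) == 0)
    return(data.frame(set = character(), sig_l3 = logical(),
                      sig_l4 = logical(), sig_l4vl3 = logical(),
                      label = character()))
  sa <- all_sets %in% a
  sb <- all_sets %in% b
  sc <- all_sets %in% c3
  label <- ifelse(sa & sb, "both_vs_NT",
           ifelse(sa | sb, "one_vs_NT", "unique_to_L4vL3"))
  data.frame(set = all_sets, sig_l3 = sa, sig_l4 = sb, sig_l4vl3 = sc,
             label = label, row.names = NULL)
}
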