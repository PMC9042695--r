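#' Tier thresholds for the perturbation scheme
#'
#' Boundaries of the qualitative effect tiers used by the decision
#' scheme. A gene significant versus NT (|FC| > `fc_thresh`,
#' p < `p_thresh`) is `strong` when |FC| >= `strong_fc`, otherwise
#' `moderate`. An insignificant gene is `weak` when |FC| >=
#' `weak_floor_fc` or when it separates in the lambda4-vs-lambda3
#' contrast, and `null` otherwise. The magnitude boundaries are
#' configurable conventions, not measured constants.
#'
#' @param fc_thresh,p_thresh The DEG rule thresholds.
#' @param strong_fc Signed-FC magnitude at or above which a significant
#'   effect counts as strong.
#' @param weak_floor_fc Smallest FC magnitude an insignificant effect
#'   needs to count as weak rather than absent.
#' @return A `tier_thresholds` list.
#' @export
tier_thresholds <- function(fc_thresh = 1.5, p_thresh = 0.05,
                            strong_fc = 4.0, weak_floor_fc = 1.1) {
  if (!(1 < weak_floor_fc && weak_floor_fc < fc_thresh &&
        fc_thresh < strong_fc))
    stop("need 1 < weak_floor_fc < fc_thresh < strong_fc")
  if (p_thresh <= 0 || p_thresh >= 1) stop("p_thresh must be in (0, 1)")
  structure(list(fc_thresh = fc_thresh, p_thresh = p_thresh,
                 strong_fc = strong_fc, weak_floor_fc = weak_floor_fc),
            class = "tier_thresholds")
}

# The DEG rule as a vectorized predicate.
sig_rule <- function(fc, p, thresholds) {
  abs(fc) > thresholds$fc_thresh & p < thresholds$p_thresh
}

#' Effect tier of one interferon on a gene
#'
#' @param signed_fc_vs_nt Signed fold change of the interferon
#'   treatment versus NT.
#' @param p_vs_nt Raw p-value of that comparison.
#' @param sig_in_l4vl3 Logical; is the gene significant in the
#'   lambda4-vs-lambda3 contrast?
#' @param thresholds A [tier_thresholds()] object.
#' @return Character vector over `c("strong", "moderate", "weak",
#'   "null")`.
#' @export
assign_tier <- function(signed_fc_vs_nt, p_vs_nt, sig_in_l4vl3,
                        thresholds = tier_thresholds()) {
  stopifnot(inherits(thresholds, "tier_thresholds"))
  sig <- sig_rule(signed_fc_vs_nt, p_vs_nt, thresholds)
  afc <- abs(signed_fc_vs_nt)
  ifelse(sig & afc >= thresholds$strong_fc, "strong",
  ifelse(sig, "moderate",
  ifelse(afc >= thresholds$weak_floor_fc | sig_in_l4vl3, "weak", "null")))
}

#' Region of the three-set Venn diagram
#'
#' Sets are A = significant in lambda3 vs NT, B = significant in
#' lambda4 vs NT, C = significant in lambda4 vs lambda3. The eight
#' membership patterns map bijectively onto the seven regions plus
#' `"none"`.
#'
#' @param sig_a,sig_b,sig_c Logical vectors.
#' @return Character vector over `c("A_only", "B_only", "C_only",
#'   "AB", "AC", "BC", "ABC", "none")`.
#' @export
venn_region <- function(sig_a, sig_b, sig_c) {
  key <- paste0(as.integer(sig_a), as.integer(sig_b), as.integer(sig_c))
  map <- c("000" = "none", "100" = "A_only", "010" = "B_only",
           "001" = "C_only", "110" = "AB", "101" = "AC",
           "011" = "BC", "111" = "ABC")
  unname(map[key])
}

# Perturbation verdict for interferon X given the other interferon Y.
# Strong or moderate effects always perturb; absent effects never do.
# A weak effect perturbs only when the other interferon pushes the gene
# moderately in the same direction or weakly in the opposite direction;
# a weak effect opposite a strong or moderate one, or shadowed by a
# strong one in the same direction, does not.
perturbed_verdict <- function(tier_x, tier_y, dir_x, dir_y) {
  same <- dir_x != "0" & dir_x == dir_y
  opposite <- dir_x != "0" & dir_y != "0" & dir_x != dir_y
  ifelse(tier_x %in% c("strong", "moderate"), TRUE,
  ifelse(tier_x == "null", FALSE,
         (tier_y == "moderate" & same) | (tier_y == "weak" & opposite)))
}

#' Classify genes from the three contrasts
#'
#' Applies the full decision scheme to a table of per-gene results for
#' the three contrasts of one or both cell types: assigns effect tiers
#' and directions for each interferon, the three-set Venn region, a
#' perturbed/unperturbed verdict per interferon, and a gene category.
#' Categories: `reciprocal` (both interferons perturb, opposite
#' directions), `same_direction` (both perturb, same direction),
#' `l4_unique` / `l3_unique` (only one perturbs), `unperturbed_both`.
#'
#' @param triplet_tbl Data frame with columns `gene`, `cell_type`,
#'   `fc_l3`, `p_l3` (lambda3 vs NT), `fc_l4`, `p_l4` (lambda4 vs NT),
#'   `fc_l4vl3`, `p_l4vl3`. See [triplet_table()] to build one from a
#'   `contrast_triplet`.
#' @param thresholds A [tier_thresholds()] object.
#' @return A `gene_class` data frame with one row per input row and
#'   columns `gene`, `cell_type`, `tier_l3`, `tier_l4`, `dir_l3`,
#'   `dir_l4`, `venn_region`, `perturbed_l3`, `perturbed_l4`,
#'   `category`.
#' @export
classify_genes <- function(triplet_tbl, thresholds = tier_thresholds()) {
  needed <- c("gene", "cell_type", "fc_l3", "p_l3", "fc_l4", "p_l4",
              "fc_l4vl3", "p_l4vl3")
  missing_cols <- setdiff(needed, names(triplet_tbl))
  if (length(missing_cols) > 0)
    stop("triplet table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  sig_a <- sig_rule(triplet_tbl$fc_l3, triplet_tbl$p_l3, thresholds)
  sig_b <- sig_rule(triplet_tbl$fc_l4, triplet_tbl$p_l4, thresholds)
  sig_c <- sig_rule(triplet_tbl$fc_l4vl3, triplet_tbl$p_l4vl3, thresholds)
  tier_l3 <- assign_tier(triplet_tbl$fc_l3, triplet_tbl$p_l3, sig_c,
                         thresholds)
  tier_l4 <- assign_tier(triplet_tbl$fc_l4, triplet_tbl$p_l4, sig_c,
                         thresholds)
  dir_l3 <- fc_direction(triplet_tbl$fc_l3, tier_l3)
  dir_l4 <- fc_direction(triplet_tbl$fc_l4, tier_l4)
  perturbed_l3 <- perturbed_verdict(tier_l3, tier_l4, dir_l3, dir_l4)
  perturbed_l4 <- perturbed_verdict(tier_l4, tier_l3, dir_l4, dir_l3)
  opposite <- dir_l3 != "0" & dir_l4 != "0" & dir_l3 != dir_l4
  same <- dir_l3 != "0" & dir_l3 == dir_l4
  category <- ifelse(perturbed_l3 & perturbed_l4 & opposite, "reciprocal",
    ifelse(perturbed_l3 & perturbed_l4 & same, "same_direction",
    ifelse(perturbed_l4 & !perturbed_l3, "l4_unique",
    ifelse(perturbed_l3 & !perturbed_l4, "l3_unique",
    ifelse(!perturbed_l3 & !perturbed_l4, "unperturbed_both", "other")))))
  out <- data.frame(
    gene = triplet_tbl$gene,
    cell_type = triplet_tbl$cell_type,
    tier_l3 = tier_l3, tier_l4 = tier_l4,
    dir_l3 = dir_l3, dir_l4 = dir_l4,
    venn_region = venn_region(sig_a, sig_b, sig_c),
    perturbed_l3 = perturbed_l3, perturbed_l4 = perturbed_l4,
    category = category,
    row.names = NULL
  )
  class(out) <- c("gene_class", "data.frame")
  out
}

# Direction of effect: the sign of the mean signed fold change versus
# NT; genes in the null tier have no direction.
fc_direction <- function(fc, tier) {
  ifelse(tier == "null" | abs(fc) <= 1, "0", ifelse(fc > 0, "+", "-"))
}

#' Flatten a contrast triplet into a classification input table
#'
#' @param triplet A `contrast_triplet` from [run_triplet()].
#' @return Data frame with the columns expected by [classify_genes()].
#' @export
triplet_table <- function(triplet) {
  stopifnot(inherits(triplet, "contrast_triplet"))
  if (!identical(triplet$l3$gene, triplet$l4$gene) ||
      !identical(triplet$l3$gene, triplet$l4vl3$gene))
    stop("triplet contrasts do not share gene order")
  data.frame(
    gene = triplet$l3$gene,
    cell_type = triplet$cell_type,
    fc_l3 = triplet$l3$signed_fc, p_l3 = triplet$l3$p_value,
    fc_l4 = triplet$l4$signed_fc, p_l4 = triplet$l4$p_value,
    fc_l4vl3 = triplet$l4vl3$signed_fc, p_l4vl3 = triplet$l4vl3$p_value,
    row.names = NULL
  )
}

#' Two-set Venn partition of DEG lists
#'
#' @param deg_a,deg_b Character vectors of gene identifiers.
#' @return List with `unique_a`, `unique_b`, `common`; a disjoint
#'   partition of the union.
#' @export
two_set_venn <- function(deg_a, deg_b) {
  deg_a <- unique(as.character(deg_a))
  deg_b <- unique(as.character(deg_b))
  list(unique_a = setdiff(deg_a, deg_b),
       unique_b = setdiff(deg_b, deg_a),
       common = intersect(deg_a, deg_b))
}

#' Summarize a classification
#'
#' Aggregates a `gene_class` table into the counts the analysis
#' reports: per cell type the Venn-region counts, category counts,
#' "unperturbed by lambda4" and "unperturbed by lambda3" totals (genes
#' significant in at least one contrast for which the verdict is
#' unperturbed), the lambda4-significant-only counts (significant in
#' lambda4 vs NT but not lambda3 vs NT, i.e. regions B-only and BC)
#' with their same-direction subset, the same-direction-with-weak-
#' lambda4 subset, and the direction split of reciprocal genes unique
#' to the lambda4-vs-lambda3 contrast. Cross-cell-type totals:
#' `reciprocal_total` (reciprocal category over both cell types),
#' `l4_unique_total` (lambda4-significant-only genes over both cell
#' types), `l4_sig_only_same_dir_total`, and `l4_strong_unique_total`
#' (the `l4_unique` decision-table category).
#'
#' @param classes A `gene_class` data frame (one or both cell types).
#' @return A `perturbation_summary` list with elements `per_cell_type`
#'   and `totals`.
#' @export
summarize_classes <- function(classes) {
  if (nrow(classes) == 0) {
    empty <- list()
    out <- list(per_cell_type = empty,
                totals = list(reciprocal_total = 0L, l4_unique_total = 0L,
                              l4_sig_only_same_dir_total = 0L,
                              l4_strong_unique_total = 0L))
    class(out) <- "perturbation_summary"
    return(out)
  }
  regions <- c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC", "none")
  categories <- c("reciprocal", "same_direction", "l4_unique", "l3_unique",
                  "unperturbed_both", "other")
  per_ct <- lapply(split(classes, classes$cell_type), function(cl) {
    sig <- cl$venn_region != "none"
    l4_sig_only <- cl$venn_region %in% c("B_only", "BC")
    same <- cl$dir_l3 != "0" & cl$dir_l3 == cl$dir_l4
    list(
      n_genes = nrow(cl),
      n_significant = sum(sig),
      region_counts = table(factor(cl$venn_region, levels = regions)),
      category_counts = table(factor(cl$category, levels = categories)),
      unperturbed_by_l4 = sum(sig & !cl$perturbed_l4),
      unperturbed_by_l3 = sum(sig & !cl$perturbed_l3),
      l4_sig_only = sum(l4_sig_only),
      l4_sig_only_same_dir = sum(l4_sig_only & same &
                                   cl$perturbed_l3 & cl$perturbed_l4),
      same_dir_weak_l4 = sum(cl$category == "same_direction" &
                               cl$tier_l4 == "weak"),
      c_only_recip_down_l3_up_l4 = sum(cl$venn_region == "C_only" &
                                         cl$category == "reciprocal" &
                                         cl$dir_l3 == "-"),
      c_only_recip_up_l3_down_l4 = sum(cl$venn_region == "C_only" &
                                         cl$category == "reciprocal" &
                                         cl$dir_l3 == "+")
    )
  })
  tot <- function(field) sum(vapply(per_ct, `[[`, numeric(1), field))
  out <- list(
    per_cell_type = per_ct,
    totals = list(
      reciprocal_total = sum(vapply(per_ct, function(x)
        unname(x$category_counts["reciprocal"]), numeric(1))),
      l4_unique_total = tot("l4_sig_only"),
      l4_sig_only_same_dir_total = tot("l4_sig_only_same_dir"),
      l4_strong_unique_total = sum(vapply(per_ct, function(x)
        unname(x$category_counts["l4_unique"]), numeric(1)))
    )
  )
  class(out) <- "perturbation_summary"
  out
}

#' @export
print.perturbation_summary <- function(x, ...) {
  for (ct in names(x$per_cell_type)) {
    s <- x$per_cell_type[[ct]]
    cat("== ", ct, " (", s$n_genes, " genes, ", s$n_significant,
        " significant in >= 1 contrast)\n", sep = "")
    cat("  Venn regions: ",
        paste(names(s$region_counts), as.integer(s$region_counts),
              sep = "=", collapse = " "), "\n", sep = "")
    cat("  Categories:   ",
        paste(names(s$category_counts), as.integer(s$category_counts),
              sep = "=", collapse = " "), "\n", sep = "")
    cat("  unperturbed by lambda4: ", s$unperturbed_by_l4,
        "; unperturbed by lambda3: ", s$unperturbed_by_l3, "\n", sep = "")
    cat("  lambda4-significant-only: ", s$l4_sig_only,
        " (same direction: ", s$l4_sig_only_same_dir, ")\n", sep = "")
  }
  t <- x$totals
  cat("== Totals: reciprocal=", t$reciprocal_total,
      " lambda4-unique=", t$l4_unique_total,
      " (same-direction ", t$l4_sig_only_same_dir_total,
      " + opposite ", t$l4_strong_unique_total, ")\n", sep = "")
  invisible(x)
}
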