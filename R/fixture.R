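#' Deterministic classification fixtures
#'
#' Builds a table of per-gene signed fold changes and p-values for the
#' three contrasts, constructed (not simulated) so that every row lands
#' in a requested Venn region with a requested direction pair when
#' re-evaluated with the DEG rule. Significant contrasts get p = 1e-4
#' and a fold change at the tier midpoint; insignificant ones get
#' p = 0.5 and a sub-threshold fold change. The fixture exercises the
#' classification algebra, not the statistical testing.
#'
#' For each region the canonical tier pair is chosen to match the
#' decision scheme's cases: e.g. a `C_only` row with opposite
#' directions is a weak/weak reciprocal pair, a `BC` row with opposite
#' directions is a strong lambda4 effect against a weak opposite
#' lambda3 effect, an `A_only` row with both directions equal is a
#' strong lambda3 effect shadowing a weak lambda4 effect.
#'
#' @param region_spec Data frame with columns `cell_type`, `region`
#'   (one of `A_only`, `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC`
#'   where A = significant in lambda3 vs NT, B = lambda4 vs NT,
#'   C = lambda4 vs lambda3), `dir_l3`, `dir_l4` (each `"+"`, `"-"` or
#'   `"0"`), and `n` (nonnegative row count).
#' @param thresholds A [tier_thresholds()] object; fold-change
#'   midpoints are placed relative to these boundaries.
#' @return Data frame with columns `gene`, `cell_type`, `fc_l3`,
#'   `p_l3`, `fc_l4`, `p_l4`, `fc_l4vl3`, `p_l4vl3`, suitable for
#'   [classify_genes()].
#' @export
build_fixture <- function(region_spec, thresholds = tier_thresholds()) {
  needed <- c("cell_type", "region", "dir_l3", "dir_l4", "n")
  missing_cols <- setdiff(needed, names(region_spec))
  if (length(missing_cols) > 0)
    stop("region_spec is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(region_spec$n < 0)) stop("region counts must be nonnegative")
  rows <- lapply(seq_len(nrow(region_spec)), function(i) {
    r <- region_spec[i, ]
    if (r$n == 0) return(NULL)
    proto <- fixture_prototype(r$region, r$dir_l3, r$dir_l4, thresholds)
    out <- proto[rep(1, r$n), , drop = FALSE]
    out$gene <- sprintf("%s_%s_%s%s_%04d", r$cell_type, r$region,
                        dir_tag(r$dir_l3), dir_tag(r$dir_l4),
                        seq_len(r$n))
    out$cell_type <- r$cell_type
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(gene = character(), cell_type = character(),
                      fc_l3 = numeric(), p_l3 = numeric(),
                      fc_l4 = numeric(), p_l4 = numeric(),
                      fc_l4vl3 = numeric(), p_l4vl3 = numeric())
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("gene", "cell_type", "fc_l3", "p_l3", "fc_l4", "p_l4",
          "fc_l4vl3", "p_l4vl3")]
}

dir_tag <- function(d) c("+" = "up", "-" = "dn", "0" = "z0")[[d]]

dir_sign <- function(d) c("+" = 1, "-" = -1, "0" = 0)[[d]]

# One prototype row of (FC, p) per contrast for a region/direction
# request. Stops with a specification error when the direction pair is
# incompatible with the region's semantics.
fixture_prototype <- function(region, dir_l3, dir_l4, th) {
  regions <- c("A_only", "B_only", "C_only", "AB", "AC", "BC", "ABC")
  if (!region %in% regions)
    stop("unknown region: ", region)
  if (!dir_l3 %in% c("+", "-", "0") || !dir_l4 %in% c("+", "-", "0"))
    stop("directions must be '+', '-' or '0'")
  s3 <- dir_sign(dir_l3); s4 <- dir_sign(dir_l4)
  in_a <- region %in% c("A_only", "AB", "AC", "ABC")
  in_b <- region %in% c("B_only", "AB", "BC", "ABC")
  in_c <- region %in% c("C_only", "AC", "BC", "ABC")
  if (in_a && s3 == 0)
    stop("region ", region, " needs a nonzero lambda3 direction")
  if (in_b && s4 == 0)
    stop("region ", region, " needs a nonzero lambda4 direction")
  if (region == "C_only" && (s3 == 0 || s4 == 0))
    stop("region C_only needs nonzero directions for both interferons")
  if (s3 == 0 && s4 == 0)
    stop("at least one direction must be nonzero for region ", region)
  same <- s3 != 0 && s3 == s4
  opposite <- s3 != 0 && s4 != 0 && s3 != s4

  # tier midpoints relative to the thresholds
  strong <- 1.5 * th$strong_fc
  moderate <- (th$fc_thresh + th$strong_fc) / 2
  weak <- (th$weak_floor_fc + th$fc_thresh) / 2
  none <- 1.0
  p_sig <- 1e-4
  p_ns <- 0.5

  pick <- function(mag3, mag4) {
    fc3 <- if (s3 == 0) none else s3 * mag3
    fc4 <- if (s4 == 0) none else s4 * mag4
    c(fc3 = fc3, fc4 = fc4)
  }
  fc <- if (region == "A_only") {
    if (s4 == 0) pick(moderate, none)
    else if (same) pick(strong, weak)     # weak lambda4 shadowed by strong lambda3
    else pick(moderate, weak)             # weak lambda4 opposite a moderate lambda3
  } else if (region == "B_only") {
    if (s3 == 0) pick(none, moderate)
    else if (same) pick(weak, moderate)   # weak lambda3 carried by moderate lambda4
    else pick(weak, moderate)             # weak lambda3 opposite a moderate lambda4
  } else if (region == "C_only") {
    pick(weak, weak)
  } else if (region == "AB" || region == "ABC") {
    pick(moderate, moderate)
  } else if (region == "AC") {
    pick(moderate, weak)
  } else { # BC
    if (opposite) pick(weak, strong)      # strong lambda4 against weak opposite lambda3
    else pick(weak, moderate)
  }

  # lambda4 vs lambda3 contrast: direction from the planted separation,
  # magnitude fixed by whether the region includes C
  l2 <- function(f) ifelse(f >= 0, log2(abs(f)), -log2(abs(f)))
  sep <- l2(fc[["fc4"]]) - l2(fc[["fc3"]])
  sgn_c <- if (sep == 0) 1 else sign(sep)
  fc_c <- if (in_c) sgn_c * (th$fc_thresh + 1) else sgn_c * 1.2
  p_c <- if (in_c) p_sig else p_ns
  data.frame(gene = NA_character_, cell_type = NA_character_,
             fc_l3 = fc[["fc3"]], p_l3 = if (in_a) p_sig else p_ns,
             fc_l4 = fc[["fc4"]], p_l4 = if (in_b) p_sig else p_ns,
             fc_l4vl3 = fc_c, p_l4vl3 = p_c,
             stringsAsFactors = FALSE)
}

#' Worked-example region counts
#'
#' The region and direction-pair counts used throughout the package's
#' worked example: a published three-contrast comparison of M1 and M2
#' monocyte-derived macrophages differentiated with IFN-lambda3 or
#' IFN-lambda4. Feeding this table to [build_fixture()] and
#' [summarize_classes()] reproduces the example's headline arithmetic:
#' 530 + 231 = 761 reciprocally regulated genes, 229 + 13 = 242 genes
#' significant only for IFN-lambda4, 1707 M2 genes unperturbed by
#' IFN-lambda4, and the 290/231 direction split of the 521 M1 genes
#' unique to the lambda4-vs-lambda3 contrast.
#'
#' Only the subsets whose counts the example states are included; the
#' orientation of direction pairs whose split is not stated is fixed
#' arbitrarily.
#'
#' @return A region-spec data frame for [build_fixture()].
#' @export
worked_example_regions <- function() {
  rbind(
    # M1: reciprocal genes unique to the lambda4-vs-lambda3 contrast
    data.frame(cell_type = "M1", region = "C_only",
               dir_l3 = "-", dir_l4 = "+", n = 290),
    data.frame(cell_type = "M1", region = "C_only",
               dir_l3 = "+", dir_l4 = "-", n = 231),
    # M1: reciprocal and significant against NT for both interferons
    data.frame(cell_type = "M1", region = "ABC",
               dir_l3 = "+", dir_l4 = "-", n = 9),
    # M1: weak lambda4 response riding a moderate lambda3 response
    data.frame(cell_type = "M1", region = "AC",
               dir_l3 = "+", dir_l4 = "+", n = 433),
    # M1: strong lambda4 effect with weak opposite lambda3 effect
    data.frame(cell_type = "M1", region = "BC",
               dir_l3 = "-", dir_l4 = "+", n = 103),
    # M1: significant only for lambda4, same direction
    data.frame(cell_type = "M1", region = "B_only",
               dir_l3 = "+", dir_l4 = "+", n = 126),
    # M1: significant only for lambda3 (fills its circle to 1123)
    data.frame(cell_type = "M1", region = "A_only",
               dir_l3 = "-", dir_l4 = "0", n = 681),
    # M2: reciprocal genes unique to the lambda4-vs-lambda3 contrast
    data.frame(cell_type = "M2", region = "C_only",
               dir_l3 = "-", dir_l4 = "+", n = 115),
    data.frame(cell_type = "M2", region = "C_only",
               dir_l3 = "+", dir_l4 = "-", n = 115),
    # M2: the one reciprocal gene significant in both NT comparisons
    data.frame(cell_type = "M2", region = "ABC",
               dir_l3 = "+", dir_l4 = "-", n = 1),
    # M2: weak lambda4 response riding a moderate lambda3 response
    data.frame(cell_type = "M2", region = "AC",
               dir_l3 = "+", dir_l4 = "+", n = 587),
    # M2: strong lambda4 effect with weak opposite lambda3 effect
    data.frame(cell_type = "M2", region = "BC",
               dir_l3 = "-", dir_l4 = "+", n = 3),
    # M2: significant only for lambda4, same direction
    data.frame(cell_type = "M2", region = "B_only",
               dir_l3 = "+", dir_l4 = "+", n = 10),
    # M2: lambda3-only genes unperturbed by lambda4 (1707 in total):
    # part with no lambda4 effect, part with a weak lambda4 effect
    # shadowed by a strong lambda3 effect
    data.frame(cell_type = "M2", region = "A_only",
               dir_l3 = "+", dir_l4 = "0", n = 1000),
    data.frame(cell_type = "M2", region = "A_only",
               dir_l3 = "+", dir_l4 = "+", n = 707)
  )
}
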