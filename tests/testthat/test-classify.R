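test_that("tier assignment follows the tier boundaries", {
  th <- tier_thresholds()
  # a 27.6-fold significant change is a strong effect
  expect_equal(assign_tier(27.55, 0.00016, FALSE, th), "strong")
  expect_equal(assign_tier(-2.0, 0.01, FALSE, th), "moderate")
  expect_equal(assign_tier(1.0, 0.9, FALSE, th), "null")
  expect_equal(assign_tier(1.2, 0.3, TRUE, th), "weak")
  expect_equal(assign_tier(1.2, 0.3, FALSE, th), "weak")
  expect_equal(assign_tier(1.05, 0.3, FALSE, th), "null")
  expect_equal(assign_tier(1.05, 0.3, TRUE, th), "weak")
  # significant but below the strong boundary stays moderate
  expect_equal(assign_tier(3.9, 0.001, FALSE, th), "moderate")
  expect_equal(assign_tier(4.0, 0.001, FALSE, th), "strong")
})

test_that("tier thresholds enforce their ordering", {
  expect_error(tier_thresholds(weak_floor_fc = 0.9), "weak_floor_fc")
  expect_error(tier_thresholds(strong_fc = 1.4), "weak_floor_fc")
  expect_error(tier_thresholds(p_thresh = 0), "p_thresh")
})

test_that("venn_region maps the 8 patterns bijectively", {
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE))
  out <- venn_region(grid$a, grid$b, grid$c)
  expect_equal(length(unique(out)), 8)
  expect_equal(venn_region(TRUE, FALSE, FALSE), "A_only")
  expect_equal(venn_region(FALSE, FALSE, TRUE), "C_only")
  expect_equal(venn_region(FALSE, FALSE, FALSE), "none")
  expect_equal(venn_region(TRUE, TRUE, TRUE), "ABC")
})

test_that("the decision table matches brute-force enumeration over all tier/direction inputs", {
  tiers <- c("strong", "moderate", "weak", "null")
  combos <- expand.grid(tier_l3 = tiers, tier_l4 = tiers,
                        dir_l3 = c("+", "-"), dir_l4 = c("+", "-"),
                        stringsAsFactors = FALSE)
  # direction is undefined exactly for the null tier
  combos$dir_l3[combos$tier_l3 == "null"] <- "0"
  combos$dir_l4[combos$tier_l4 == "null"] <- "0"
  combos <- unique(combos)
  th <- tier_thresholds()
  fc_for <- function(tier, dir) {
    mag <- c(strong = 6, moderate = 2.5, weak = 1.3, null = 1.0)[[tier]]
    if (dir == "-") -mag else mag
  }
  p_for <- function(tier) if (tier %in% c("strong", "moderate")) 1e-4 else 0.5
  tbl <- data.frame(
    gene = sprintf("g%d", seq_len(nrow(combos))), cell_type = "M1",
    fc_l3 = mapply(fc_for, combos$tier_l3, combos$dir_l3),
    p_l3 = sapply(combos$tier_l3, p_for),
    fc_l4 = mapply(fc_for, combos$tier_l4, combos$dir_l4),
    p_l4 = sapply(combos$tier_l4, p_for),
    fc_l4vl3 = 1.0, p_l4vl3 = 0.5)
  cl <- classify_genes(tbl, th)
  expect_identical(cl$tier_l3, combos$tier_l3)
  expect_identical(cl$tier_l4, combos$tier_l4)
  for (i in seq_len(nrow(combos))) {
    rel <- if (combos$dir_l3[i] == "0" || combos$dir_l4[i] == "0") "none"
           else if (combos$dir_l3[i] == combos$dir_l4[i]) "same"
           else "opposite"
    want3 <- oracle_perturbed(combos$tier_l3[i], combos$tier_l4[i], rel)
    want4 <- oracle_perturbed(combos$tier_l4[i], combos$tier_l3[i], rel)
    expect_equal(cl$perturbed_l3[i], want3,
                 label = paste0("perturbed_l3[", i, "]"))
    expect_equal(cl$perturbed_l4[i], want4,
                 label = paste0("perturbed_l4[", i, "]"))
    expect_equal(cl$category[i], oracle_category(want3, want4, rel),
                 label = paste0("category[", i, "]"))
  }
})

test_that("swapping the two interferons swaps the verdicts and preserves reciprocity", {
  set.seed(17)
  n <- 400
  tbl <- data.frame(
    gene = sprintf("g%d", 1:n), cell_type = "M1",
    fc_l3 = signed_fc(rnorm(n, 0, 1.5)), p_l3 = runif(n),
    fc_l4 = signed_fc(rnorm(n, 0, 1.5)), p_l4 = runif(n),
    fc_l4vl3 = signed_fc(rnorm(n, 0, 1.5)), p_l4vl3 = runif(n))
  swapped <- data.frame(
    gene = tbl$gene, cell_type = tbl$cell_type,
    fc_l3 = tbl$fc_l4, p_l3 = tbl$p_l4,
    fc_l4 = tbl$fc_l3, p_l4 = tbl$p_l3,
    fc_l4vl3 = -tbl$fc_l4vl3, p_l4vl3 = tbl$p_l4vl3)
  a <- classify_genes(tbl)
  b <- classify_genes(swapped)
  expect_identical(a$perturbed_l3, b$perturbed_l4)
  expect_identical(a$perturbed_l4, b$perturbed_l3)
  expect_identical(a$category == "reciprocal", b$category == "reciprocal")
  expect_identical(a$category == "l4_unique", b$category == "l3_unique")
})

test_that("categories partition the genes and regions conserve the significant total", {
  set.seed(23)
  n <- 500
  tbl <- data.frame(
    gene = sprintf("g%d", 1:n), cell_type = sample(c("M1", "M2"), n, TRUE),
    fc_l3 = signed_fc(rnorm(n, 0, 1.5)), p_l3 = runif(n),
    fc_l4 = signed_fc(rnorm(n, 0, 1.5)), p_l4 = runif(n),
    fc_l4vl3 = signed_fc(rnorm(n, 0, 1.5)), p_l4vl3 = runif(n))
  cl <- classify_genes(tbl)
  s <- summarize_classes(cl)
  for (ct in names(s$per_cell_type)) {
    x <- s$per_cell_type[[ct]]
    expect_equal(sum(x$category_counts), x$n_genes)
    expect_equal(sum(x$region_counts) - x$region_counts[["none"]],
                 x$n_significant)
  }
  expect_true(all(cl$category != "other"))
  # classification invariant: direction 0 iff tier null
  expect_identical(cl$dir_l3 == "0", cl$tier_l3 == "null")
  expect_identical(cl$dir_l4 == "0", cl$tier_l4 == "null")
  # reciprocal implies both perturbed in opposite directions
  rec <- cl[cl$category == "reciprocal", ]
  expect_true(all(rec$perturbed_l3 & rec$perturbed_l4))
  expect_true(all(rec$dir_l3 != rec$dir_l4 & rec$dir_l3 != "0" &
                    rec$dir_l4 != "0"))
})

test_that("two_set_venn partitions the union", {
  v <- two_set_venn(c("a", "b", "c"), c("x", "y"))
  expect_equal(lengths(v), c(unique_a = 3, unique_b = 2, common = 0))
  v2 <- two_set_venn(c("a", "b"), c("a", "b"))
  expect_equal(lengths(v2), c(unique_a = 0, unique_b = 0, common = 2))
  set.seed(4)
  for (i in 1:10) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    v <- two_set_venn(a, b)
    expect_setequal(c(v$unique_a, v$unique_b, v$common), union(a, b))
    expect_length(intersect(v$unique_a, v$common), 0)
    expect_length(intersect(v$unique_b, v$common), 0)
    expect_equal(length(v$common), length(intersect(unique(a), unique(b))))
  }
})

test_that("summarize_classes on an empty classification returns zero totals", {
  s <- summarize_classes(classify_genes(data.frame(
    gene = character(), cell_type = character(), fc_l3 = numeric(),
    p_l3 = numeric(), fc_l4 = numeric(), p_l4 = numeric(),
    fc_l4vl3 = numeric(), p_l4vl3 = numeric())))
  expect_equal(s$totals$reciprocal_total, 0)
  expect_equal(length(s$per_cell_type), 0)
})
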