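# Independent oracle implementations used to check the package's core
# computations. These deliberately share no code with the package:
# brute-force enumeration, literal decision tables, and step-by-step
# formula transcriptions.

# Conditional NB split test by direct pmf enumeration via gamma
# functions: P(Y = y | Y + Z = t) with Y ~ NB(size ra), Z ~ NB(size rb)
# and a common (cancelling) probability parameter.
oracle_nb_split_p <- function(ya, yb, n_a, n_b, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  y <- 0:t
  if (phi == 0) {
    logw <- lchoose(t, y) + y * log(n_a / (n_a + n_b)) +
      (t - y) * log(n_b / (n_a + n_b))
  } else {
    ra <- n_a / phi
    rb <- n_b / phi
    logw <- lgamma(y + ra) - lgamma(y + 1) - lgamma(ra) +
      lgamma(t - y + rb) - lgamma(t - y + 1) - lgamma(rb)
  }
  w <- exp(logw - max(logw))
  p <- w / sum(w)
  sum(p[p <= p[ya + 1] * (1 + 1e-7)])
}

# Literal transcription of the perturbation decision table. X is the
# interferon being judged, Y the other one. rel is "same", "opposite"
# or "none" (at least one direction undefined).
oracle_perturbed <- function(tier_x, tier_y, rel) {
  if (tier_x == "strong") return(TRUE)
  if (tier_x == "moderate") return(TRUE)
  if (tier_x == "null") return(FALSE)
  # tier_x == "weak"
  if (tier_y == "moderate" && rel == "same") return(TRUE)
  if (tier_y == "weak" && rel == "opposite") return(TRUE)
  FALSE
}

oracle_category <- function(p3, p4, rel) {
  if (p3 && p4 && rel == "opposite") return("reciprocal")
  if (p3 && p4 && rel == "same") return("same_direction")
  if (p4 && !p3) return("l4_unique")
  if (p3 && !p4) return("l3_unique")
  if (!p3 && !p4) return("unperturbed_both")
  "other"
}

# Step-by-step trimmed weighted mean of M-values for one sample
# against a reference, transcribing the published formulas with
# order/position logic instead of ranks.
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * (log2(obs / n_obs) + log2(ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  cut_m <- floor(0.30 * n)
  cut_a <- floor(0.05 * n)
  pos_m <- order(order(m))   # position of each gene in the sorted M
  pos_a <- order(order(a))
  keep <- pos_m > cut_m & pos_m <= n - cut_m &
    pos_a > cut_a & pos_a <= n - cut_a
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

oracle_tmm_factors <- function(counts, reference) {
  lib <- colSums(counts)
  f <- sapply(seq_len(ncol(counts)), function(j) {
    oracle_tmm_pair(counts[, j], counts[, reference], lib[j],
                    lib[reference])
  })
  f / exp(mean(log(f)))
}

# Small deterministic count matrix with one inflated gene, used by
# several normalization tests.
toy_counts <- function() {
  m <- matrix(c(100, 200, 300, 400, 500, 600,
                110, 190, 310, 390, 510, 590,
                100, 200, 3000, 400, 500, 600),
              ncol = 3,
              dimnames = list(sprintf("g%d", 1:6), c("s1", "s2", "s3")))
  storage.mode(m) <- "integer"
  m
}

# A tiny complete study design for matrix-level tests: 2 donors, one
# cell type unless both = TRUE.
toy_design <- function(n_donors = 2, both = FALSE) {
  cells <- if (both) c("M1", "M2") else "M1"
  d <- expand.grid(donor = sprintf("d%d", seq_len(n_donors)),
                   cell_type = cells,
                   treatment = c("NT", "IFNL3", "IFNL4"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$sample <- paste(d$cell_type, d$treatment, d$donor, sep = "_")
  d[, c("sample", "donor", "cell_type", "treatment")]
}
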