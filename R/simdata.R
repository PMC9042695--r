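#' Default archetype mixture for simulated genes
#'
#' Proportions of the planted gene archetypes. Most genes are null;
#' the remainder cover the response patterns the classification scheme
#' distinguishes: single-interferon responders in both directions,
#' shared same-direction responders, reciprocally regulated genes
#' (strong opposite effects), weak lambda4 responses shadowed by a
#' moderate or strong lambda3 response, and weak-weak opposite pairs.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_archetype_mix <- function() {
  c(null = 0.55,
    l3_up = 0.05, l3_down = 0.05,
    l4_up = 0.05, l4_down = 0.05,
    shared_same = 0.06,
    reciprocal = 0.07,
    weak_l4_moderate_l3 = 0.05,
    weak_l4_strong_l3 = 0.03,
    weak_weak_opposite = 0.04)
}

#' Simulation configuration
#'
#' Study-shaped negative-binomial count simulation: a full
#' donor x cell type x treatment grid with gene effects planted
#' according to an archetype mixture. Counts for gene g in sample s are
#' NB with mean `baseline_g * 2^lfc(g, cell, treatment) * depth_s` and
#' variance `mu + dispersion * mu^2`. Library depths are drawn
#' log-uniformly over `library_size_range` so that normalization is
#' exercised. In M2 cells the planted lambda4 effects are multiplied by
#' `m2_attenuation`, emulating the higher signaling threshold
#' IFN-lambda4 shows in M2 macrophages.
#'
#' @param n_genes,n_donors Positive integers (4 donors by default).
#' @param cell_types,treatments Factor levels of the design grid.
#' @param baseline_log2_mean Range (log2 counts) for per-gene baseline
#'   means, drawn uniformly.
#' @param dispersion Common NB dispersion phi > 0.
#' @param library_size_range Range of library depths (log-uniform).
#' @param archetype_mix Named proportions over archetypes, summing
#'   to 1.
#' @param effect_sizes Named |log2FC| per tier: must satisfy
#'   strong > moderate > weak > 0.
#' @param m2_attenuation Multiplier applied to lambda4 effects in M2.
#' @param polarization_frac Fraction of genes given an M1-vs-M2
#'   baseline difference, emulating the large constitutive expression
#'   differences between macrophage polarization states.
#' @param polarization_lfc |log2FC| of that baseline difference (sign
#'   drawn per gene).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_donors = 4,
                       cell_types = c("M1", "M2"),
                       treatments = c("NT", "IFNL3", "IFNL4"),
                       baseline_log2_mean = c(4, 9),
                       dispersion = 0.1,
                       library_size_range = c(5e5, 2e6),
                       archetype_mix = default_archetype_mix(),
                       effect_sizes = c(strong = 2, moderate = 1,
                                        weak = 0.35),
                       m2_attenuation = 0.25,
                       polarization_frac = 0.3,
                       polarization_lfc = 2,
                       seed = 1) {
  if (n_genes < 1 || n_donors < 1)
    stop("n_genes and n_donors must be positive")
  if (length(dispersion) != 1 || is.na(dispersion) || dispersion <= 0)
    stop("dispersion must be a single positive number")
  known <- names(default_archetype_mix())
  if (is.null(names(archetype_mix)) ||
      !all(names(archetype_mix) %in% known))
    stop("unknown archetype in mix; allowed: ",
         paste(known, collapse = ", "))
  if (any(archetype_mix < 0) || abs(sum(archetype_mix) - 1) > 1e-9)
    stop("archetype_mix proportions must be nonnegative and sum to 1")
  es <- effect_sizes
  if (!all(c("strong", "moderate", "weak") %in% names(es)) ||
      !(es[["strong"]] > es[["moderate"]] &&
        es[["moderate"]] > es[["weak"]] && es[["weak"]] > 0))
    stop("effect sizes must satisfy strong > moderate > weak > 0")
  if (library_size_range[1] <= 0 ||
      library_size_range[2] < library_size_range[1])
    stop("malformed library_size_range")
  structure(list(n_genes = as.integer(n_genes),
                 n_donors = as.integer(n_donors),
                 cell_types = cell_types, treatments = treatments,
                 baseline_log2_mean = baseline_log2_mean,
                 dispersion = dispersion,
                 library_size_range = library_size_range,
                 archetype_mix = archetype_mix,
                 effect_sizes = effect_sizes,
                 m2_attenuation = m2_attenuation,
                 polarization_frac = polarization_frac,
                 polarization_lfc = polarization_lfc,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Planted (lambda3, lambda4) log2 effects for one archetype in one cell
# type, given tier effect sizes, an orientation sign for symmetric
# archetypes, and the lambda4 attenuation factor for that cell type.
archetype_effects <- function(archetype, effect_sizes, orient, l4_scale) {
  s <- effect_sizes[["strong"]]
  m <- effect_sizes[["moderate"]]
  w <- effect_sizes[["weak"]]
  eff <- switch(archetype,
    null = c(0, 0),
    l3_up = c(s, 0), l3_down = c(-s, 0),
    l4_up = c(0, s), l4_down = c(0, -s),
    shared_same = orient * c(s, s),
    reciprocal = orient * c(s, -s),
    weak_l4_moderate_l3 = orient * c(m, w),
    weak_l4_strong_l3 = orient * c(s, w),
    weak_weak_opposite = orient * c(w, -w),
    stop("unknown archetype: ", archetype))
  c(l3 = eff[1], l4 = eff[2] * l4_scale)
}

#' Simulate a full study's worth of counts
#'
#' Draws negative-binomial counts for the complete
#' donor x cell type x treatment grid described by a [sim_config()],
#' with per-gene effects planted according to the archetype mixture.
#' The RNG seed is taken from the config, so a given config always
#' yields the same output (the global RNG state is advanced).
#'
#' @param config A [sim_config()] object.
#' @return List with `counts` (genes x samples integer matrix),
#'   `design` (data frame: `sample`, `donor`, `cell_type`,
#'   `treatment`) and `truth` (data frame per gene and cell type:
#'   `gene`, `cell_type`, `archetype`, `lfc_l3`, `lfc_l4` — the
#'   planted log2 fold changes versus NT).
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("gene%05d", seq_len(config$n_genes))
  design <- expand.grid(
    donor = sprintf("d%d", seq_len(config$n_donors)),
    cell_type = config$cell_types,
    treatment = config$treatments,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$sample <- paste(design$cell_type, design$treatment, design$donor,
                         sep = "_")
  design <- design[, c("sample", "donor", "cell_type", "treatment")]

  mix <- config$archetype_mix
  archetype <- sample(names(mix), config$n_genes, replace = TRUE,
                      prob = mix)
  orient <- sample(c(-1, 1), config$n_genes, replace = TRUE)
  baseline <- 2^stats::runif(config$n_genes,
                             config$baseline_log2_mean[1],
                             config$baseline_log2_mean[2])
  # constitutive M1-vs-M2 expression differences (half the planted
  # |log2FC| applied with opposite signs to the two cell types)
  polarized <- stats::runif(config$n_genes) < config$polarization_frac
  pol_lfc <- ifelse(polarized,
                    sample(c(-1, 1), config$n_genes, replace = TRUE) *
                      config$polarization_lfc / 2, 0)
  lib <- exp(stats::runif(nrow(design),
                          log(config$library_size_range[1]),
                          log(config$library_size_range[2])))
  depth <- lib / exp(mean(log(lib)))

  truth <- do.call(rbind, lapply(config$cell_types, function(ct) {
    l4_scale <- if (ct == "M2") config$m2_attenuation else 1
    eff <- t(vapply(seq_len(config$n_genes), function(g) {
      archetype_effects(archetype[g], config$effect_sizes, orient[g],
                        l4_scale)
    }, numeric(2)))
    data.frame(gene = genes, cell_type = ct, archetype = archetype,
               lfc_l3 = eff[, 1], lfc_l4 = eff[, 2], row.names = NULL)
  }))

  lfc_lookup <- function(ct, tr) {
    if (tr == "NT") return(rep(0, config$n_genes))
    tt <- truth[truth$cell_type == ct, ]
    if (tr == "IFNL3") tt$lfc_l3 else tt$lfc_l4
  }
  counts <- matrix(0L, nrow = config$n_genes, ncol = nrow(design),
                   dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    pol <- if (design$cell_type[j] == "M1") pol_lfc else -pol_lfc
    mu <- baseline * 2^(lfc_lookup(design$cell_type[j],
                                   design$treatment[j]) + pol) * depth[j]
    counts[, j] <- as.integer(stats::rnbinom(config$n_genes,
                                             size = 1 / config$dispersion,
                                             mu = mu))
  }
  list(counts = counts, design = design, truth = truth)
}

#' Write / read the tab-separated study files
#'
#' Counts are written as a tab-separated matrix with gene rows and a
#' header of sample ids; the design and truth tables as plain
#' tab-separated tables.
#'
#' @param counts,design Study objects as produced by
#'   [simulate_counts()].
#' @param path File path.
#' @return `read_counts` returns the integer matrix; `read_design` the
#'   design data frame; the writers return their path invisibly.
#' @name study_io
NULL

#' @rdname study_io
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  check_count_matrix(m)
}

#' @rdname study_io
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_design <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
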