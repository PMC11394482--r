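# Differential expression by plain two-sample t-tests on log2 values,
# uncorrected at alpha = 0.05 — the study's basal statistical rule. No
# moderation or shrinkage by design; multiplicity is handled only at the
# enrichment stage.

#' Differential-expression configuration
#'
#' @param alpha Significance level (default 0.05; p-values are *not*
#'   corrected for multiple testing at this stage).
#' @param test `"welch"` (unequal-variance, default) or `"student"`
#'   (pooled-variance) two-sample t-test.
#' @param log2fc_min Minimum absolute log2 fold change required for
#'   significance (default 0: direction only).
#' @param normalization `"median_center"`, `"library_size"` or `"none"`.
#' @return A `de_config` list.
#' @export
de_config <- function(alpha = 0.05, test = c("welch", "student"),
                      log2fc_min = 0,
                      normalization = c("median_center", "library_size", "none")) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_cmpn("`alpha` must be in (0, 1)", "invalid_config")
  }
  if (log2fc_min < 0) stop_cmpn("`log2fc_min` must be >= 0", "invalid_config")
  structure(list(alpha = alpha, test = match.arg(test),
                 log2fc_min = log2fc_min,
                 normalization = match.arg(normalization)),
            class = "de_config")
}

#' Normalize an abundance matrix
#'
#' `median_center` divides each sample by `2^median(log2 value)` so every
#' sample's log2 median is 0 (zeros/NAs excluded from the median);
#' `library_size` rescales each column to the mean column sum; `none`
#' returns the input unchanged.
#'
#' @param mat Abundance tibble (`feature_id` + sample columns).
#' @param method `"median_center"`, `"library_size"` or `"none"`.
#' @return Normalized abundance tibble with ids unchanged.
#' @export
normalize_abundance <- function(mat, method = c("median_center",
                                                "library_size", "none")) {
  method <- match.arg(method)
  if (method == "none") return(mat)
  m <- tibble_to_matrix(mat)
  if (method == "median_center") {
    med <- apply(m, 2, function(x) {
      x <- x[!is.na(x) & x > 0]
      median(log2(x))
    })
    m <- sweep(m, 2, 2^med, "/")
  } else {
    libs <- colSums(m, na.rm = TRUE)
    if (any(libs == 0)) {
      stop_cmpn(paste0("all-zero sample column(s): ",
                       paste(colnames(m)[libs == 0], collapse = ", ")),
                "zero_library")
    }
    m <- sweep(m, 2, mean(libs) / libs, "*")
  }
  matrix_to_tibble(m)
}

#' Call differentially expressed features between two sample groups
#'
#' Two-sided two-sample t-test on log2-transformed values per feature, no
#' multiple-testing correction. Counts get a pseudo-count of 1 before log2;
#' proteomic zeros are treated as missing for that feature/sample pair.
#' Fold change is the difference of group means of log2 values
#' (group B over group A).
#'
#' @param mat Abundance tibble (`feature_id` + sample columns).
#' @param group_a,group_b Character vectors of sample ids; disjoint, each of
#'   size >= 2.
#' @param config A [de_config()].
#' @param modality `"proteomic"` (zeros treated as missing) or `"rna"`
#'   (pseudo-count of 1).
#' @return A `de_result` tibble: `feature_id`, `log2fc`, `t_stat`,
#'   `p_value`, `direction` (`"up"`/`"down"`), `significant`
#'   (`p < alpha` and `|log2fc| >= log2fc_min`).
#' @examples
#' mat <- tibble::tibble(feature_id = "f1",
#'                       a1 = 2, a2 = 4, a3 = 8, b1 = 16, b2 = 32, b3 = 64)
#' call_de(mat, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
#'         de_config(test = "student"), modality = "rna")
#' @export
call_de <- function(mat, group_a, group_b, config = de_config(),
                    modality = c("proteomic", "rna")) {
  modality <- match.arg(modality)
  stopifnot(inherits(config, "de_config"))
  if (length(intersect(group_a, group_b)) > 0) {
    stop_cmpn("groups must be disjoint", "invalid_groups")
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_cmpn("each group needs at least 2 samples", "invalid_groups")
  }
  missing <- setdiff(c(group_a, group_b), names(mat))
  if (length(missing)) {
    stop_cmpn(paste0("unknown sample id(s): ", paste(missing, collapse = ", ")),
              "invalid_groups")
  }
  m <- tibble_to_matrix(mat)
  if (modality == "rna") {
    lm2 <- log2(m + 1)
  } else {
    m[m == 0] <- NA_real_
    lm2 <- log2(m)
  }
  a <- lm2[, group_a, drop = FALSE]
  b <- lm2[, group_b, drop = FALSE]

  na_count <- function(x) rowSums(!is.na(x))
  n_a <- na_count(a); n_b <- na_count(b)
  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  var_a <- apply(a, 1, stats::var, na.rm = TRUE)
  var_b <- apply(b, 1, stats::var, na.rm = TRUE)
  diff <- mean_b - mean_a

  if (config$test == "welch") {
    se2 <- var_a / n_a + var_b / n_b
    df <- se2^2 / ((var_a / n_a)^2 / (n_a - 1) + (var_b / n_b)^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * var_a + (n_b - 1) * var_b) / (n_a + n_b - 2)
    se2 <- sp2 * (1 / n_a + 1 / n_b)
    df <- n_a + n_b - 2
  }
  t_stat <- diff / sqrt(se2)
  p <- 2 * pt(abs(t_stat), df, lower.tail = FALSE)

  # degenerate variance: identical constant groups -> null (p = 1);
  # separated constant groups -> certain difference (p -> 0)
  zero_se <- !is.na(se2) & se2 == 0
  t_stat[zero_se & diff == 0] <- 0
  p[zero_se & diff == 0] <- 1
  p[zero_se & diff != 0] <- 0
  # insufficient observations (proteomic missingness): untestable
  untestable <- n_a < 2 | n_b < 2
  t_stat[untestable] <- NA_real_
  p[untestable] <- NA_real_

  res <- tibble(
    feature_id = rownames(m),
    log2fc = unname(diff),
    t_stat = unname(t_stat),
    p_value = unname(p),
    direction = unname(ifelse(diff > 0, "up", "down")),
    significant = unname(!is.na(p) & p < config$alpha &
                           abs(diff) >= config$log2fc_min)
  )
  class(res) <- c("de_result", class(res))
  attr(res, "config") <- config
  res
}

#' Split a DE result into up / down / all-significant feature sets
#'
#' @param results A `de_result` tibble from [call_de()].
#' @return Named list of character vectors `up`, `down`, `all_significant`;
#'   `up` and `down` partition `all_significant`.
#' @export
de_sets <- function(results) {
  if (nrow(results) == 0) stop_cmpn("empty DE result", "invalid_input")
  sig <- results[results$significant, ]
  list(
    up = sig$feature_id[sig$direction == "up"],
    down = sig$feature_id[sig$direction == "down"],
    all_significant = sig$feature_id
  )
}

#' Select sample ids from a design sheet
#'
#' Convenience selector for building DE contrasts.
#'
#' @param design Design tibble (`sample_id`, `genotype`, `treatment`, ...).
#' @param genotype,treatment Optional values to filter on.
#' @return Character vector of sample ids.
#' @export
design_samples <- function(design, genotype = NULL, treatment = NULL) {
  keep <- rep(TRUE, nrow(design))
  if (!is.null(genotype)) keep <- keep & design$genotype %in% genotype
  if (!is.null(treatment)) keep <- keep & design$treatment %in% treatment
  design$sample_id[keep]
}

#' Export tables for volcano and heatmap plotting
#'
#' @param results A `de_result` tibble.
#' @return `volcano_table()`: tibble of `feature_id`, `log2fc`,
#'   `neg_log10_p`, `significant`.
#' @export
volcano_table <- function(results) {
  tibble(feature_id = results$feature_id,
         log2fc = results$log2fc,
         neg_log10_p = -log10(results$p_value),
         significant = results$significant)
}

#' Z-scored group-mean table for heatmap export
#'
#' @param mat Abundance tibble.
#' @param design Design tibble.
#' @param features Feature ids to include.
#' @param modality `"proteomic"` or `"rna"`.
#' @return Tibble of per-feature z-scored log2 group means, one column per
#'   genotype-by-treatment cell.
#' @export
heatmap_table <- function(mat, design, features,
                          modality = c("proteomic", "rna")) {
  modality <- match.arg(modality)
  m <- tibble_to_matrix(mat)[features, , drop = FALSE]
  lm2 <- if (modality == "rna") log2(m + 1) else {
    m[m == 0] <- NA_real_
    log2(m)
  }
  cells <- split(design$sample_id,
                 paste(design$genotype, design$treatment, sep = "."))
  means <- vapply(cells, function(s) rowMeans(lm2[, s, drop = FALSE],
                                              na.rm = TRUE),
                  numeric(length(features)))
  if (length(features) == 1) means <- matrix(means, nrow = 1,
                                             dimnames = list(features, names(cells)))
  z <- t(scale(t(means)))
  as_tibble(z, rownames = "feature_id")
}
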