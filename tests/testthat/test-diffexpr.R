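make_mat <- function(values) {
  # values: named list sample -> numeric vector (one entry per feature)
  tbl <- tibble::tibble(feature_id = sprintf("f%02d",
                                             seq_along(values[[1]])))
  dplyr::bind_cols(tbl, tibble::as_tibble(values))
}

test_that("normalization satisfies its defining identities", {
  mat <- make_mat(list(s1 = c(2, 8, 32), s2 = c(8, 32, 128)))
  expect_identical(normalize_abundance(mat, "none"), mat)

  # per-sample log2 medians become 0 under median centering
  cen <- normalize_abundance(mat, "median_center")
  m <- as.matrix(cen[-1])
  expect_equal(apply(log2(m), 2, median), c(s1 = 0, s2 = 0))

  # library-size columns are rescaled to the mean library size
  mat2 <- make_mat(list(s1 = c(40, 60), s2 = c(100, 200)))
  lib <- normalize_abundance(mat2, "library_size")
  expect_equal(unname(colSums(as.matrix(lib[-1]))), c(200, 200))

  mat3 <- make_mat(list(s1 = c(1, 2), s2 = c(0, 0)))
  err <- expect_error(normalize_abundance(mat3, "library_size"),
                      class = "cmpnomics_zero_library")
  expect_match(conditionMessage(err), "s2")
})

test_that("student t-test matches the closed-form worked example", {
  # groups (1,2,3) vs (4,5,6) on the log2 scale
  mat <- make_mat(list(a1 = 2^1, a2 = 2^2, a3 = 2^3,
                       b1 = 2^4, b2 = 2^5, b3 = 2^6))
  res <- call_de(mat, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                 de_config(test = "student"), modality = "proteomic")
  expect_equal(abs(res$t_stat), 3.674, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0214, tolerance = 1e-2)
  expect_equal(res$p_value,
               stats::t.test(1:3, 4:6, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
  expect_equal(res$log2fc, 3)
  expect_true(res$significant)
  expect_identical(res$direction, "up")
})

test_that("identical groups give t = 0, p = 1, not significant", {
  mat <- make_mat(list(a1 = c(4, 7), a2 = c(8, 9), a3 = c(16, 11),
                       b1 = c(4, 7), b2 = c(8, 9), b3 = c(16, 11)))
  res <- call_de(mat, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                 de_config(test = "student"))
  expect_equal(res$t_stat, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
  expect_false(any(res$significant))

  # zero within-group variance, equal means -> p = 1 by convention
  con <- make_mat(list(a1 = 4, a2 = 4, b1 = 4, b2 = 4))
  res2 <- call_de(con, c("a1", "a2"), c("b1", "b2"), de_config())
  expect_equal(res2$p_value, 1)
})

test_that("group preconditions are enforced", {
  mat <- make_mat(list(a1 = 1:3, a2 = 1:3, b1 = 1:3, b2 = 1:3))
  expect_error(call_de(mat, c("a1", "a2"), c("a2", "b1"), de_config()),
               class = "cmpnomics_invalid_groups")
  expect_error(call_de(mat, "a1", c("b1", "b2"), de_config()),
               class = "cmpnomics_invalid_groups")
  expect_error(call_de(mat, c("a1", "zz"), c("b1", "b2"), de_config()),
               class = "cmpnomics_invalid_groups")
  expect_error(de_config(alpha = 1.5), class = "cmpnomics_invalid_config")
})

test_that("student p-values agree with stats::t.test on random instances", {
  withr::local_seed(42)
  for (i in 1:100) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    va <- rnorm(na, sd = runif(1, 0.5, 2))
    vb <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    vals <- as.list(2^c(va, vb))
    names(vals) <- c(sprintf("a%d", seq_len(na)), sprintf("b%d", seq_len(nb)))
    mat <- make_mat(vals)
    for (tst in c("student", "welch")) {
      res <- call_de(mat, names(vals)[seq_len(na)],
                     names(vals)[na + seq_len(nb)],
                     de_config(test = tst), modality = "proteomic")
      ref <- stats::t.test(vb, va, var.equal = (tst == "student"))
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
      expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-10)
    }
  }
})

test_that("rna counts get a pseudo-count and proteomic zeros become missing", {
  mat <- make_mat(list(a1 = c(0, 3), a2 = c(0, 3), a3 = c(0, 3),
                       b1 = c(7, 3), b2 = c(7, 3), b3 = c(7, 3)))
  res <- call_de(mat, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                 de_config(), modality = "rna")
  expect_equal(res$log2fc[1], log2(8) - log2(1))
  # proteomic: an all-zero group is untestable, reported NA
  resp <- call_de(mat, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                  de_config(), modality = "proteomic")
  expect_true(is.na(resp$p_value[1]))
  expect_false(resp$significant[1])
})

test_that("de_sets partitions significant features by direction", {
  res <- structure(
    tibble::tibble(
      feature_id = c("a", "b", "c", "d"),
      log2fc = c(2, -1, 3, 0.5), t_stat = c(5, -4, 6, 1),
      p_value = c(0.01, 0.02, 0.001, 0.5),
      direction = c("up", "down", "up", "up"),
      significant = c(TRUE, TRUE, TRUE, FALSE)),
    class = c("de_result", class(tibble::tibble())))
  s <- de_sets(res)
  expect_setequal(s$up, c("a", "c"))
  expect_setequal(s$down, "b")
  expect_setequal(s$all_significant, union(s$up, s$down))
  expect_length(intersect(s$up, s$down), 0)
})

test_that("recovered planted features carry the planted sign", {
  sim <- generate_omics(experiment_config(
    n_features_protein = 600, n_features_rna = 50, effect_log2fc = 2,
    frac_treatment_de = 0.1, seed = 31))
  res <- call_de(sim$proteomic,
                 design_samples(sim$design, "WT", "VEH"),
                 design_samples(sim$design, "WT", "PRG_MIF"),
                 de_config())
  tde <- sim$ground_truth$treatment_de
  tde <- tde[tde$modality == "proteomic" & tde$genotype == "WT", ]
  rec <- dplyr::inner_join(tidy(res)[res$significant, ], tde,
                           by = "feature_id")
  expect_gt(nrow(rec), 0)
  expect_true(all(ifelse(rec$sign > 0, "up", "down") == rec$direction))
})

test_that("type-I error is controlled at the nominal level on null data", {
  sim <- generate_omics(experiment_config(
    n_features_protein = 3000, n_features_rna = 50,
    frac_genotype_de = 0, frac_treatment_de = 0, seed = 101))
  res <- call_de(sim$proteomic,
                 design_samples(sim$design, "KO", "VEH"),
                 design_samples(sim$design, "KO", "PRG_MIF"),
                 de_config(test = "student"))
  rate <- mean(res$p_value < 0.05)
  half_width <- 2.576 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(rate - 0.05), half_width)
})

test_that("planted-effect recovery is monotone in effect size and replicates", {
  recovery <- function(effect, reps, seed = 77) {
    sim <- generate_omics(experiment_config(
      n_features_protein = 500, n_features_rna = 50,
      effect_log2fc = effect, replicates = reps,
      frac_treatment_de = 0.2, seed = seed))
    res <- call_de(sim$proteomic,
                   design_samples(sim$design, "KO", "VEH"),
                   design_samples(sim$design, "KO", "PRG_MIF"),
                   de_config())
    tde <- sim$ground_truth$treatment_de
    planted <- tde$feature_id[tde$modality == "proteomic" &
                                tde$genotype == "KO"]
    mean(res$significant[res$feature_id %in% planted])
  }
  by_effect <- vapply(c(0.25, 1, 3), recovery, numeric(1), reps = 3)
  expect_true(all(diff(by_effect) >= 0))
  by_reps <- vapply(c(2, 4, 12), function(r) recovery(1, r), numeric(1))
  expect_true(all(diff(by_reps) >= 0))
})
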