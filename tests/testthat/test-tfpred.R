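test_that("standardization truncates at the N-terminus and pads with X", {
  rec <- tibble::tibble(
    id = c("keep", "long", "short"),
    sequence = c(strrep("A", 50), paste0(strrep("C", 60), strrep("D", 20)),
                 "MKVLA"),
    label = c("TF", "NTF", NA))
  out <- standardize_seqs(rec, 50)
  expect_equal(nchar(out$sequence), rep(50, 3))
  expect_equal(out$sequence[1], rec$sequence[1])          # identity
  expect_equal(out$sequence[2], strrep("C", 50))          # prefix rule
  expect_equal(out$sequence[3], paste0("MKVLA", strrep("X", 45)))
  expect_equal(out$id, rec$id)
  expect_equal(out$label, rec$label)

  bad <- tibble::tibble(id = "empty", sequence = "", label = NA)
  err <- expect_error(standardize_seqs(bad, 10),
                      class = "cmpnomics_empty_sequence")
  expect_match(conditionMessage(err), "empty")
})

test_that("built-in featurizer is deterministic, normalized and composition-aware", {
  rec <- tibble::tibble(id = c("a", "b", "c"),
                        sequence = c("AAAA", "AAAA", "CCCC"),
                        label = c("TF", "TF", "NTF"))
  emb <- featurize(rec)
  expect_equal(ncol(emb), 421)  # id + 20 composition + 400 k-mer buckets
  v <- as.matrix(emb[-1])
  # identical sequences give identical vectors; different ones differ
  expect_equal(v[1, ], v[2, ])
  expect_false(isTRUE(all.equal(v[1, ], v[3, ])))
  # L2 norm 1
  expect_equal(unname(sqrt(rowSums(v^2))), rep(1, 3), tolerance = 1e-12)
  # "AAAA": composition weight only on A
  comp <- v[1, 1:20]
  expect_true(comp[1] > 0)
  expect_equal(unname(comp[2:20]), rep(0, 19))
  # padding X carries no signal: "AA" padded still has A-only composition
  padded <- featurize(standardize_seqs(
    tibble::tibble(id = "p", sequence = "AAAA", label = NA), 100))
  expect_equal(as.numeric(padded[1, 2:21]), as.numeric(emb[1, 2:21]))
})

test_that("external embedding tables are validated and passed through", {
  rec <- tibble::tibble(id = c("a", "b"), sequence = c("AA", "CC"),
                        label = c("TF", "NTF"))
  ext <- tibble::tibble(id = c("b", "a"), v1 = c(1, 2), v2 = c(3, 4))
  out <- featurize(rec, backend = "external_table", external = ext)
  expect_equal(out$id, c("a", "b"))  # reordered to match records
  expect_equal(out$v1, c(2, 1))
  expect_error(featurize(rec, backend = "external_table",
                         external = ext[ext$id == "a", ]),
               class = "cmpnomics_missing_embedding")
  bad <- tibble::tibble(id = c("a", "b"), v1 = c("x", "y"))
  expect_error(featurize(rec, backend = "external_table", external = bad),
               class = "cmpnomics_bad_embedding")
})

test_that("class costs are inversely proportional to class frequency", {
  bal <- class_costs(rep(c("TF", "NTF"), each = 10))
  expect_equal(unname(bal["TF"]), unname(bal["NTF"]))

  paper <- class_costs(rep(c("NTF", "TF"), c(2784, 954)))
  expect_equal(unname(paper["TF"] / paper["NTF"]), 2784 / 954,
               tolerance = 1e-12)
  expect_equal(unname(paper["TF"] / paper["NTF"]), 2.918, tolerance = 1e-3)

  nine <- class_costs(rep(c("maj", "min"), c(90, 10)))
  expect_equal(unname(nine["min"] / nine["maj"]), 9)
  # cost(c) = total / (n_classes * count(c))
  expect_equal(unname(nine["maj"]), 100 / (2 * 90))

  expect_error(class_costs(rep("TF", 5)), class = "cmpnomics_single_class")
})

test_that("confusion metrics satisfy their defining identities", {
  m <- cmpnomics:::confusion_metrics(40, 20, 80, 10)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$balanced_accuracy, 0.8)
  expect_equal(m$f1, 80 / 110)

  withr::local_seed(3)
  for (i in 1:200) {
    cm <- sample(0:50, 4, replace = TRUE) + 1
    m <- cmpnomics:::confusion_metrics(cm[1], cm[2], cm[3], cm[4])
    expect_equal(m$sensitivity, cm[1] / (cm[1] + cm[4]))
    expect_equal(m$specificity, cm[3] / (cm[3] + cm[2]))
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    expect_equal(m$f1, 2 * cm[1] / (2 * cm[1] + cm[2] + cm[4]))
    expect_true(all(unlist(m[c("f1", "specificity", "sensitivity",
                               "balanced_accuracy")]) >= 0))
    expect_true(all(unlist(m[c("f1", "specificity", "sensitivity",
                               "balanced_accuracy")]) <= 1))
  }
})

test_that("stratified folds are balanced, seeded and reproducible", {
  labels <- rep(c("TF", "NTF"), c(30, 70))
  f1 <- cmpnomics:::stratified_folds(labels, 5, 42)
  f2 <- cmpnomics:::stratified_folds(labels, 5, 42)
  expect_identical(f1, f2)
  expect_false(identical(f1, cmpnomics:::stratified_folds(labels, 5, 43)))
  per_fold_tf <- table(f1[labels == "TF"])
  expect_true(max(per_fold_tf) - min(per_fold_tf) <= 1)
})

test_that("perfectly separable clusters give perfect per-fold metrics", {
  withr::local_seed(8)
  fx <- cluster_embeddings(40, 60, sep = 30, sd = 0.5)
  rep <- cross_validate(fx$records, fx$embeddings,
                        cv_config(folds = 5, seed = 4))
  metrics <- rep$per_fold[c("f1", "specificity", "sensitivity",
                            "balanced_accuracy")]
  expect_true(all(as.matrix(metrics) == 1))
  # every TF is a consensus candidate, no NTF is
  expect_setequal(rep$candidates, fx$records$id[fx$records$label == "TF"])
})

test_that("cross-validation refuses degenerate inputs", {
  withr::local_seed(9)
  fx <- cluster_embeddings(3, 50, sep = 5)
  expect_error(cross_validate(fx$records, fx$embeddings,
                              cv_config(folds = 10, seed = 1)),
               class = "cmpnomics_too_few_per_class")
  one <- fx$records; one$label <- "NTF"
  expect_error(cross_validate(one, fx$embeddings, cv_config(seed = 1)),
               class = "cmpnomics_single_class")
})

test_that("cross-validation is deterministic under a fixed seed", {
  withr::local_seed(10)
  fx <- cluster_embeddings(20, 40, sep = 1, sd = 1.5)
  a <- cross_validate(fx$records, fx$embeddings, cv_config(folds = 4, seed = 5))
  b <- cross_validate(fx$records, fx$embeddings, cv_config(folds = 4, seed = 5))
  expect_identical(a$per_fold, b$per_fold)
  expect_identical(a$consensus, b$consensus)
})

test_that("permuted labels yield chance-level balanced accuracy", {
  means <- numeric(20)
  for (s in 1:20) {
    means[s] <- withr::with_seed(s, {
      fx <- cluster_embeddings(50, 50, sep = 0)  # no signal at all
      rep <- cross_validate(fx$records, fx$embeddings,
                            cv_config(folds = 5, seed = s))
      rep$means$balanced_accuracy
    })
  }
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * se + 1e-8)
})

test_that("inverse-frequency costs protect minority-class sensitivity", {
  diffs <- numeric(10)
  for (s in 1:10) {
    diffs[s] <- withr::with_seed(100 + s, {
      fx <- cluster_embeddings(25, 225, sep = 1.1, sd = 1)
      sens <- function(mode) {
        cross_validate(fx$records, fx$embeddings,
                       cv_config(folds = 5, seed = s,
                                 cost_mode = mode))$means$sensitivity
      }
      sens("inverse_frequency") - sens("uniform")
    })
  }
  expect_gte(mean(diffs), 0)
})

test_that("consensus candidate calling applies the >= threshold rule", {
  report <- structure(list(
    consensus = tibble::tibble(id = c("a", "b", "c"),
                               label = c("TF", "TF", "NTF"),
                               tf_fraction = c(0.6, 0.4, 0)),
    config = cv_config(consensus_threshold = 0.5)),
    class = "cv_report")
  expect_equal(consensus_candidates(report), "a")
  # boundary: a fraction exactly at the threshold is included
  report$consensus$tf_fraction[2] <- 0.5
  expect_equal(consensus_candidates(report), c("a", "b"))
  # zero fraction excluded at any positive threshold
  expect_false("c" %in% consensus_candidates(report, 0.01))
  expect_error(consensus_candidates(report, 0),
               class = "cmpnomics_invalid_config")
})

test_that("motif benchmark at reduced scale is learned accurately", {
  bench <- generate_tf_benchmark(n_tf = 80, n_ntf = 240,
                                 length_range = c(80, 150),
                                 motif = "CKRPLHC", seed = 17)
  std <- standardize_seqs(bench, 200)
  emb <- featurize(std)
  rep <- cross_validate(std, emb, cv_config(folds = 5, standard_length = 200,
                                            seed = 17))
  expect_gt(rep$means$balanced_accuracy, 0.9)
})
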