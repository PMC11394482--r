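# Cost-sensitive SVM transcription-factor predictor: fixed-length sequence
# standardization (N-terminal truncation / C-terminal X padding to 1000
# residues), pluggable per-sequence embeddings (built-in k-mer featurizer
# or an external table, e.g. protein-language-model encodings), inverse-
# frequency class costs, stratified k-fold cross-validation with confusion-
# matrix metrics, and consensus candidate calling across held-out
# evaluations.

#' Cross-validation configuration for the TF predictor
#'
#' @param folds Number of stratified CV folds (default 10).
#' @param standard_length Fixed sequence length after truncation/padding
#'   (default 1000 residues).
#' @param kernel SVM kernel, `"linear"` (default) or `"rbf"`.
#' @param cost_mode `"inverse_frequency"` (default; misclassification cost
#'   per class inversely proportional to class frequency) or `"uniform"`.
#' @param seed Integer seed for fold assignment.
#' @param consensus_threshold Minimum fraction of held-out evaluations
#'   predicting TF for a consensus call (default 0.5; the boundary is
#'   inclusive).
#' @param repeats Number of repeated CV rounds the consensus fraction is
#'   averaged over (default 1).
#' @param svm_cost SVM regularization constant C (default 1).
#' @return A `cv_config` list.
#' @export
cv_config <- function(folds = 10, standard_length = 1000,
                      kernel = c("linear", "rbf"),
                      cost_mode = c("inverse_frequency", "uniform"),
                      seed = 1L, consensus_threshold = 0.5, repeats = 1,
                      svm_cost = 1) {
  assert_count(folds, "folds", min = 2)
  assert_count(standard_length, "standard_length", min = 1)
  assert_count(repeats, "repeats", min = 1)
  if (consensus_threshold <= 0 || consensus_threshold > 1) {
    stop_cmpn("`consensus_threshold` must be in (0, 1]", "invalid_config")
  }
  structure(list(folds = as.integer(folds),
                 standard_length = as.integer(standard_length),
                 kernel = match.arg(kernel),
                 cost_mode = match.arg(cost_mode),
                 seed = as.integer(seed),
                 consensus_threshold = consensus_threshold,
                 repeats = as.integer(repeats),
                 svm_cost = svm_cost),
            class = "cv_config")
}

#' Standardize sequences to a fixed length
#'
#' Longer sequences keep their first `length` residues (N-terminus);
#' shorter sequences are padded at the C-terminus with the neutral symbol
#' `X`.
#'
#' @param records Sequence-set tibble (`id`, `sequence`, `label`).
#' @param length Target length in residues (default 1000).
#' @return The tibble with every sequence exactly `length` residues; ids
#'   and labels unchanged.
#' @export
standardize_seqs <- function(records, length = 1000) {
  assert_count(length, "length", min = 1)
  lens <- nchar(records$sequence)
  if (any(lens == 0)) {
    stop_cmpn(paste0("empty sequence(s): ",
                     paste(records$id[lens == 0], collapse = ", ")),
              "empty_sequence")
  }
  out <- records
  out$sequence <- ifelse(
    lens >= length,
    substr(records$sequence, 1, length),
    paste0(records$sequence,
           strrep("X", pmax(length - lens, 0))))
  out
}

#' Featurize sequences into fixed-dimension embeddings
#'
#' The built-in `kmer_builtin` backend concatenates the 20-dimension
#' amino-acid composition with 3-mer frequencies hashed into 400 buckets,
#' then L2-normalizes; `X` positions (padding/unknown) are skipped. The
#' `external_table` backend passes through precomputed per-sequence
#' vectors (e.g. protein-language-model embeddings) after coverage and
#' dimension checks.
#'
#' @param records Sequence-set tibble.
#' @param backend `"kmer_builtin"` (default) or `"external_table"`.
#' @param external Embedding tibble (`id`, `v1..vd`) when
#'   `backend = "external_table"`.
#' @return Embedding tibble: `id` followed by numeric columns `v1..vd`.
#' @export
featurize <- function(records, backend = c("kmer_builtin", "external_table"),
                      external = NULL) {
  backend <- match.arg(backend)
  if (backend == "external_table") {
    if (is.null(external)) {
      stop_cmpn("external backend requires an embedding table", "missing_table")
    }
    miss <- setdiff(records$id, external$id)
    if (length(miss)) {
      stop_cmpn(paste0("embedding table missing id(s): ",
                       paste(head(miss, 10), collapse = ", ")),
                "missing_embedding")
    }
    dims <- ncol(external) - 1
    if (dims < 1 || !all(purrr::map_lgl(external[-1], is.numeric))) {
      stop_cmpn("external embedding columns must be numeric", "bad_embedding")
    }
    return(external[match(records$id, external$id), ])
  }
  vecs <- t(vapply(records$sequence, kmer_vector, numeric(420),
                   USE.NAMES = FALSE))
  out <- as_tibble(vecs, .name_repair = ~ paste0("v", seq_along(.x)))
  dplyr::bind_cols(tibble(id = records$id), out)
}

# 20-dim composition + 400-bucket hashed 3-mer frequencies, L2-normalized
kmer_vector <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, AA_ALPHABET)  # NA for X / unknown
  comp <- tabulate(idx, nbins = 20)
  n_obs <- sum(comp)
  comp <- if (n_obs > 0) comp / n_obs else comp
  kmer <- numeric(400)
  if (length(idx) >= 3) {
    i1 <- idx[1:(length(idx) - 2)]
    i2 <- idx[2:(length(idx) - 1)]
    i3 <- idx[3:length(idx)]
    code <- (i1 - 1) * 400 + (i2 - 1) * 20 + (i3 - 1)
    code <- code[!is.na(code)]
    if (length(code)) {
      bucket <- code %% 400 + 1
      kmer <- tabulate(bucket, nbins = 400) / length(code)
    }
  }
  v <- c(comp, kmer)
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

#' Inverse-frequency misclassification costs
#'
#' `cost(c) = total / (n_classes * count(c))`; the ratio of class costs
#' equals the inverse ratio of class frequencies, so the minority class is
#' penalized proportionally more when misclassified.
#'
#' @param labels Character/factor vector of class labels (>= 2 classes).
#' @return Named numeric vector of per-class costs.
#' @examples
#' class_costs(rep(c("NTF", "TF"), c(2784, 954)))
#' @export
class_costs <- function(labels) {
  tab <- table(as.character(labels))
  if (length(tab) < 2) {
    stop_cmpn("class costs undefined for single-class input", "single_class")
  }
  costs <- sum(tab) / (length(tab) * as.numeric(tab))
  setNames(costs, names(tab))
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

confusion_metrics <- function(tp, fp, tn, fn) {
  tibble(
    TP = tp, FP = fp, TN = tn, FN = fn,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    balanced_accuracy = (tn / (tn + fp) + tp / (tp + fn)) / 2
  )
}

#' Stratified cross-validation of the cost-sensitive SVM
#'
#' Assigns stratified folds from `config$seed`, trains a support-vector
#' machine with inverse-frequency (or uniform) class costs on each
#' training split, and collects held-out predictions into per-fold
#' confusion matrices and metrics (TF is the positive class). Consensus
#' fractions record, per sequence, the fraction of held-out evaluations
#' (over `repeats` CV rounds) in which it was predicted TF.
#'
#' @param records Sequence-set tibble with labels in `{"TF", "NTF"}`.
#' @param embeddings Embedding tibble from [featurize()] covering all ids.
#' @param config A [cv_config()].
#' @return A `cv_report` object: `per_fold` tibble (repeat, fold, TP, FP,
#'   TN, FN, f1, specificity, sensitivity, balanced_accuracy), `means`
#'   (named list of metric means), `consensus` tibble (`id`, `label`,
#'   `tf_fraction`), `candidates` (ids at or above the consensus
#'   threshold) and `config`.
#' @export
cross_validate <- function(records, embeddings, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  labels <- records$label
  tab <- table(labels)
  if (length(tab) < 2) {
    stop_cmpn("cross-validation needs both classes present", "single_class")
  }
  if (min(tab) < config$folds) {
    stop_cmpn("each class must have at least as many records as folds",
              "too_few_per_class")
  }
  x <- as.matrix(embeddings[match(records$id, embeddings$id), -1])
  y <- factor(labels, levels = c("NTF", "TF"))
  weights <- if (config$cost_mode == "inverse_frequency") {
    class_costs(labels)
  } else {
    setNames(c(1, 1), levels(y))
  }
  kernel <- if (config$kernel == "linear") "linear" else "radial"

  per_fold <- list()
  tf_votes <- matrix(0L, nrow(records), config$repeats,
                     dimnames = list(records$id, NULL))
  for (r in seq_len(config$repeats)) {
    fold <- stratified_folds(labels, config$folds,
                             derive_seed(config$seed, r))
    for (f in seq_len(config$folds)) {
      test <- fold == f
      fit <- e1071::svm(x[!test, , drop = FALSE], y[!test],
                        kernel = kernel, cost = config$svm_cost,
                        class.weights = weights, scale = FALSE)
      pred <- stats::predict(fit, x[test, , drop = FALSE])
      tp <- sum(pred == "TF" & y[test] == "TF")
      fp <- sum(pred == "TF" & y[test] == "NTF")
      tn <- sum(pred == "NTF" & y[test] == "NTF")
      fn <- sum(pred == "NTF" & y[test] == "TF")
      per_fold[[length(per_fold) + 1]] <-
        dplyr::bind_cols(tibble(repeat_ = r, fold = f),
                         confusion_metrics(tp, fp, tn, fn))
      tf_votes[test, r] <- as.integer(pred == "TF")
    }
  }
  per_fold <- bind_rows(per_fold)
  means <- as.list(colMeans(per_fold[c("f1", "specificity", "sensitivity",
                                       "balanced_accuracy")], na.rm = TRUE))
  consensus <- tibble(
    id = records$id, label = labels,
    tf_fraction = rowMeans(tf_votes)
  )
  report <- structure(
    list(per_fold = per_fold, means = means, consensus = consensus,
         candidates = consensus_candidates_impl(consensus,
                                                config$consensus_threshold),
         config = config),
    class = "cv_report")
  report
}

consensus_candidates_impl <- function(consensus, threshold) {
  sort(consensus$id[consensus$tf_fraction >= threshold])
}

#' Consensus TF candidates from a cross-validation report
#'
#' Returns the ids predicted TF in at least `threshold` of held-out
#' evaluations (inclusive boundary: a fraction exactly equal to the
#' threshold is called).
#'
#' @param report A `cv_report` from [cross_validate()].
#' @param threshold Fraction in (0, 1]; defaults to the report's configured
#'   consensus threshold.
#' @return Sorted character vector of candidate ids.
#' @export
consensus_candidates <- function(report, threshold = NULL) {
  stopifnot(inherits(report, "cv_report"))
  threshold <- threshold %||% report$config$consensus_threshold
  if (threshold <= 0 || threshold > 1) {
    stop_cmpn("`threshold` must be in (0, 1]", "invalid_config")
  }
  consensus_candidates_impl(report$consensus, threshold)
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$config$folds, "fold(s) x", x$config$repeats,
      "repeat(s)\n")
  cat(sprintf("  mean F1 %.4f | specificity %.4f | sensitivity %.4f | balanced accuracy %.4f\n",
              x$means$f1, x$means$specificity, x$means$sensitivity,
              x$means$balanced_accuracy))
  cat("  consensus candidates:", length(x$candidates), "\n")
  invisible(x)
}

#' Write a cross-validation report to disk
#'
#' Per-fold metrics as TSV, summary + consensus as JSON, candidates as a
#' one-id-per-line list.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$per_fold, file.path(dir, "cv_folds.tsv"))
  jsonlite::write_json(
    list(means = report$means,
         consensus = report$consensus,
         threshold = report$config$consensus_threshold),
    file.path(dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(report$candidates, file.path(dir, "tf_candidates.txt"))
  invisible(dir)
}
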