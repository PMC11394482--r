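# Gene-set over-representation analysis: upper-tail hypergeometric test
# per term with GeneRatio (k/n over the annotated query), BH adjustment
# within each collection category, and comparative dot-plot tables with
# filter-based term exclusion.

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper: step-up BH (`p_adj(i) = min_{j>=i} p(j) * m / j`,
#' capped at 1), returned in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # 0.03 0.03 0.03
#' @export
bh_adjust <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_cmpn("p-values must lie in [0, 1]", "invalid_p")
  }
  stats::p.adjust(p_values, method = if (method == "BH") "BH" else "bonferroni")
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query hits the term more often than
#' expected under sampling without replacement from the universe:
#' `p_hyper = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`, where `N` is
#' the universe size, `K` the term size within the universe, `n` the number
#' of query features annotated to at least one term, and `k` the query hits
#' in the term. One-sided upper tail only (over-representation). Adjusted
#' p-values are computed per collection category (GO and KEGG separately).
#'
#' @param query Character vector of feature ids; must be a subset of
#'   `universe`.
#' @param universe Character vector: all identified features of the
#'   modality (the background is the identified set, not the genome).
#' @param collection Gene-set collection tibble (see [read_gmt()]); members
#'   are intersected with the universe before testing, and terms left empty
#'   are dropped.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return An `ora_result` tibble sorted by `p_adj` then `term_id`:
#'   `term_id`, `name`, `category`, `k`, `K`, `n`, `N`, `gene_ratio`
#'   (character `"k/n"`), `gene_ratio_num`, `p_hyper`, `p_adj`. Empty query
#'   yields an empty result with a warning.
#' @examples
#' coll <- tibble::tibble(term_id = "T1", name = "t", category = "GO",
#'                        members = list(as.character(1:5)))
#' ora(as.character(1:4), as.character(1:10), coll)
#' @export
ora <- function(query, universe, collection, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  validate_collection(collection)
  if (!all(query %in% universe)) {
    stop_cmpn("query must be a subset of the universe", "query_not_in_universe")
  }
  empty <- tibble(term_id = character(), name = character(),
                  category = character(), k = integer(), K = integer(),
                  n = integer(), N = integer(), gene_ratio = character(),
                  gene_ratio_num = numeric(), p_hyper = numeric(),
                  p_adj = numeric())
  if (length(query) == 0) {
    rlang::warn("empty query; returning empty ORA result")
    attr(empty, "empty_query") <- TRUE
    class(empty) <- c("ora_result", class(empty))
    return(empty)
  }
  members <- purrr::map(collection$members, ~ intersect(.x, universe))
  keep <- lengths(members) > 0
  collection <- collection[keep, ]
  members <- members[keep]
  if (nrow(collection) == 0) {
    class(empty) <- c("ora_result", class(empty))
    return(empty)
  }
  annotated <- unique(unlist(members, use.names = FALSE))
  n <- length(intersect(query, annotated))
  N <- length(universe)
  K <- lengths(members)
  k <- purrr::map_int(members, ~ length(intersect(query, .x)))
  p_hyper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  res <- tibble(
    term_id = collection$term_id, name = collection$name,
    category = collection$category,
    k = as.integer(k), K = as.integer(K), n = as.integer(n), N = as.integer(N),
    gene_ratio = paste0(k, "/", n),
    gene_ratio_num = ifelse(n > 0, k / n, NA_real_),
    p_hyper = p_hyper
  )
  res <- res |>
    group_by(.data$category) |>
    mutate(p_adj = bh_adjust(.data$p_hyper, adjust)) |>
    ungroup() |>
    arrange(.data$p_adj, .data$term_id)
  class(res) <- c("ora_result", class(res))
  res
}

#' Comparative dot-plot table across conditions with term exclusion
#'
#' Integrates per-condition ORA results into one long table (one row per
#' term-by-condition), flags terms hit by any exclusion filter with the
#' filter's name (the "highlighted, then eliminated" convention), and marks
#' terms enriched in more than one condition as shared.
#'
#' @param results Named list of `ora_result` tibbles, one per condition.
#' @param exclusion_filters Named list of character vectors of term ids
#'   (e.g. the CCM1-dosage and non-mPR pathway filters). Default: none.
#' @return A `dotplot_table` tibble: `condition`, `term_id`, `name`,
#'   `category`, `gene_ratio_num`, `p_adj`, `excluded`, `exclusion_reason`,
#'   `shared`.
#' @export
comparative_dotplot <- function(results, exclusion_filters = list()) {
  if (length(results) == 0 || is.null(names(results))) {
    stop_cmpn("`results` must be a non-empty named list", "invalid_input")
  }
  long <- purrr::imap(results, function(res, cond) {
    if (nrow(res) == 0) return(NULL)
    tibble(condition = cond, term_id = res$term_id, name = res$name,
           category = res$category, gene_ratio_num = res$gene_ratio_num,
           p_adj = res$p_adj)
  }) |> bind_rows()
  if (nrow(long) == 0) {
    out <- tibble(condition = character(), term_id = character(),
                  name = character(), category = character(),
                  gene_ratio_num = numeric(), p_adj = numeric(),
                  excluded = logical(), exclusion_reason = character(),
                  shared = logical())
    class(out) <- c("dotplot_table", class(out))
    return(out)
  }
  reason <- rep(NA_character_, nrow(long))
  for (fname in names(exclusion_filters)) {
    hit <- long$term_id %in% exclusion_filters[[fname]] & is.na(reason)
    reason[hit] <- fname
  }
  n_cond <- table(unique(long[c("term_id", "condition")])$term_id)
  long$excluded <- !is.na(reason)
  long$exclusion_reason <- reason
  long$shared <- as.logical(n_cond[long$term_id] > 1)
  class(long) <- c("dotplot_table", class(long))
  long
}

#' Write ORA results / dot-plot tables as TSV
#'
#' @param x An `ora_result` or `dotplot_table` tibble.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_ora_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
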