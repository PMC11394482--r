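# Venn set algebra over families of DEP/DEG sets, with the percentage
# conventions used in the study's printed Venn diagrams (explicit
# denominator, round-half-up to one decimal), and the two-step filtration
# that removes CCM1-dosage-dependent then non-mPR "antagonist" features.

#' Construct a named family of 2 or 3 feature sets
#'
#' @param name Family name.
#' @param members Named list of 2 or 3 character vectors (duplicates within
#'   a set are dropped).
#' @return A `set_family` object.
#' @examples
#' set_family("demo", list(A = c("1", "2", "3"), B = c("2", "3", "4")))
#' @export
set_family <- function(name, members) {
  if (length(members) < 2 || length(members) > 3) {
    stop_cmpn("a set family holds 2 or 3 sets", "invalid_family")
  }
  if (is.null(names(members)) || anyDuplicated(names(members)) ||
      any(!nzchar(names(members)))) {
    stop_cmpn("set labels must be unique and non-empty", "invalid_family")
  }
  members <- purrr::map(members, ~ unique(as.character(.x)))
  structure(list(name = name, members = members), class = "set_family")
}

#' @export
print.set_family <- function(x, ...) {
  cat("<set_family>", x$name, "with", length(x$members), "sets:\n")
  for (lb in names(x$members)) {
    cat("  ", lb, ": ", length(x$members[[lb]]), " ids\n", sep = "")
  }
  invisible(x)
}

# region signatures in stable order: singles, pairs, then the triple
region_signatures <- function(labels) {
  k <- length(labels)
  sigs <- list()
  for (size in seq_len(k)) {
    cmb <- combn(labels, size, simplify = FALSE)
    sigs <- c(sigs, cmb)
  }
  sigs
}

#' Exhaustive Venn partition of a set family
#'
#' Decomposes the family union into its `2^k - 1` disjoint regions and
#' reports, per region, the member ids, count, and percentage of an
#' explicitly supplied denominator. The denominator is a required argument
#' because published Venn percentages use varying bases (total identified
#' features vs filtered totals); it is never inferred. Percentages are
#' rounded half-up to one decimal.
#'
#' @param family A [set_family()].
#' @param denominator Positive count, at least the size of the union.
#' @return A `venn_partition` tibble: `region` (e.g. `"A"`, `"A&B"`),
#'   `labels` (list-column), `count`, `percentage`, `members` (list-column);
#'   regions ordered singles, pairs, triple. The denominator and family
#'   name are attached as attributes.
#' @examples
#' fam <- set_family("demo", list(A = c("1","2","3"), B = c("2","3","4"),
#'                                C = c("3","4","5")))
#' venn_partition(fam, denominator = 5)
#' @export
venn_partition <- function(family, denominator) {
  stopifnot(inherits(family, "set_family"))
  union_ids <- unique(unlist(family$members, use.names = FALSE))
  assert_count(denominator, "denominator")
  if (denominator < length(union_ids)) {
    stop_cmpn("denominator must be >= the family union size", "bad_denominator")
  }
  labels <- names(family$members)
  membership <- vapply(family$members, function(s) union_ids %in% s,
                       logical(length(union_ids)))
  if (length(union_ids) == 1) {
    membership <- matrix(membership, nrow = 1, dimnames = list(NULL, labels))
  }
  sigs <- region_signatures(labels)
  rows <- purrr::map(sigs, function(sig) {
    inside <- rowSums(membership[, sig, drop = FALSE]) == length(sig) &
      rowSums(membership[, setdiff(labels, sig), drop = FALSE]) == 0
    ids <- union_ids[inside]
    tibble(region = paste(sig, collapse = "&"),
           labels = list(sig),
           count = length(ids),
           percentage = round_half_up(100 * length(ids) / denominator, 1),
           members = list(sort(ids)))
  })
  out <- bind_rows(rows)
  class(out) <- c("venn_partition", class(out))
  attr(out, "denominator") <- as.integer(denominator)
  attr(out, "family_name") <- family$name
  out
}

#' Apply a feature filter to every set of a family
#'
#' @param family A [set_family()].
#' @param filter_set Character vector of feature ids.
#' @param mode `"subtract"` (remove filter ids) or `"intersect"` (keep only
#'   filter ids).
#' @param id_normalization `"exact"` or `"case_insensitive_symbol"`
#'   (case-folded matching, for cross-species gene-symbol filters).
#' @return A `set_family` with every set reduced accordingly.
#' @export
apply_filter <- function(family, filter_set,
                         mode = c("subtract", "intersect"),
                         id_normalization = c("exact",
                                              "case_insensitive_symbol")) {
  stopifnot(inherits(family, "set_family"))
  mode <- match.arg(mode)
  id_normalization <- match.arg(id_normalization)
  norm <- if (id_normalization == "exact") identity else toupper
  filt <- norm(as.character(filter_set))
  members <- purrr::map(family$members, function(s) {
    hit <- norm(s) %in% filt
    if (mode == "subtract") s[!hit] else s[hit]
  })
  set_family(family$name, members)
}

#' Filter specification for the two-step filtration
#'
#' @param layer1 Feature ids whose response tracks CCM1 protein dosage
#'   (removed first).
#' @param layer2 Feature ids responding to non-mPR ("antagonist", GR/nPR)
#'   progesterone actions (removed second).
#' @param id_normalization `"exact"` or `"case_insensitive_symbol"`; the
#'   default case-folds gene symbols because the antagonist layer typically
#'   derives from another species' dataset.
#' @return A `filter_spec` list. Layers may overlap.
#' @export
filter_spec <- function(layer1, layer2,
                        id_normalization = c("case_insensitive_symbol",
                                             "exact")) {
  structure(list(layer1 = unique(as.character(layer1)),
                 layer2 = unique(as.character(layer2)),
                 id_normalization = match.arg(id_normalization)),
            class = "filter_spec")
}

#' Two-step filtration isolating mPR-specific features
#'
#' Removes, in order, (1) features whose response follows CCM1 protein
#' expression level and (2) features attributable to non-mPR-specific
#' progesterone actions (shared GR/nPR "antagonist" responses). Because
#' both steps are set subtraction by fixed filters, the result is
#' order-independent; the per-layer removal report follows the stated
#' order.
#'
#' @param prg_response A [set_family()] of progesterone-responsive feature
#'   sets (one set per genotype).
#' @param spec A [filter_spec()].
#' @return List with `mpr_specific` (the surviving [set_family()]) and
#'   `report` (tibble: per set label, sizes before/after each layer and
#'   per-layer removal counts).
#' @export
two_step_filtration <- function(prg_response, spec) {
  stopifnot(inherits(prg_response, "set_family"), inherits(spec, "filter_spec"))
  after1 <- apply_filter(prg_response, spec$layer1, "subtract",
                         spec$id_normalization)
  after2 <- apply_filter(after1, spec$layer2, "subtract",
                         spec$id_normalization)
  report <- tibble(
    set_label = names(prg_response$members),
    input = lengths(prg_response$members),
    removed_layer1 = lengths(prg_response$members) - lengths(after1$members),
    removed_layer2 = lengths(after1$members) - lengths(after2$members),
    surviving = lengths(after2$members)
  )
  list(mpr_specific = after2, report = report)
}

#' Export a Venn partition as a plain table / JSON report
#'
#' @param partition A [venn_partition()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_venn_tsv <- function(partition, path) {
  readr::write_tsv(
    tibble(region = partition$region, count = partition$count,
           percentage = partition$percentage),
    path)
  invisible(path)
}

#' @rdname write_venn_tsv
#' @export
write_venn_json <- function(partition, path) {
  jsonlite::write_json(
    list(family = attr(partition, "family_name"),
         denominator = attr(partition, "denominator"),
         regions = purrr::pmap(
           list(partition$region, partition$count, partition$percentage,
                partition$members),
           function(r, k, p, m) list(region = r, count = k, percentage = p,
                                     members = m))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
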