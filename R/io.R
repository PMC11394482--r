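# Plain-text readers/writers for every artifact the pipeline exchanges:
# feature-by-sample TSV matrices, design sheets, GMT collections,
# labelled FASTA, feature-set lists and embedding tables. Every writer
# round-trips with the matching reader.

#' Write / read a feature-by-sample abundance matrix as TSV
#'
#' Matrices are tibbles with a `feature_id` column followed by one numeric
#' column per sample (header row of sample ids).
#'
#' @param mat Tibble: `feature_id` + one column per sample.
#' @param path File path.
#' @return `write_matrix_tsv()` returns `path` invisibly; `read_matrix_tsv()`
#'   returns the matrix tibble.
#' @export
write_matrix_tsv <- function(mat, path) {
  stopifnot(names(mat)[1] == "feature_id")
  readr::write_tsv(mat, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read a sample design sheet
#'
#' Design sheets have columns `sample_id`, `genotype`, `treatment`,
#' `replicate`; one row per sample.
#'
#' @param design Design tibble.
#' @param path File path.
#' @return The path (writer, invisibly) or the design tibble (reader).
#' @export
write_design_tsv <- function(design, path) {
  stopifnot(all(c("sample_id", "genotype", "treatment", "replicate") %in%
                  names(design)))
  readr::write_tsv(design, path)
  invisible(path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", genotype = "c",
                    treatment = "c", replicate = "i"))
}

#' Gene-set collections in GMT format
#'
#' A collection is a tibble with columns `term_id`, `name`,
#' `category` (`"GO"`, `"KEGG"` or `"other"`) and a list-column `members`.
#' On disk each GMT line is `term_id<TAB>description<TAB>member1<TAB>...`;
#' the category is encoded in the description field as `category|name` so
#' the files stay valid GMT for external tools.
#'
#' @param collection Gene-set collection tibble.
#' @param path File path.
#' @return The path (writer, invisibly) or the collection tibble (reader).
#' @export
write_gmt <- function(collection, path) {
  validate_collection(collection)
  lines <- purrr::pmap_chr(
    list(collection$term_id, collection$name, collection$category,
         collection$members),
    function(id, nm, cat, mem) {
      paste(c(id, paste0(cat, "|", nm), mem), collapse = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  desc <- purrr::map_chr(parts, 2)
  has_cat <- grepl("|", desc, fixed = TRUE)
  category <- ifelse(has_cat, sub("\\|.*$", "", desc), "other")
  name <- ifelse(has_cat, sub("^[^|]*\\|", "", desc), desc)
  tibble(
    term_id  = purrr::map_chr(parts, 1),
    name     = name,
    category = category,
    members  = purrr::map(parts, ~ .x[-(1:2)])
  )
}

validate_collection <- function(collection) {
  stopifnot(all(c("term_id", "name", "category", "members") %in%
                  names(collection)))
  if (anyDuplicated(collection$term_id)) {
    stop_cmpn("term ids must be unique", "invalid_collection")
  }
  if (any(lengths(collection$members) == 0)) {
    stop_cmpn("every term must have at least one member", "invalid_collection")
  }
  invisible(collection)
}

#' Labelled protein sequences in FASTA
#'
#' Sequence sets are tibbles with columns `id`, `sequence`, `label`
#' (`"TF"`, `"NTF"` or `NA` when unlabelled). Headers are `>id|label`
#' (`>id` when unlabelled).
#'
#' @param records Sequence-set tibble.
#' @param path File path.
#' @return The path (writer, invisibly) or the sequence tibble (reader).
#' @export
write_seq_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence", "label") %in% names(records)))
  hdr <- ifelse(is.na(records$label), records$id,
                paste0(records$id, "|", records$label))
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path, width = 80)
  invisible(path)
}

#' @rdname write_seq_fasta
#' @export
read_seq_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  has_label <- grepl("|", hdr, fixed = TRUE)
  tibble(
    id       = ifelse(has_label, sub("\\|.*$", "", hdr), hdr),
    sequence = unname(as.character(seqs)),
    label    = ifelse(has_label, sub("^[^|]*\\|", "", hdr), NA_character_)
  )
}

#' Feature sets as one-id-per-line or two-column TSV
#'
#' @param ids Character vector of feature ids.
#' @param path File path.
#' @return The path (writer, invisibly) or a character vector (reader).
#' @export
write_feature_set <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  ids <- readLines(path)
  ids[nzchar(ids)]
}

#' Write / read a labelled set family as two-column TSV
#'
#' Columns: `set_label`, `id`.
#'
#' @param family A set family (see [set_family()]).
#' @param path File path.
#' @return The path (writer, invisibly) or a set family (reader).
#' @export
write_set_family <- function(family, path) {
  df <- tibble(
    set_label = rep(names(family$members), lengths(family$members)),
    id = unlist(family$members, use.names = FALSE)
  )
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_set_family
#' @export
read_set_family <- function(path, name = "family") {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  set_family(name, split(df$id, factor(df$set_label, unique(df$set_label))))
}

#' External per-sequence embedding tables
#'
#' TSV with an `id` column followed by numeric columns `v1..vd`.
#'
#' @param embeddings Embedding table tibble (see [featurize()]).
#' @param path File path.
#' @return The path (writer, invisibly) or the embedding tibble (reader).
#' @export
write_embedding_tsv <- function(embeddings, path) {
  stopifnot(names(embeddings)[1] == "id")
  readr::write_tsv(embeddings, path)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
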