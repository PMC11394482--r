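# Fixtures built in code: region-wise set families matching the published
# Venn counts, and small simulation shortcuts.

# Build a set family from explicit region sizes. `regions` is a named list:
# names are region signatures like "WT", "WT&KO", "WT&KO&KI96"; values are
# region sizes. Ids are generated per region with a prefix so regions are
# disjoint by construction. Returns list(family, region_ids).
family_from_regions <- function(regions, labels, name = "fixture",
                                prefix = "F") {
  members <- setNames(vector("list", length(labels)), labels)
  region_ids <- list()
  for (sig in names(regions)) {
    n <- regions[[sig]]
    ids <- if (n > 0) sprintf("%s_%s_%03d", prefix, gsub("&", ".", sig),
                              seq_len(n)) else character(0)
    region_ids[[sig]] <- ids
    for (lb in strsplit(sig, "&", fixed = TRUE)[[1]]) {
      members[[lb]] <- c(members[[lb]], ids)
    }
  }
  list(family = set_family(name, members), region_ids = region_ids)
}

# Printed Venn tables: list(regions, denominator, expected percentages)
# in the same region order.
published_venn_fixtures <- function() {
  list(
    genotype_pairs_dep = list(
      labels = c("pair1", "pair2", "pair3"),
      regions = c("pair1" = 205, "pair2" = 120, "pair3" = 194,
                  "pair1&pair2" = 113, "pair1&pair3" = 173,
                  "pair2&pair3" = 186, "pair1&pair2&pair3" = 68),
      denominator = 1059,
      expected = c("pair1" = 19.4, "pair2" = 11.3, "pair3" = 18.3,
                   "pair1&pair2" = 10.7, "pair1&pair3" = 16.3,
                   "pair2&pair3" = 17.6, "pair1&pair2&pair3" = 6.4)),
    prg_response_dep = list(
      labels = c("WT", "KO", "KI96"),
      regions = c("WT" = 218, "KO" = 212, "KI96" = 115,
                  "WT&KO" = 48, "WT&KI96" = 27, "KO&KI96" = 29,
                  "WT&KO&KI96" = 12),
      denominator = 1059,
      expected = c("WT" = 20.6, "KO" = 20.0, "KI96" = 10.9,
                   "WT&KO" = 4.5, "WT&KI96" = 2.5, "KO&KI96" = 2.7,
                   "WT&KO&KI96" = 1.1)),
    filtered_dep = list(
      labels = c("WT", "KO", "KI96"),
      regions = c("WT" = 262, "KO" = 224, "KI96" = 151,
                  "WT&KO" = 79, "WT&KI96" = 66, "KO&KI96" = 42,
                  "WT&KO&KI96" = 52),
      denominator = 876,
      expected = c("WT" = 29.9, "KO" = 25.6, "KI96" = 17.2,
                   "WT&KO" = 9.0, "WT&KI96" = 7.5, "KO&KI96" = 4.8,
                   "WT&KO&KI96" = 5.9)),
    filtered_deg = list(
      labels = c("KO", "KI96"),
      regions = c("KO" = 1230, "KI96" = 3242, "KO&KI96" = 1952),
      denominator = 6424,
      expected = c("KO" = 19.1, "KI96" = 50.5, "KO&KI96" = 30.4)),
    mpr_dep = list(
      labels = c("WT", "KO", "KI96"),
      regions = c("WT" = 7, "KO" = 2, "KI96" = 2,
                  "WT&KO" = 3, "WT&KI96" = 1, "KO&KI96" = 3,
                  "WT&KO&KI96" = 0),
      denominator = 18,
      expected = c("WT" = 38.9, "KO" = 11.1, "KI96" = 11.1,
                   "WT&KO" = 16.7, "WT&KI96" = 5.6, "KO&KI96" = 16.7,
                   "WT&KO&KI96" = 0.0)),
    mpr_deg = list(
      labels = c("KO", "KI96"),
      regions = c("KO" = 20, "KI96" = 57, "KO&KI96" = 26),
      denominator = 103,
      expected = c("KO" = 19.4, "KI96" = 55.3, "KO&KI96" = 25.2))
  )
}

# Two-step filtration fixture: a raw progesterone-response family that the
# dosage layer reduces to the published filtered counts (876) and the
# antagonist layer reduces to the published mPR-specific counts (18).
two_step_fixture <- function() {
  fx <- published_venn_fixtures()
  filtered <- family_from_regions(fx$filtered_dep$regions,
                                  fx$filtered_dep$labels, prefix = "DEP")
  final_counts <- fx$mpr_dep$regions
  survivors <- unlist(purrr::imap(final_counts, function(n, sig) {
    utils::head(filtered$region_ids[[sig]], n)
  }), use.names = FALSE)
  layer2 <- setdiff(unlist(filtered$region_ids, use.names = FALSE), survivors)
  # dosage-tracking ids present in the raw family but removed by layer 1
  dosage <- sprintf("DOSAGE_%03d", 1:61)
  raw_members <- purrr::map(filtered$family$members, ~ c(.x, dosage))
  list(
    raw = set_family("prg_response_raw", raw_members),
    spec = filter_spec(layer1 = dosage, layer2 = layer2,
                       id_normalization = "exact"),
    filtered_counts = fx$filtered_dep$regions,
    final = fx$mpr_dep
  )
}

# small random 2/3-set family for property tests
random_family <- function(k = sample(2:3, 1), universe = 60) {
  ids <- sprintf("x%03d", seq_len(universe))
  members <- purrr::map(seq_len(k),
                        ~ sample(ids, sample.int(universe, 1)))
  names(members) <- LETTERS[seq_len(k)]
  set_family("random", members)
}

# gaussian-cluster embedding fixture for the SVM
cluster_embeddings <- function(n_pos, n_neg, sep, dim = 5, sd = 1) {
  ids <- c(sprintf("TF%03d", seq_len(n_pos)), sprintf("NT%03d", seq_len(n_neg)))
  x <- rbind(
    matrix(rnorm(n_pos * dim, mean = sep, sd = sd), n_pos, dim),
    matrix(rnorm(n_neg * dim, mean = 0, sd = sd), n_neg, dim))
  emb <- tibble::as_tibble(x, .name_repair = ~ paste0("v", seq_along(.x)))
  emb <- dplyr::bind_cols(tibble::tibble(id = ids), emb)
  records <- tibble::tibble(id = ids, sequence = strrep("A", 10),
                            label = rep(c("TF", "NTF"), c(n_pos, n_neg)))
  list(records = records, embeddings = emb)
}

# exhaustive hypergeometric upper-tail oracle: P(X >= k) by enumerating
# all C(N, n) draws of size n from a universe with K marked items
hyper_tail_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# run ora for one (N, K, n, k) configuration: term 1 has the first K ids,
# a catch-all term annotates the whole universe so the annotated query size
# equals the query size
ora_single_config <- function(N, K, n, k) {
  universe <- sprintf("u%02d", seq_len(N))
  coll <- tibble::tibble(
    term_id = c("T1", "ALL"), name = c("t", "all"),
    category = c("GO", "GO"),
    members = list(universe[seq_len(K)], universe))
  query <- c(universe[seq_len(k)],
             universe[K + seq_len(n - k)])
  res <- ora(query, universe, coll)
  res$p_hyper[res$term_id == "T1"]
}
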