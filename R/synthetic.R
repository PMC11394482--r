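# Synthetic multi-omics generator. The study design it emulates: three
# CCM1 genotypes (WT, KO, KI96) x progesterone treatments x 3 biological
# replicates, proteomic iBAQ-like intensities and RNA-seq counts, with
# planted genotype- and treatment-effects whose identities are returned
# as ground truth so every downstream stage can be recovery-tested.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Experiment configuration for the synthetic generator
#'
#' Defines the simulated study: genotype and treatment arms, replication,
#' feature counts per modality, planted effect size and the fractions of
#' features carrying genotype (CCM1-dosage) and treatment (progesterone
#' response) effects.
#'
#' @param n_features_protein Number of proteomic features (default 2000, the
#'   order of a quantified fibroblast proteome scaled to desk size).
#' @param n_features_rna Number of RNA features (default 8000).
#' @param genotypes Genotype labels; the first is the reference (default
#'   `c("WT", "KO", "KI96")`).
#' @param treatments Treatment labels; the first is the control arm (default
#'   `c("VEH", "PRG_MIF")`, vehicle vs combined progesterone + mifepristone).
#' @param replicates Biological replicates per genotype-by-treatment cell
#'   (default 3, the study design).
#' @param effect_log2fc Planted effect size in log2 units (default 2).
#' @param frac_genotype_de Fraction of features carrying a genotype effect in
#'   each non-reference genotype (default 0.1).
#' @param frac_treatment_de Fraction of features carrying a treatment effect
#'   in each genotype (default 0.1).
#' @param frac_mpr_specific Fraction of each genotype's treatment-responsive
#'   features designated mPR-specific; the rest are "antagonist" (non-mPR)
#'   responses removable by the second filtration layer (default 0.5).
#' @param nb_dispersion Negative-binomial dispersion for RNA counts
#'   (default 0.1; `size = 1/dispersion`).
#' @param sigma_log2 Replicate noise SD on the log2 scale (default 0.5).
#' @param missing_rate Missing-at-random rate for proteomic values
#'   (default 0, i.e. off).
#' @param seed Integer seed; identical config + seed reproduce the output
#'   byte for byte.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_features_protein = 2000,
                              n_features_rna = 8000,
                              genotypes = c("WT", "KO", "KI96"),
                              treatments = c("VEH", "PRG_MIF"),
                              replicates = 3,
                              effect_log2fc = 2,
                              frac_genotype_de = 0.1,
                              frac_treatment_de = 0.1,
                              frac_mpr_specific = 0.5,
                              nb_dispersion = 0.1,
                              sigma_log2 = 0.5,
                              missing_rate = 0,
                              seed = 1L) {
  assert_count(n_features_protein, "n_features_protein")
  assert_count(n_features_rna, "n_features_rna")
  assert_count(replicates, "replicates", min = 2)
  assert_fraction(frac_genotype_de, "frac_genotype_de")
  assert_fraction(frac_treatment_de, "frac_treatment_de")
  assert_fraction(frac_mpr_specific, "frac_mpr_specific")
  assert_fraction(missing_rate, "missing_rate")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0) {
    stop_cmpn("`nb_dispersion` must be positive", "invalid_config")
  }
  if (anyDuplicated(genotypes) || anyDuplicated(treatments)) {
    stop_cmpn("genotype and treatment labels must be unique", "invalid_config")
  }
  structure(
    list(n_features_protein = as.integer(n_features_protein),
         n_features_rna = as.integer(n_features_rna),
         genotypes = genotypes, treatments = treatments,
         replicates = as.integer(replicates),
         effect_log2fc = effect_log2fc,
         frac_genotype_de = frac_genotype_de,
         frac_treatment_de = frac_treatment_de,
         frac_mpr_specific = frac_mpr_specific,
         nb_dispersion = nb_dispersion, sigma_log2 = sigma_log2,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "experiment_config")
}

sample_design <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      treatment = config$treatments,
                      genotype = config$genotypes,
                      stringsAsFactors = FALSE)
  tibble(
    sample_id = paste(grid$genotype, grid$treatment, grid$replicate, sep = "_"),
    genotype = grid$genotype,
    treatment = grid$treatment,
    replicate = as.integer(grid$replicate)
  )
}

# Draw planted-feature assignments for one modality. Genotype-effect
# features are drawn from the universe; treatment-effect features from the
# remainder, independently per genotype, each with one sign and one
# mPR-specific flag per feature.
plant_effects <- function(feature_ids, config, modality) {
  n <- length(feature_ids)
  n_g <- round(config$frac_genotype_de * n)
  n_t <- round(config$frac_treatment_de * n)
  geno_pool <- sample(feature_ids, min(n_g * max(length(config$genotypes) - 1, 1), n))

  genotype_de <- purrr::map(config$genotypes[-1], function(g) {
    tibble(genotype = g, feature_id = sample(geno_pool, n_g),
           modality = modality)
  }) |> bind_rows()
  if (nrow(genotype_de)) {
    signs <- sample(c(-1, 1), length(unique(genotype_de$feature_id)),
                    replace = TRUE)
    names(signs) <- unique(genotype_de$feature_id)
    genotype_de$sign <- unname(signs[genotype_de$feature_id])
  } else {
    genotype_de$sign <- numeric(0)
  }

  trt_pool <- setdiff(feature_ids, geno_pool)
  treatment_de <- purrr::map(config$genotypes, function(g) {
    tibble(genotype = g, feature_id = sample(trt_pool, n_t),
           modality = modality)
  }) |> bind_rows()
  if (nrow(treatment_de)) {
    uniq <- unique(treatment_de$feature_id)
    signs <- sample(c(-1, 1), length(uniq), replace = TRUE)
    n_mpr <- round(config$frac_mpr_specific * length(uniq))
    mpr <- c(rep(TRUE, n_mpr), rep(FALSE, length(uniq) - n_mpr))[
      sample.int(length(uniq))]
    names(signs) <- names(mpr) <- uniq
    treatment_de$sign <- unname(signs[treatment_de$feature_id])
    treatment_de$mpr_specific <- unname(mpr[treatment_de$feature_id])
  } else {
    treatment_de$sign <- numeric(0)
    treatment_de$mpr_specific <- logical(0)
  }
  list(genotype_de = genotype_de, treatment_de = treatment_de)
}

# per-feature x per-sample matrix of planted log2 shifts
effect_matrix <- function(feature_ids, design, planted, config) {
  shift <- matrix(0, length(feature_ids), nrow(design),
                  dimnames = list(feature_ids, design$sample_id))
  gde <- planted$genotype_de
  for (i in seq_len(nrow(gde))) {
    cols <- design$genotype == gde$genotype[i]
    shift[gde$feature_id[i], cols] <- shift[gde$feature_id[i], cols] +
      gde$sign[i] * config$effect_log2fc
  }
  tde <- planted$treatment_de
  treated <- design$treatment != config$treatments[1]
  for (i in seq_len(nrow(tde))) {
    cols <- design$genotype == tde$genotype[i] & treated
    shift[tde$feature_id[i], cols] <- shift[tde$feature_id[i], cols] +
      tde$sign[i] * config$effect_log2fc
  }
  shift
}

#' Generate paired proteomic and RNA-seq matrices with planted effects
#'
#' Proteomic values are positive log-normal intensities (log2-scale baseline
#' plus Gaussian replicate noise); RNA values are negative-binomial counts.
#' Features designated in the returned ground truth are shifted by
#' `effect_log2fc` in the corresponding genotype or treated cells.
#'
#' @param config An [experiment_config()].
#' @return A list with elements `proteomic` and `rna` (tibbles:
#'   `feature_id` + one column per sample), `design` (sample sheet) and
#'   `ground_truth` (list of tibbles `genotype_de`, `treatment_de` with
#'   per-feature sign and mPR-specific designation).
#' @examples
#' sim <- generate_omics(experiment_config(n_features_protein = 50,
#'                                         n_features_rna = 50, seed = 7))
#' dim(sim$proteomic)
#' @export
generate_omics <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  design <- sample_design(config)
  with_seed(config$seed, {
    prot_ids <- sprintf("P%04d", seq_len(config$n_features_protein))
    rna_ids <- sprintf("G%05d", seq_len(config$n_features_rna))

    prot_planted <- plant_effects(prot_ids, config, "proteomic")
    rna_planted <- plant_effects(rna_ids, config, "rna")

    # proteomic: log2 baseline ~ U(20, 30), iBAQ-like dynamic range
    base_p <- runif(length(prot_ids), 20, 30)
    noise <- matrix(rnorm(length(prot_ids) * nrow(design), 0, config$sigma_log2),
                    length(prot_ids), nrow(design))
    log2_p <- base_p + noise + effect_matrix(prot_ids, design, prot_planted, config)
    prot <- 2^log2_p
    if (config$missing_rate > 0) {
      prot[matrix(runif(length(prot)) < config$missing_rate,
                  nrow(prot), ncol(prot))] <- NA_real_
    }
    dimnames(prot) <- list(prot_ids, design$sample_id)

    # rna: NB counts, mean 2^U(3, 12), planted fold changes multiply the mean
    base_r <- runif(length(rna_ids), 3, 12)
    mu <- 2^(base_r + effect_matrix(rna_ids, design, rna_planted, config))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow(mu), ncol(mu), dimnames = dimnames(mu))
    dimnames(counts) <- list(rna_ids, design$sample_id)

    list(
      proteomic = matrix_to_tibble(prot),
      rna = matrix_to_tibble(counts),
      design = design,
      ground_truth = list(
        genotype_de = bind_rows(prot_planted$genotype_de, rna_planted$genotype_de),
        treatment_de = bind_rows(prot_planted$treatment_de, rna_planted$treatment_de)
      )
    )
  })
}

matrix_to_tibble <- function(m) {
  out <- as_tibble(m, rownames = "feature_id")
  out
}

tibble_to_matrix <- function(tbl) {
  m <- as.matrix(tbl[-1])
  rownames(m) <- tbl$feature_id
  m
}

#' Generate a gene-set collection with planted enriched terms
#'
#' Planted terms draw a fixed fraction of their members from the supplied
#' differentially expressed features, so over-representation analysis should
#' recover them; remaining members and all non-planted terms are uniform
#' draws from the universe. Flat term lists only (no ontology structure).
#'
#' @param n_terms Number of terms.
#' @param sizes Length-2 integer range of term sizes.
#' @param universe Character vector of feature ids.
#' @param planted_terms Number of terms to enrich (must be <= `n_terms`).
#' @param de_features Feature ids the planted terms should over-represent;
#'   either a character vector or the `ground_truth` list from
#'   [generate_omics()] (treatment-responsive features are used).
#' @param seed Integer seed.
#' @param overlap_frac Fraction of each planted term drawn from
#'   `de_features` (default 0.75).
#' @return Gene-set collection tibble (`term_id`, `name`, `category`,
#'   `members`, `planted`), serializable with [write_gmt()].
#' @export
generate_gene_sets <- function(n_terms, sizes, universe, planted_terms,
                               de_features, seed, overlap_frac = 0.75) {
  assert_count(n_terms, "n_terms")
  if (planted_terms > n_terms) {
    stop_cmpn("planted_terms must not exceed n_terms", "invalid_config")
  }
  if (max(sizes) > length(universe)) {
    stop_cmpn("term sizes must not exceed the universe size", "invalid_config")
  }
  if (is.list(de_features)) {
    de_features <- unique(de_features$treatment_de$feature_id)
  }
  de_features <- intersect(de_features, universe)
  with_seed(seed, {
    size_pool <- seq(min(sizes), max(sizes))
    term_sizes <- size_pool[sample.int(length(size_pool), n_terms,
                                       replace = TRUE)]
    planted <- seq_len(n_terms) <= planted_terms
    members <- purrr::map2(term_sizes, planted, function(sz, pl) {
      if (pl && length(de_features)) {
        n_de <- min(round(overlap_frac * sz), length(de_features))
        de_part <- sample(de_features, n_de)
        bg <- sample(setdiff(universe, de_part), sz - n_de)
        sample(c(de_part, bg))
      } else {
        sample(universe, sz)
      }
    })
    tibble(
      term_id = sprintf("T%04d", seq_len(n_terms)),
      name = sprintf("synthetic term %d", seq_len(n_terms)),
      category = rep_len(c("GO", "KEGG"), n_terms),
      members = members,
      planted = planted
    )
  })
}

#' Generate an imbalanced TF/NTF protein-sequence benchmark
#'
#' Transcription-factor-labelled sequences contain a planted amino-acid
#' motif at random internal positions; non-TF sequences are motif-free
#' uniform background. Default composition is 2784 NTF / 954 TF (3738
#' sequences), the benchmark's class imbalance. The motif is planted in
#' `motif_copies` non-overlapping copies per TF sequence (default 3),
#' emulating the tandem repeats of DNA-binding domains typical of real
#' transcription-factor families.
#'
#' @param n_tf Number of TF-labelled sequences (default 954).
#' @param n_ntf Number of NTF-labelled sequences (default 2784).
#' @param length_range Length-2 range of sequence lengths (default 200-600).
#' @param motif Planted motif over the 20-letter amino-acid alphabet
#'   (default `"CKRPLHC"`, an arbitrary synthetic 7-mer, not a real
#'   DNA-binding domain).
#' @param motif_copies Copies of the motif per TF sequence (default 3).
#' @param seed Integer seed.
#' @return Sequence-set tibble (`id`, `sequence`, `label`), serializable
#'   with [write_seq_fasta()].
#' @export
generate_tf_benchmark <- function(n_tf = 954, n_ntf = 2784,
                                  length_range = c(200, 600),
                                  motif = "CKRPLHC", motif_copies = 3,
                                  seed = 1L) {
  assert_count(n_tf, "n_tf", min = 0)
  assert_count(n_ntf, "n_ntf", min = 0)
  assert_count(motif_copies, "motif_copies", min = 1)
  motif_chars <- strsplit(motif, "")[[1]]
  if (!all(motif_chars %in% AA_ALPHABET)) {
    stop_cmpn("motif contains non-amino-acid symbols", "invalid_config")
  }
  if (motif_copies * nchar(motif) >= min(length_range)) {
    stop_cmpn("planted motif copies must fit inside the shortest sequence",
              "invalid_config")
  }
  with_seed(seed, {
    rand_seq <- function(len) {
      paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
    }
    len_pool <- seq(length_range[1], length_range[2])
    lens_tf <- len_pool[sample.int(length(len_pool), n_tf, replace = TRUE)]
    lens_ntf <- len_pool[sample.int(length(len_pool), n_ntf, replace = TRUE)]
    mlen <- nchar(motif)
    tf_seqs <- purrr::map_chr(lens_tf, function(len) {
      s <- rand_seq(len)
      # one copy per equal-length chunk at a random offset: copies never
      # overlap and sit at random internal positions
      chunk <- len %/% motif_copies
      for (j in seq_len(motif_copies)) {
        off <- sample.int(chunk - mlen + 1, 1)
        pos <- (j - 1) * chunk + off
        s <- paste0(substr(s, 1, pos - 1), motif,
                    substr(s, pos + mlen, len))
      }
      s
    })
    ntf_seqs <- purrr::map_chr(lens_ntf, function(len) {
      s <- rand_seq(len)
      while (grepl(motif, s, fixed = TRUE)) s <- rand_seq(len)
      s
    })
    tibble(
      id = c(sprintf("TF%04d", seq_len(n_tf)),
             sprintf("NT%04d", seq_len(n_ntf))),
      sequence = c(tf_seqs, ntf_seqs),
      label = rep(c("TF", "NTF"), c(n_tf, n_ntf))
    )
  })
}

#' Generate the antagonist (non-mPR) response filter set
#'
#' Emulates the external mifepristone-response filter: a feature set covering
#' a stated fraction of the planted non-mPR treatment responses plus
#' background ids, guaranteed disjoint from the planted mPR-specific
#' features.
#'
#' @param ground_truth Ground-truth list from [generate_omics()].
#' @param coverage Fraction of planted non-mPR features the filter covers.
#' @param seed Integer seed.
#' @param universe Optional feature universe from which background
#'   (non-planted) ids are drawn.
#' @param n_background Number of background ids to add (default 50; 0 if no
#'   universe is supplied).
#' @param modality Restrict to `"proteomic"` or `"rna"` planted features,
#'   or `"all"` (default).
#' @return Character vector of feature ids.
#' @export
generate_antagonist_filter <- function(ground_truth, coverage, seed,
                                       universe = NULL, n_background = 50,
                                       modality = "all") {
  assert_fraction(coverage, "coverage")
  tde <- ground_truth$treatment_de
  if (modality != "all") tde <- tde[tde$modality == modality, ]
  non_mpr <- unique(tde$feature_id[!tde$mpr_specific])
  mpr <- unique(tde$feature_id[tde$mpr_specific])
  with_seed(seed, {
    n_cov <- round_half_up(coverage * length(non_mpr))
    covered <- if (n_cov > 0) sample(non_mpr, n_cov) else character(0)
    bg <- character(0)
    if (!is.null(universe) && n_background > 0) {
      pool <- setdiff(universe, unique(tde$feature_id))
      bg <- sample(pool, min(n_background, length(pool)))
    }
    sort(unique(c(covered, bg)))
  })
}
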