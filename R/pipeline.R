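# End-to-end orchestration: synthetic (or file-based) inputs -> normalize
# -> per-genotype treatment DE -> Venn partition -> two-step filtration ->
# ORA + comparative dot plot -> TF prediction. Writes every stage table
# plus a run manifest; identical config + seed reproduce identical bytes.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all stage tables and the manifest.
#' @param seed Master integer seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @param experiment An [experiment_config()] for the synthetic inputs
#'   (ignored when `paths` supplies files).
#' @param de A [de_config()].
#' @param cv A [cv_config()] for the TF stage.
#' @param n_terms,planted_terms,term_sizes Gene-set generation knobs
#'   (defaults 200 terms of size 15-60, 10 planted).
#' @param antagonist_coverage Fraction of planted non-mPR responses the
#'   synthetic antagonist filter covers (default 0.9).
#' @param venn_denominator `"n_features"` (default: all identified features
#'   of the modality, the "total identified proteins" convention) or
#'   `"union"` (size of the family union).
#' @param run_tf Run the TF-prediction stage (default TRUE).
#' @param tf_benchmark Named list of [generate_tf_benchmark()] arguments for
#'   the synthetic TF stage (defaults to the benchmark composition,
#'   954 TF / 2784 NTF).
#' @param paths Optional named list of input files
#'   (`proteomic`, `rna`, `design`, `gmt`, `layer1`, `layer2`, `fasta`)
#'   read instead of generating synthetic inputs; `fasta = NULL` skips the
#'   TF stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            experiment = experiment_config(seed = seed),
                            de = de_config(),
                            cv = cv_config(seed = seed),
                            n_terms = 200, planted_terms = 10,
                            term_sizes = c(15, 60),
                            antagonist_coverage = 0.9,
                            venn_denominator = c("n_features", "union"),
                            run_tf = TRUE, tf_benchmark = list(),
                            paths = NULL) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 experiment = experiment, de = de, cv = cv,
                 n_terms = n_terms, planted_terms = planted_terms,
                 term_sizes = term_sizes,
                 antagonist_coverage = antagonist_coverage,
                 venn_denominator = match.arg(venn_denominator),
                 run_tf = isTRUE(run_tf), tf_benchmark = tf_benchmark,
                 paths = paths),
            class = "pipeline_config")
}

stage_fail <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_cmpn(sprintf("pipeline stage '%s' failed: %s", stage,
                      conditionMessage(e)), "stage_error")
  })
}

#' Run the full pipeline
#'
#' Executes every stage in order, writes stage outputs and a JSON manifest
#' (inputs, seeds, per-stage row counts) under `config$out_dir`, and
#' returns the manifest invisibly together with the in-memory results.
#' Re-running with the same config reproduces identical output bytes.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `manifest` and the per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, package = "cmpnomics",
                   version = as.character(utils::packageVersion("cmpnomics")),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  # ---- inputs ----
  if (is.null(config$paths)) {
    cfg <- config$experiment
    cfg$seed <- derive_seed(config$seed, 1)
    sim <- stage_fail("generate", generate_omics(cfg))
    proteomic <- sim$proteomic; rna <- sim$rna; design <- sim$design
    collection <- stage_fail("generate", generate_gene_sets(
      config$n_terms, config$term_sizes, proteomic$feature_id,
      config$planted_terms, sim$ground_truth, derive_seed(config$seed, 2)))
    layer2 <- stage_fail("generate", generate_antagonist_filter(
      sim$ground_truth, config$antagonist_coverage,
      derive_seed(config$seed, 3), universe = proteomic$feature_id))
    fasta <- if (config$run_tf) {
      args <- utils::modifyList(list(seed = derive_seed(config$seed, 4)),
                                config$tf_benchmark)
      stage_fail("generate", do.call(generate_tf_benchmark, args))
    } else NULL
    layer1_external <- NULL
    write_matrix_tsv(proteomic, file.path(config$out_dir, "proteomic.tsv"))
    write_matrix_tsv(rna, file.path(config$out_dir, "rna.tsv"))
    write_design_tsv(design, file.path(config$out_dir, "design.tsv"))
    write_gmt(collection, file.path(config$out_dir, "gene_sets.gmt"))
    write_feature_set(layer2, file.path(config$out_dir, "antagonist_filter.txt"))
    ground_truth <- sim$ground_truth
  } else {
    p <- config$paths
    proteomic <- read_matrix_tsv(p$proteomic)
    rna <- if (!is.null(p$rna)) read_matrix_tsv(p$rna) else NULL
    design <- read_design_tsv(p$design)
    collection <- read_gmt(p$gmt)
    layer2 <- read_feature_set(p$layer2)
    layer1_external <- if (!is.null(p$layer1)) read_feature_set(p$layer1) else NULL
    fasta <- if (config$run_tf && !is.null(p$fasta)) read_seq_fasta(p$fasta) else NULL
    ground_truth <- NULL
  }
  note("generate", n_proteomic = nrow(proteomic),
       n_rna = if (is.null(rna)) 0L else nrow(rna),
       n_samples = nrow(design), n_terms = nrow(collection),
       synthetic = is.null(config$paths))

  # ---- normalize ----
  proteomic_n <- stage_fail("normalize",
                            normalize_abundance(proteomic,
                                                config$de$normalization))
  note("normalize", method = config$de$normalization)

  genotypes <- unique(design$genotype)
  treatments <- unique(design$treatment)
  ref_geno <- genotypes[1]
  ctrl <- treatments[1]
  trt <- treatments[treatments != ctrl][1]

  # ---- treatment DE per genotype (progesterone response) ----
  de_by_geno <- purrr::map(setNames(genotypes, genotypes), function(g) {
    stage_fail("de", call_de(
      proteomic_n,
      design_samples(design, genotype = g, treatment = ctrl),
      design_samples(design, genotype = g, treatment = trt),
      config$de, modality = "proteomic"))
  })
  for (g in genotypes) {
    readr::write_tsv(select(as_tibble(de_by_geno[[g]]), -dplyr::any_of("members")),
                     file.path(config$out_dir, paste0("de_", g, ".tsv")))
  }
  sets_by_geno <- purrr::map(de_by_geno, de_sets)
  note("de", contrasts = length(de_by_geno),
       n_significant = purrr::map_int(sets_by_geno,
                                      ~ length(.x$all_significant)))

  # ---- dosage (layer 1) DE: genotype contrasts under the control arm ----
  layer1 <- if (!is.null(layer1_external)) layer1_external else {
    dosage <- purrr::map(genotypes[genotypes != ref_geno], function(g) {
      res <- stage_fail("de", call_de(
        proteomic_n,
        design_samples(design, genotype = ref_geno, treatment = ctrl),
        design_samples(design, genotype = g, treatment = ctrl),
        config$de, modality = "proteomic"))
      de_sets(res)$all_significant
    })
    sort(unique(unlist(dosage)))
  }
  write_feature_set(layer1, file.path(config$out_dir, "dosage_filter.txt"))
  note("layer1", n_features = length(layer1))

  # ---- Venn partition of the progesterone response ----
  family <- set_family("prg_response",
                       purrr::map(sets_by_geno, "all_significant"))
  denom <- if (config$venn_denominator == "n_features") nrow(proteomic_n) else
    length(unique(unlist(family$members)))
  venn <- stage_fail("venn", venn_partition(family, denom))
  write_venn_tsv(venn, file.path(config$out_dir, "venn_prg_response.tsv"))
  write_venn_json(venn, file.path(config$out_dir, "venn_prg_response.json"))
  note("venn", union = sum(venn$count), denominator = denom)

  # ---- two-step filtration ----
  spec <- filter_spec(layer1, layer2, id_normalization = "exact")
  filt <- stage_fail("filter", two_step_filtration(family, spec))
  readr::write_tsv(filt$report, file.path(config$out_dir, "filtration_report.tsv"))
  mpr_union <- sort(unique(unlist(filt$mpr_specific$members)))
  write_feature_set(mpr_union, file.path(config$out_dir, "mpr_specific.txt"))
  surviving_denom <- max(length(mpr_union), 1L)
  if (length(mpr_union) > 0) {
    venn_mpr <- venn_partition(filt$mpr_specific, surviving_denom)
    write_venn_tsv(venn_mpr, file.path(config$out_dir, "venn_mpr_specific.tsv"))
  }
  note("filter", surviving = length(mpr_union),
       removed_layer1 = sum(filt$report$removed_layer1),
       removed_layer2 = sum(filt$report$removed_layer2))

  # ---- ORA + comparative dot plot ----
  universe <- proteomic_n$feature_id
  ora_by_geno <- purrr::map(setNames(genotypes, genotypes), function(g) {
    stage_fail("ora", ora(intersect(filt$mpr_specific$members[[g]], universe),
                          universe, collection))
  })
  # term-level exclusion filters: pathways enriched in the two feature
  # filters themselves
  term_filters <- list()
  for (nm in c("ccm1_dosage", "antagonist")) {
    ids <- intersect(if (nm == "ccm1_dosage") layer1 else layer2, universe)
    if (length(ids)) {
      res <- stage_fail("ora", ora(ids, universe, collection))
      term_filters[[nm]] <- res$term_id[res$p_adj < config$de$alpha]
    }
  }
  dot <- stage_fail("ora", comparative_dotplot(ora_by_geno, term_filters))
  for (g in genotypes) {
    write_ora_tsv(select(ora_by_geno[[g]], -dplyr::any_of("members")),
                  file.path(config$out_dir, paste0("ora_", g, ".tsv")))
  }
  write_ora_tsv(dot, file.path(config$out_dir, "dotplot.tsv"))
  note("ora", conditions = length(ora_by_geno),
       excluded_terms = sum(dot$excluded), rows = nrow(dot))

  # ---- TF prediction ----
  if (!is.null(fasta)) {
    std <- stage_fail("tfpredict",
                      standardize_seqs(fasta, config$cv$standard_length))
    emb <- stage_fail("tfpredict", featurize(std))
    report <- stage_fail("tfpredict", cross_validate(std, emb, config$cv))
    write_cv_report(report, file.path(config$out_dir, "tf"))
    note("tfpredict", n_sequences = nrow(fasta),
         n_candidates = length(report$candidates),
         balanced_accuracy = report$means$balanced_accuracy)
  } else {
    report <- NULL
    note("tfpredict", skipped = TRUE)
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, venn = venn, filtration = filt,
                 ora = ora_by_geno, dotplot = dot, cv_report = report,
                 ground_truth = ground_truth, de = de_by_geno,
                 layer1 = layer1, layer2 = layer2))
}
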