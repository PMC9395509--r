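#' End-to-end run configuration
#'
#' Collects everything [run_pipeline()] needs. Exactly one genotype source
#' is used: a simulation spec (with a trait architecture) or a path to an
#' existing cohort (with a phenotype column in its sample table).
#'
#' @param spec A [cohort_spec()] (simulation source), or `NULL`.
#' @param arch A [trait_architecture()] for the simulated trait.
#' @param genotype_path,genotype_format Alternative file source for
#'   [read_genotypes()]; the phenotype column named by `phenotype` must then
#'   be present in the sample table.
#' @param phenotype Phenotype column name (simulated trait is stored under
#'   this name).
#' @param n_discovery,group_weights Discovery-GWAS settings for
#'   [make_discovery_sumstats()] (simulation source only).
#' @param sumstats_path Optional TSV of existing summary statistics (file
#'   source).
#' @param rules A [harmonization_rules()].
#' @param maf_floor Pooled-MAF filter floor.
#' @param n_pcs Number of genetic PCs.
#' @param candidate_p Candidate-SNP p-value threshold.
#' @param prs_grid Clump-and-threshold grid from [ct_grid()].
#' @param ensemble An [ensemble_config()].
#' @param test_frac,split_mode Train/test split settings.
#' @param unrelated_filter Drop related samples (greedy, kinship 0.0625)
#'   before splitting.
#' @param reml Estimate heritability on the training set.
#' @param out_dir Optional output directory for artifacts.
#' @param seed Global seed; fans out to named per-stage streams.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spec = NULL, arch = NULL,
                       genotype_path = NULL, genotype_format = "bundle",
                       phenotype = "trait",
                       n_discovery = 10000, group_weights = NULL,
                       sumstats_path = NULL,
                       rules = harmonization_rules(),
                       maf_floor = 0.01, n_pcs = 5, candidate_p = 1e-4,
                       prs_grid = ct_grid(),
                       ensemble = ensemble_config(),
                       test_frac = 0.2, split_mode = "random",
                       unrelated_filter = TRUE,
                       reml = TRUE, out_dir = NULL, seed = 1L) {
  sim_source <- !is.null(spec)
  file_source <- !is.null(genotype_path)
  if (sim_source == file_source) {
    stop_field("spec/genotype_path", "exactly one genotype source must be given")
  }
  if (sim_source && is.null(arch)) stop_field("arch", "required with a simulation source")
  structure(as.list(environment()), class = "run_config")
}

pipeline_log <- function(fmt, ...) message(sprintf(paste0("[nlprs] ", fmt), ...))

#' Run the full prediction pipeline
#'
#' Chains the stages end to end: obtain genotypes and a phenotype (simulated
#' or from files), obtain discovery summary statistics, harmonize the
#' phenotype, MAF-filter and orient the genotypes, optionally restrict to a
#' pairwise-unrelated sample set, split 80/20 stratified by group, compute
#' genetic PCs on the training set, tune the clump-and-threshold PRS, fit
#' the four model families (linear PRS, LASSO baseline, boosted trees alone,
#' boosted trees with the PRS feature), evaluate PVE per model and per group
#' on the held-out set, and estimate REML heritability for context. Every
#' stage draws from a named stream derived from the global seed, so a rerun
#' with the same config is bit-identical.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `report`
#'   (an `evaluation_report`), fitted `models`, the `split`, the tuned
#'   `prs`, and a `manifest`. When `config$out_dir` is set, the report,
#'   model summaries, PRS weights, config, and manifest are written there.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_field("config", "must be a run_config")
  seed <- config$seed
  stage <- function(k) derive_seed(seed, k)

  if (!is.null(config$spec)) {
    pipeline_log("simulating cohort (%d variants)", config$spec$n_variants)
    cohort <- simulate_genotypes(config$spec, stream = stage(1))
    trait <- simulate_trait(cohort, config$arch, seed = stage(2))
    cohort$samples[[config$phenotype]] <- trait$phenotype
    cohort$samples$medication <- trait$med_flags
    pipeline_log("simulating discovery GWAS (n = %d)", config$n_discovery)
    sumstats <- make_discovery_sumstats(config$spec, config$arch,
                                        n_discovery = config$n_discovery,
                                        group_weights = config$group_weights,
                                        seed = stage(3))
  } else {
    pipeline_log("reading genotypes from %s", config$genotype_path)
    cohort <- read_genotypes(config$genotype_path, config$genotype_format)
    if (is.null(cohort$samples[[config$phenotype]])) {
      stop(sprintf("phenotype column `%s` missing from sample table",
                   config$phenotype), call. = FALSE)
    }
    if (is.null(config$sumstats_path)) {
      stop_field("sumstats_path", "required with a file genotype source")
    }
    sumstats <- read_sumstats(config$sumstats_path)
  }

  pipeline_log("harmonizing phenotype `%s`", config$phenotype)
  adj <- harmonize(cohort$samples, config$phenotype, config$rules)
  y <- adj$values

  cohort <- filter_maf(cohort, floor = config$maf_floor)
  pipeline_log("%d variants after MAF filter", ncol(cohort$genotypes))

  # ancestry-adjusted GRM: in a multi-ancestry cohort the plain GRM's
  # within-group offset would masquerade as relatedness (see ?compute_grm)
  K <- compute_grm(cohort, adjust_pcs = config$n_pcs)
  if (isTRUE(config$unrelated_filter)) {
    keep <- select_unrelated(K)
    if (length(keep) < nrow(cohort$genotypes)) {
      pipeline_log("unrelated filter keeps %d / %d samples",
                   length(keep), nrow(cohort$genotypes))
      sel <- cohort$samples$id %in% keep
      cohort$genotypes <- cohort$genotypes[sel, , drop = FALSE]
      cohort$samples <- cohort$samples[sel, , drop = FALSE]
      y <- y[sel]
      K <- K[keep, keep]
    }
  }

  split <- split_train_test(cohort, test_frac = config$test_frac,
                            seed = stage(4), K = K, mode = config$split_mode)
  tr <- cohort$samples$id %in% split$train_ids
  te <- cohort$samples$id %in% split$test_ids
  cohort_tr <- subset_cohort(cohort, split$train_ids)
  cohort_te <- subset_cohort(cohort, split$test_ids)
  y_tr <- y[tr]
  y_te <- y[te]

  pipeline_log("computing %d genetic PCs", config$n_pcs)
  pcs <- compute_pcs(cohort_tr, k = config$n_pcs)
  pcs_tr <- pcs$scores
  pcs_te <- predict(pcs, cohort_te)

  pipeline_log("tuning clump-and-threshold PRS")
  prs <- tune_ct(sumstats, cohort_tr, y_tr, covariates = pcs_tr,
                 grid = config$prs_grid)
  prs_tr <- prs_score(cohort_tr, prs$weights)
  prs_te <- prs_score(cohort_te, prs$weights)

  candidates <- candidate_filter(sumstats, cohort_tr, threshold = config$candidate_p)
  pipeline_log("%d candidate SNPs at p < %g", length(candidates), config$candidate_p)

  cfg_alone <- config$ensemble
  cfg_alone$include_prs <- FALSE
  cfg_alone$seed <- stage(5)
  cfg_prs <- config$ensemble
  cfg_prs$include_prs <- TRUE
  cfg_prs$seed <- stage(5)

  pipeline_log("fitting ensemble (SNPs only)")
  ens <- fit_ensemble(cohort_tr, y_tr, candidates, cfg_alone, pcs = pcs_tr)
  pipeline_log("fitting ensemble (SNPs + PRS feature)")
  ens_prs <- fit_ensemble(cohort_tr, y_tr, candidates, cfg_prs,
                          pcs = pcs_tr, prs = prs_tr)
  pipeline_log("fitting LASSO baseline on %d selected SNPs",
               length(ens$selected_snps))
  lasso <- lasso_baseline(cohort_tr, y_tr, ens$selected_snps, ens$alpha_star,
                          covariates = pcs_tr)

  predictions <- list(
    prs = predict(prs, cohort_te, covariates = pcs_te),
    lasso = predict(lasso, cohort_te, covariates = pcs_te),
    xgb = predict(ens, cohort_te, pcs = pcs_te),
    xgb_prs = predict(ens_prs, cohort_te, pcs = pcs_te, prs = prs_te))
  train_predictions <- list(
    prs = predict(prs, cohort_tr, covariates = pcs_tr),
    lasso = predict(lasso, cohort_tr, covariates = pcs_tr),
    xgb = predict(ens, cohort_tr, pcs = pcs_tr),
    xgb_prs = predict(ens_prs, cohort_tr, pcs = pcs_tr, prs = prs_tr))

  herit <- NULL
  if (isTRUE(config$reml)) {
    pipeline_log("REML heritability on the training set")
    herit <- tryCatch(reml_h2(y_tr, K[split$train_ids, split$train_ids]),
                      error = function(e) {
                        warning("heritability skipped: ", conditionMessage(e),
                                call. = FALSE)
                        NULL
                      })
  }

  report <- stratified_report(predictions, y_te, cohort_te$samples$group,
                              heritability = herit, split = split)
  # overfitting guard: training-minus-test PVE gap per model
  keep_tr <- !is.na(y_tr)
  gaps <- vapply(names(predictions), function(m) {
    pve(y_tr[keep_tr], train_predictions[[m]][keep_tr]) -
      report$pve_table$pve[report$pve_table$model == m &
                             report$pve_table$group == "pooled"]
  }, 0)
  manifest <- list(package_version = as.character(utils::packageVersion("nlprs")),
                   seed = seed,
                   n_train = sum(tr), n_test = sum(te),
                   n_variants = ncol(cohort$genotypes),
                   n_candidates = length(candidates),
                   train_test_gap = as.list(gaps),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  result <- structure(list(report = report,
                           models = list(prs = prs, lasso = lasso,
                                         xgb = ens, xgb_prs = ens_prs),
                           split = split, predictions = predictions,
                           manifest = manifest, y_test = y_te),
                      class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    report_to_json(report, file.path(config$out_dir, "report.json"))
    utils::write.table(report$pve_table, file.path(config$out_dir, "pve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(prs$weights, file.path(config$out_dir, "prs_weights.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_out <- config
    cfg_out$spec <- NULL; cfg_out$arch <- NULL
    cfg_out$rules <- NULL; cfg_out$ensemble <- NULL; cfg_out$prs_grid <- NULL
    yaml::write_yaml(Filter(Negate(is.null), unclass(cfg_out)),
                     file.path(config$out_dir, "config.yaml"))
    files <- list.files(config$out_dir, full.names = TRUE)
    manifest$file_md5 <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    result$manifest <- manifest
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d train / %d test samples\n",
              x$manifest$n_train, x$manifest$n_test))
  print(x$report)
  invisible(x)
}
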