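#' Configuration of the LASSO + gradient-boosted-trees ensemble
#'
#' Holds the joint cross-validation settings: the candidate L1 penalties for
#' the LASSO selection stage, the number of chromosome-balanced SNP chunks
#' the LASSO is fit on, the boosting cross-validation folds, the tree cap
#' and early-stopping patience, and the fixed booster settings (learning
#' rate 0.01, maximum depth 5, column subsample per tree 0.9, minimum child
#' weight 10, row subsample 0.5).
#'
#' @param alpha_grid Candidate L1 penalties (> 0); the default geometric
#'   grid spans dense-to-empty selections on standardized features.
#' @param n_chunks Number of SNP chunks for the LASSO stage (default 5).
#' @param cv_folds Boosting cross-validation folds (default 3).
#' @param max_trees Boosting-round cap (default 10000).
#' @param early_stop_rounds Early-stopping patience (default 10).
#' @param booster Fixed booster settings; override only for experiments.
#' @param include_prs Add the (standardized) PRS as a booster feature.
#' @param include_pcs Add the genetic PC scores as features (default TRUE).
#' @param lasso_cv_folds When `lasso_mode = "majority"`, the number of folds
#'   whose per-fold selections are voted on (default 10).
#' @param lasso_mode `"single"` fits the LASSO once per penalty on the full
#'   training data; `"majority"` averages selection over `lasso_cv_folds`
#'   folds and keeps SNPs selected in a majority of them.
#' @param seed Integer seed for fold assignment and booster subsampling.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(alpha_grid = 10^seq(-3, 0, length.out = 8),
                            n_chunks = 5,
                            cv_folds = 3,
                            max_trees = 10000,
                            early_stop_rounds = 10,
                            booster = list(eta = 0.01, max_depth = 5,
                                           colsample_bytree = 0.9,
                                           min_child_weight = 10,
                                           subsample = 0.5),
                            include_prs = FALSE,
                            include_pcs = TRUE,
                            lasso_cv_folds = 10,
                            lasso_mode = c("single", "majority"),
                            seed = 1L) {
  if (!length(alpha_grid) || any(alpha_grid <= 0)) {
    stop_field("alpha_grid", "must be non-empty with values > 0")
  }
  if (cv_folds < 2) stop_field("cv_folds", "need >= 2 folds")
  structure(list(alpha_grid = sort(alpha_grid), n_chunks = as.integer(n_chunks),
                 cv_folds = as.integer(cv_folds), max_trees = as.integer(max_trees),
                 early_stop_rounds = as.integer(early_stop_rounds),
                 booster = booster, include_prs = include_prs,
                 include_pcs = include_pcs,
                 lasso_cv_folds = as.integer(lasso_cv_folds),
                 lasso_mode = match.arg(lasso_mode), seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Partition variants into chromosome-balanced chunks
#'
#' Chromosomes are assigned whole: largest variant count first, each into
#' the currently smallest chunk (ties toward the lower chunk index), so
#' chunk sizes come out roughly equal and no chromosome is split.
#'
#' @param variants Data frame with `id` and `chrom` columns.
#' @param n_chunks Target number of chunks (default 5).
#' @return List of variant-id vectors partitioning the input; fewer,
#'   non-empty chunks (with a warning) when there are fewer chromosomes
#'   than chunks.
#' @export
partition_snps <- function(variants, n_chunks = 5) {
  counts <- table(variants$chrom)
  if (length(counts) < n_chunks) {
    warning(sprintf("only %d chromosome(s); returning %d chunk(s)",
                    length(counts), length(counts)), call. = FALSE)
    n_chunks <- length(counts)
  }
  ord <- order(-as.integer(counts), names(counts))
  load <- numeric(n_chunks)
  assign_to <- integer(length(counts))
  for (k in ord) {
    j <- which.min(load)
    assign_to[k] <- j
    load[j] <- load[j] + counts[k]
  }
  lapply(seq_len(n_chunks), function(j) {
    chroms <- names(counts)[assign_to == j]
    variants$id[as.character(variants$chrom) %in% chroms]
  })
}

# Non-zero-coefficient SNP ids of one penalized fit at penalty `alpha`.
lasso_fit_chunk <- function(x, y, alpha, n_snps) {
  if (ncol(x) < 2) {  # glmnet needs >= 2 columns; pad with an inert dummy
    x <- cbind(x, `.dummy` = 0)
  }
  pf <- c(rep(1, n_snps), rep(0, ncol(x) - n_snps))
  lmax <- suppressWarnings(
    max(abs(crossprod(scale(x[, seq_len(n_snps), drop = FALSE]),
                      y - mean(y))), na.rm = TRUE)) / length(y)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  hi <- max(lmax * 1.05, alpha * 1.05)
  lambdas <- exp(seq(log(hi), log(alpha), length.out = 60))
  lambdas[length(lambdas)] <- alpha
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        penalty.factor = pf, lambda = lambdas,
                        standardize = TRUE)
  cf <- as.matrix(stats::coef(fit, s = alpha))[-1, 1]
  names(which(cf[seq_len(n_snps)] != 0))
}

#' LASSO SNP selection over chromosome chunks
#'
#' For each chunk, fits an L1-penalized least-squares model of the phenotype
#' on the standardized chunk SNPs plus unpenalized covariates at the given
#' penalty, and returns the union of SNPs with non-zero coefficients across
#' chunks. In `"majority"` mode the per-chunk fit is repeated on
#' `lasso_cv_folds` leave-one-fold-out subsets and a SNP is kept when
#' selected in more than half of them.
#'
#' @param G Numeric genotype matrix of the candidate SNPs (samples x SNPs).
#' @param y Phenotype vector.
#' @param alpha L1 penalty (> 0), on the `glmnet` lambda scale.
#' @param covariates Optional numeric covariate matrix, left unpenalized.
#' @param chunks List of SNP-id chunks from [partition_snps()]; a single
#'   chunk of all columns when `NULL`.
#' @param config An [ensemble_config()] (used for `lasso_mode` settings).
#' @return Character vector of selected SNP ids.
#' @export
lasso_select <- function(G, y, alpha, covariates = NULL, chunks = NULL,
                         config = ensemble_config()) {
  if (alpha <= 0) stop_field("alpha", "must be > 0")
  chunks <- chunks %||% list(colnames(G))
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  selected <- character()
  for (ch in chunks) {
    ch <- intersect(ch, colnames(G))
    if (!length(ch)) next
    x <- cbind(G[, ch, drop = FALSE], C)
    if (config$lasso_mode == "single") {
      sel <- lasso_fit_chunk(x, y, alpha, length(ch))
    } else {
      folds <- with_rng(derive_seed(config$seed, 777L),
                        sample(rep_len(seq_len(config$lasso_cv_folds), length(y))))
      votes <- table(unlist(lapply(seq_len(config$lasso_cv_folds), function(k) {
        lasso_fit_chunk(x[folds != k, , drop = FALSE], y[folds != k],
                        alpha, length(ch))
      })))
      sel <- names(votes)[votes > config$lasso_cv_folds / 2]
    }
    selected <- c(selected, sel)
  }
  unique(selected)
}

#' Cross-validated gradient-boosted trees with early stopping
#'
#' k-fold cross-validation of the booster on the feature matrix with the
#' fixed settings from the config: up to `max_trees` rounds, stopping when
#' the mean held-out squared error has not improved for
#' `early_stop_rounds` rounds. Each fold's held-out part is both the
#' evaluation set and the early-stopping monitor (aggregated as the mean
#' across folds). The selected round count `theta` is the argmin of the
#' mean held-out MSE curve.
#'
#' @param features Numeric feature matrix (samples x features).
#' @param y Phenotype vector.
#' @param config An [ensemble_config()].
#' @return List with `theta`, `cv_mse` (mean held-out MSE at `theta`), and
#'   `curve` (mean held-out MSE per round).
#' @export
gbt_cv <- function(features, y, config = ensemble_config()) {
  if (is.null(dim(features)) || ncol(features) == 0) {
    stop("empty feature set; widen the alpha grid so the LASSO selects SNPs",
         call. = FALSE)
  }
  params <- c(config$booster,
              list(objective = "reg:squarederror", nthread = 1,
                   seed = config$seed))
  with_rng(config$seed, {
    cv <- xgboost::xgb.cv(params = params,
                          data = xgboost::xgb.DMatrix(as.matrix(features), label = y),
                          nrounds = config$max_trees,
                          nfold = config$cv_folds,
                          early_stopping_rounds = config$early_stop_rounds,
                          verbose = 0)
    curve <- cv$evaluation_log$test_rmse_mean^2
    theta <- which.min(curve)
    list(theta = as.integer(theta), cv_mse = curve[theta], curve = curve)
  })
}

# Assemble the booster feature matrix: selected SNP allele counts
# (mean-imputed with training means), PC scores, optionally the PRS
# standardized with training constants.
build_features <- function(G, snp_ids, snp_means, pcs = NULL,
                           prs = NULL, prs_center = 0, prs_scale = 1) {
  parts <- list()
  if (length(snp_ids)) {
    parts$snps <- impute_genotypes(G[, snp_ids, drop = FALSE],
                                   means = snp_means[snp_ids])
  }
  if (!is.null(pcs)) parts$pcs <- as.matrix(pcs)
  if (!is.null(prs)) parts$prs <- matrix((prs - prs_center) / prs_scale,
                                         ncol = 1, dimnames = list(NULL, "PRS"))
  do.call(cbind, parts)
}

#' Fit the LASSO -> gradient-boosted-trees ensemble
#'
#' The joint tuning loop: for every penalty in `alpha_grid`, (1) select
#' SNPs by chunked LASSO with unpenalized covariates, (2) cross-validate
#' the booster on the selected SNPs plus PCs (and the standardized PRS when
#' configured), recording the best round count `theta_alpha` and its mean
#' held-out MSE. The penalty with the smallest cross-validated MSE wins
#' (ties toward the larger penalty, i.e. fewer SNPs), and the booster is
#' refit on the full training data with `theta` rounds.
#'
#' @param cohort Training `genotype_cohort`.
#' @param y Adjusted phenotype for the training samples.
#' @param candidates Candidate SNP ids (from [candidate_filter()]).
#' @param config An [ensemble_config()].
#' @param pcs Optional PC score matrix for the training samples.
#' @param prs Optional per-sample PRS vector (training samples).
#' @return An object of class `ensemble_model` with `alpha_star`,
#'   `selected_snps`, `theta`, `cv_mse`, the fitted `booster`, the feature
#'   manifest, and the per-penalty `cv_table`.
#' @export
fit_ensemble <- function(cohort, y, candidates, config = ensemble_config(),
                         pcs = NULL, prs = NULL) {
  assert_cohort(cohort)
  ok <- !is.na(y)
  candidates <- intersect(candidates, cohort$variants$id)
  if (!length(candidates)) stop("empty candidate SNP set", call. = FALSE)
  G <- cohort$genotypes[ok, candidates, drop = FALSE]
  yv <- y[ok]
  snp_means <- colMeans(G, na.rm = TRUE)
  Gi <- impute_genotypes(G, means = snp_means)
  pcs_ok <- if (!is.null(pcs) && config$include_pcs)
    as.matrix(pcs)[ok, , drop = FALSE] else NULL
  prs_ok <- NULL; prs_center <- 0; prs_scale <- 1
  if (!is.null(prs) && config$include_prs) {
    prs_ok <- as.numeric(prs)[ok]
    prs_center <- mean(prs_ok)
    prs_scale <- stats::sd(prs_ok)
    if (prs_scale == 0) prs_scale <- 1
  }
  if (stats::var(yv) < 1e-12) {
    # degenerate outcome: constant predictor, no selection
    return(structure(list(alpha_star = config$alpha_grid[length(config$alpha_grid)],
                          selected_snps = character(), theta = 0L, cv_mse = 0,
                          booster = NULL, constant = mean(yv),
                          snp_means = snp_means, include_pcs = config$include_pcs,
                          include_prs = config$include_prs,
                          prs_center = prs_center, prs_scale = prs_scale,
                          cv_table = NULL, config = config),
                     class = "ensemble_model"))
  }
  chunks <- partition_snps(cohort$variants[cohort$variants$id %in% candidates, ],
                           config$n_chunks)
  tab <- data.frame(alpha = config$alpha_grid, n_snps = NA_integer_,
                    theta = NA_integer_, cv_mse = NA_real_)
  sels <- vector("list", length(config$alpha_grid))
  for (i in seq_along(config$alpha_grid)) {
    a <- config$alpha_grid[i]
    sel <- lasso_select(Gi, yv, a, covariates = pcs_ok, chunks = chunks,
                        config = config)
    sels[[i]] <- sel
    tab$n_snps[i] <- length(sel)
    if (!length(sel)) next
    feats <- build_features(Gi, sel, snp_means, pcs_ok, prs_ok,
                            prs_center, prs_scale)
    cvr <- gbt_cv(feats, yv, config)
    tab$theta[i] <- cvr$theta
    tab$cv_mse[i] <- cvr$cv_mse
  }
  if (all(is.na(tab$cv_mse))) {
    stop("every penalty yields an empty SNP selection; extend alpha_grid downward",
         call. = FALSE)
  }
  best_mse <- min(tab$cv_mse, na.rm = TRUE)
  i_star <- max(which(!is.na(tab$cv_mse) & tab$cv_mse == best_mse))  # ties -> larger alpha
  sel <- sels[[i_star]]
  feats <- build_features(Gi, sel, snp_means, pcs_ok, prs_ok,
                          prs_center, prs_scale)
  params <- c(config$booster, list(objective = "reg:squarederror", nthread = 1,
                                   seed = config$seed))
  booster <- with_rng(config$seed, {
    xgboost::xgb.train(params = params,
                       data = xgboost::xgb.DMatrix(feats, label = yv),
                       nrounds = tab$theta[i_star], verbose = 0)
  })
  structure(list(alpha_star = tab$alpha[i_star], selected_snps = sel,
                 theta = tab$theta[i_star], cv_mse = tab$cv_mse[i_star],
                 booster = booster, constant = NULL, snp_means = snp_means,
                 include_pcs = config$include_pcs, include_prs = config$include_prs,
                 prs_center = prs_center, prs_scale = prs_scale,
                 cv_table = tab, config = config),
            class = "ensemble_model")
}

#' Predict from a fitted ensemble model
#'
#' Rebuilds the feature manifest for the new samples (allele counts of the
#' selected SNPs imputed with training means, PC scores, standardized PRS
#' with training constants) and runs the booster; predictions are a pure
#' function of that manifest.
#'
#' @param object An `ensemble_model`.
#' @param cohort A `genotype_cohort` containing the selected SNPs.
#' @param pcs PC scores of the new samples (projected with the training
#'   loadings) when the model uses PCs.
#' @param prs PRS vector of the new samples when the model uses the PRS.
#' @param ... Unused.
#' @return Named numeric prediction vector.
#' @export
predict.ensemble_model <- function(object, cohort, pcs = NULL, prs = NULL, ...) {
  assert_cohort(cohort)
  n <- nrow(cohort$genotypes)
  if (!is.null(object$constant)) {
    return(stats::setNames(rep(object$constant, n), cohort$samples$id))
  }
  feats <- build_features(cohort$genotypes[, , drop = FALSE],
                          object$selected_snps, object$snp_means,
                          if (object$include_pcs) pcs else NULL,
                          if (object$include_prs) prs else NULL,
                          object$prs_center, object$prs_scale)
  stats::setNames(stats::predict(object$booster, xgboost::xgb.DMatrix(feats)),
                  cohort$samples$id)
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf(
    "ensemble_model: alpha* = %.4g, %d SNPs selected, theta = %d trees, cv MSE %.4f%s\n",
    x$alpha_star, length(x$selected_snps), x$theta, x$cv_mse,
    if (x$include_prs) " (+PRS feature)" else ""))
  invisible(x)
}

#' LASSO baseline on the ensemble's selected SNPs
#'
#' Refits an L1-penalized linear model restricted to exactly the SNPs the
#' ensemble selected (plus unpenalized covariates), either at the
#' ensemble's `alpha_star` (default) or with the penalty chosen by
#' cross-validation on the LASSO loss (`mode = "cv"`). This is the linear
#' comparator: same variants, no interactions.
#'
#' @param cohort Training `genotype_cohort`.
#' @param y Adjusted phenotype.
#' @param selected_snps SNP ids from a fitted [fit_ensemble()] model.
#' @param alpha Penalty for `mode = "fixed"`.
#' @param covariates Optional unpenalized covariate matrix (PCs).
#' @param mode `"fixed"` or `"cv"`.
#' @return An object of class `lasso_model` with the coefficient vector and
#'   prediction constants.
#' @export
lasso_baseline <- function(cohort, y, selected_snps, alpha,
                           covariates = NULL, mode = c("fixed", "cv")) {
  mode <- match.arg(mode)
  assert_cohort(cohort)
  if (!length(selected_snps)) stop("empty SNP selection", call. = FALSE)
  ok <- !is.na(y)
  snp_means <- colMeans(cohort$genotypes[ok, selected_snps, drop = FALSE],
                        na.rm = TRUE)
  G <- impute_genotypes(cohort$genotypes[ok, selected_snps, drop = FALSE],
                        means = snp_means)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)[ok, , drop = FALSE]
  x <- cbind(G, C)
  yv <- y[ok]
  if (stats::var(yv) < 1e-12) {
    return(structure(list(coef = stats::setNames(rep(0, ncol(x)), colnames(x)),
                          intercept = mean(yv), snp_ids = selected_snps,
                          snp_means = snp_means, alpha = alpha, mode = mode),
                     class = "lasso_model"))
  }
  padded <- ncol(x) < 2
  if (padded) x <- cbind(x, `.dummy` = 0)
  pf <- c(rep(1, ncol(G)), rep(0, ncol(x) - ncol(G)))
  if (mode == "cv") {
    cvfit <- glmnet::cv.glmnet(x, yv, family = "gaussian", alpha = 1,
                               penalty.factor = pf)
    alpha <- cvfit$lambda.min
    cf <- as.matrix(stats::coef(cvfit, s = "lambda.min"))[, 1]
  } else {
    lmax <- suppressWarnings(
      max(abs(crossprod(scale(G), yv - mean(yv))), na.rm = TRUE)) / length(yv)
    if (!is.finite(lmax) || lmax <= 0) lmax <- 1
    hi <- max(lmax * 1.05, alpha * 1.05)
    lambdas <- exp(seq(log(hi), log(alpha), length.out = 60))
    lambdas[length(lambdas)] <- alpha
    fit <- glmnet::glmnet(x, yv, family = "gaussian", alpha = 1,
                          penalty.factor = pf, lambda = lambdas)
    cf <- as.matrix(stats::coef(fit, s = alpha))[, 1]
  }
  if (padded) cf <- cf[names(cf) != ".dummy"]
  structure(list(coef = cf[-1], intercept = cf[1], snp_ids = selected_snps,
                 snp_means = snp_means, alpha = alpha, mode = mode),
            class = "lasso_model")
}

#' Predict from the LASSO baseline
#'
#' @param object A `lasso_model`.
#' @param cohort A `genotype_cohort` containing the model's SNPs.
#' @param covariates Covariate matrix matching the training one.
#' @param ... Unused.
#' @return Named numeric prediction vector.
#' @export
predict.lasso_model <- function(object, cohort, covariates = NULL, ...) {
  G <- impute_genotypes(cohort$genotypes[, object$snp_ids, drop = FALSE],
                        means = object$snp_means)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  x <- cbind(G, C)
  stats::setNames(as.vector(object$intercept + x %*% object$coef),
                  cohort$samples$id)
}

#' Random-SNP selection baseline for the booster
#'
#' Repeatedly draws `n_snps` candidate SNPs uniformly without replacement,
#' cross-validates and refits the booster on them (same fixed settings),
#' and evaluates the test-set percentage of variance explained. The mean
#' over repetitions benchmarks how much of the ensemble's performance is
#' owed to the LASSO selection rather than to boosting itself.
#'
#' @param cohort_train,cohort_test Training and test `genotype_cohort`s.
#' @param y_train,y_test Adjusted phenotypes for the two sets.
#' @param candidates Candidate SNP id pool.
#' @param n_snps Number of SNPs per draw (> 0).
#' @param reps Number of repetitions (default 20).
#' @param config An [ensemble_config()].
#' @param pcs_train,pcs_test Optional PC scores for the two sets.
#' @param seed Seed for the draws.
#' @return List with `mean_pve`, `sd_pve`, and the per-repetition `pves`.
#' @export
random_snp_baseline <- function(cohort_train, cohort_test, y_train, y_test,
                                candidates, n_snps, reps = 20,
                                config = ensemble_config(),
                                pcs_train = NULL, pcs_test = NULL, seed = 1L) {
  if (n_snps <= 0) stop_field("n_snps", "must be > 0")
  candidates <- intersect(candidates, cohort_train$variants$id)
  if (n_snps > length(candidates)) {
    stop_field("n_snps", "exceeds the candidate-set size")
  }
  draws <- with_rng(seed, {
    lapply(seq_len(reps), function(r) sample(candidates, n_snps))
  })
  ok <- !is.na(y_train)
  snp_means <- colMeans(cohort_train$genotypes[ok, candidates, drop = FALSE],
                        na.rm = TRUE)
  pves <- vapply(seq_len(reps), function(r) {
    sel <- draws[[r]]
    Gtr <- impute_genotypes(cohort_train$genotypes[ok, sel, drop = FALSE],
                            means = snp_means[sel])
    feats <- build_features(Gtr, sel, snp_means,
                            if (!is.null(pcs_train)) as.matrix(pcs_train)[ok, , drop = FALSE])
    cvr <- gbt_cv(feats, y_train[ok], config)
    params <- c(config$booster, list(objective = "reg:squarederror",
                                     nthread = 1, seed = config$seed))
    booster <- with_rng(config$seed, {
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(feats, label = y_train[ok]),
                         nrounds = cvr$theta, verbose = 0)
    })
    Gte <- impute_genotypes(cohort_test$genotypes[, sel, drop = FALSE],
                            means = snp_means[sel])
    fte <- build_features(Gte, sel, snp_means,
                          if (!is.null(pcs_test)) as.matrix(pcs_test))
    pred <- stats::predict(booster, xgboost::xgb.DMatrix(fte))
    keep <- !is.na(y_test)
    pve(y_test[keep], pred[keep])
  }, 0)
  list(mean_pve = mean(pves), sd_pve = stats::sd(pves), pves = pves)
}
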