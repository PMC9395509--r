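#' Remove strand-ambiguous variants from summary statistics
#'
#' Drops variants whose allele pair is A/T or C/G in either order; for
#' those, strand cannot be resolved from the alleles alone.
#'
#' @param sumstats Summary-statistics data frame.
#' @return The filtered data frame; warns when nothing survives.
#' @export
remove_ambiguous <- function(sumstats) {
  assert_sumstats(sumstats)
  pair <- paste(pmin(sumstats$a1, sumstats$a2), pmax(sumstats$a1, sumstats$a2))
  keep <- !(pair %in% c("A T", "C G"))
  if (!any(keep)) warning("all variants are strand-ambiguous", call. = FALSE)
  out <- sumstats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise LD as squared allele-count correlation
#'
#' Squared Pearson correlation between the unphased allele counts of two
#' variants, computed on the cohort samples with both genotypes observed.
#'
#' @param cohort A `genotype_cohort`.
#' @param i,j Variant ids (or column indices).
#' @return r-squared in `[0, 1]`; `0` with a warning for a monomorphic
#'   variant.
#' @export
ld_r2 <- function(cohort, i, j) {
  assert_cohort(cohort)
  gi <- cohort$genotypes[, i]
  gj <- cohort$genotypes[, j]
  ok <- !is.na(gi) & !is.na(gj)
  if (stats::sd(gi[ok]) == 0 || stats::sd(gj[ok]) == 0) {
    warning("monomorphic variant in LD computation; r2 defined as 0", call. = FALSE)
    return(0)
  }
  stats::cor(gi[ok], gj[ok])^2
}

#' Greedy LD clumping of summary statistics
#'
#' Sorts variants by ascending p-value (ties by chromosome, then position),
#' repeatedly takes the best remaining variant as an index SNP, and removes
#' all remaining variants on the same chromosome within `window_kb`
#' kilobases on either side whose squared correlation with the index exceeds
#' `clump_r2`. LD is measured on the supplied cohort (the training cohort
#' doubles as the LD reference panel).
#'
#' @param sumstats Summary statistics aligned to the cohort (see
#'   [align_sumstats()]).
#' @param cohort A `genotype_cohort`.
#' @param window_kb Clumping distance on each side of the index SNP, kb.
#' @param clump_r2 LD r-squared threshold; strictly greater is pruned.
#' @return Character vector of index-variant ids in selection order.
#' @export
clump <- function(sumstats, cohort, window_kb = 250, clump_r2 = 0.1) {
  assert_cohort(cohort)
  ss <- sumstats[sumstats$id %in% cohort$variants$id, , drop = FALSE]
  if (!nrow(ss)) return(character())
  ss <- ss[order(ss$p, ss$chrom, ss$pos), , drop = FALSE]
  G <- impute_genotypes(cohort$genotypes[, ss$id, drop = FALSE])
  win <- window_kb * 1000
  active <- rep(TRUE, nrow(ss))
  idx <- character()
  while (any(active)) {
    i <- which(active)[1]
    idx <- c(idx, ss$id[i])
    active[i] <- FALSE
    near <- which(active & ss$chrom == ss$chrom[i] &
                    abs(ss$pos - ss$pos[i]) <= win)
    if (length(near)) {
      g0 <- G[, i]
      r2 <- if (stats::sd(g0) == 0) rep(0, length(near)) else
        suppressWarnings(as.vector(stats::cor(g0, G[, near, drop = FALSE]))^2)
      r2[is.na(r2)] <- 0
      active[near[r2 > clump_r2]] <- FALSE
    }
  }
  idx
}

#' Polygenic score as a weighted allele-count sum
#'
#' `score_s = sum_v w_v g_sv` over the weighted variants with p-value below
#' `p_threshold`. Weights are oriented to the cohort's counted allele: a
#' weight whose effect allele is the cohort's other allele has its sign
#' flipped (the constant offset this ignores is absorbed by the intercept of
#' any downstream regression). Missing genotypes contribute the variant's
#' mean count.
#'
#' @param cohort A `genotype_cohort`.
#' @param weights Data frame with columns `id`, `a1` (effect allele),
#'   `beta`, and optionally `p`.
#' @param p_threshold Strict inclusion threshold applied to `weights$p`
#'   when present.
#' @return Named numeric vector of per-sample scores.
#' @export
prs_score <- function(cohort, weights, p_threshold = 1) {
  assert_cohort(cohort)
  if (!is.null(weights$p)) weights <- weights[weights$p < p_threshold, , drop = FALSE]
  v <- cohort$variants
  m <- match(weights$id, v$id)
  if (anyNA(m)) {
    stop("weights refer to variant(s) absent from the cohort: ",
         paste(utils::head(weights$id[is.na(m)], 5), collapse = ", "), call. = FALSE)
  }
  sgn <- ifelse(weights$a1 == v$a1[m], 1,
                ifelse(weights$a1 == v$a2[m], -1, NA))
  if (anyNA(sgn)) {
    stop("allele mismatch for variant(s): ",
         paste(utils::head(weights$id[is.na(sgn)], 5), collapse = ", "), call. = FALSE)
  }
  if (!nrow(weights)) {
    return(stats::setNames(numeric(nrow(cohort$genotypes)), cohort$samples$id))
  }
  G <- impute_genotypes(cohort$genotypes[, weights$id, drop = FALSE])
  stats::setNames(as.vector(G %*% (sgn * weights$beta)), cohort$samples$id)
}

#' Default clump-and-threshold tuning grid
#'
#' Clumping windows of 250 and 500 kb, clumping r-squared of 0.1, 0.2, 0.3,
#' and p-value thresholds from 0.5 down to 1e-10.
#'
#' @return A list with `window_kb`, `clump_r2`, and `p_thresholds`.
#' @export
ct_grid <- function() {
  list(window_kb = c(250, 500), clump_r2 = c(0.1, 0.2, 0.3),
       p_thresholds = c(0.5, 0.1, 0.05, 0.01, 10^-(3:10)))
}

#' Tune a clump-and-threshold PRS by training MSE
#'
#' For every grid cell (clumping window x clumping r-squared x p-value
#' threshold): clump the summary statistics on the training cohort, score
#' the samples with the surviving weights below the threshold, fit an OLS
#' model of the adjusted phenotype on the score plus the supplied covariates
#' (genetic PCs and any others), and record the training mean squared error.
#' The cell with the smallest training MSE wins; ties go to the cell with
#' fewer variants, then the smaller window. Strand-ambiguous variants are
#' removed before clumping.
#'
#' @param sumstats Summary statistics (aligned internally to the cohort).
#' @param cohort Training `genotype_cohort`.
#' @param y Adjusted phenotype for the training samples.
#' @param covariates Numeric matrix of covariates for the selection model
#'   (typically the genetic PC scores); may be `NULL`.
#' @param grid Tuning grid as from [ct_grid()].
#' @return An object of class `prs_model`: the selected hyperparameters,
#'   oriented `weights`, training `scores`, `train_mse`, the fitted linear
#'   model coefficients, and the full `grid` results table.
#' @export
tune_ct <- function(sumstats, cohort, y, covariates = NULL, grid = ct_grid()) {
  assert_cohort(cohort)
  ss <- remove_ambiguous(align_sumstats(sumstats, cohort))
  ok <- !is.na(y)
  design0 <- if (is.null(covariates)) matrix(0, nrow(cohort$genotypes), 0) else
    as.matrix(covariates)
  cells <- expand.grid(window_kb = grid$window_kb, clump_r2 = grid$clump_r2,
                       p_threshold = grid$p_thresholds,
                       KEEP.OUT.ATTRS = FALSE)
  cells$n_variants <- NA_integer_
  cells$train_mse <- NA_real_
  skipped <- FALSE
  for (w in grid$window_kb) for (r2 in grid$clump_r2) {
    idx <- clump(ss, cohort, window_kb = w, clump_r2 = r2)
    ssc <- ss[match(idx, ss$id), , drop = FALSE]
    for (pt in grid$p_thresholds) {
      row <- which(cells$window_kb == w & cells$clump_r2 == r2 &
                     cells$p_threshold == pt)
      wts <- ssc[ssc$p < pt, , drop = FALSE]
      cells$n_variants[row] <- nrow(wts)
      if (!nrow(wts)) { skipped <- TRUE; next }
      sc <- prs_score(cohort, wts)
      X <- cbind(1, score = sc[ok], design0[ok, , drop = FALSE])
      fit <- stats::lm.fit(X, y[ok])
      cells$train_mse[row] <- mean(fit$residuals^2)
    }
  }
  if (skipped) warning("grid cell(s) with no surviving variants skipped",
                       call. = FALSE)
  if (all(is.na(cells$train_mse))) {
    stop("every grid cell is empty; no PRS can be built", call. = FALSE)
  }
  ord <- order(cells$train_mse, cells$n_variants, cells$window_kb)
  best <- cells[ord[1], ]
  idx <- clump(ss, cohort, window_kb = best$window_kb, clump_r2 = best$clump_r2)
  wts <- ss[match(idx, ss$id), , drop = FALSE]
  wts <- wts[wts$p < best$p_threshold, , drop = FALSE]
  sc <- prs_score(cohort, wts)
  X <- cbind(1, score = sc[ok], design0[ok, , drop = FALSE])
  fit <- stats::lm.fit(X, y[ok])
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  structure(list(window_kb = best$window_kb, clump_r2 = best$clump_r2,
                 p_threshold = best$p_threshold,
                 weights = wts[, c("id", "chrom", "pos", "a1", "a2", "beta", "p")],
                 scores = sc, train_mse = best$train_mse,
                 lm_coef = coefs, grid = cells),
            class = "prs_model")
}

#' Predict from a tuned PRS model
#'
#' Scores a cohort with the tuned weights and, unless `score_only = TRUE`,
#' applies the linear model (intercept, score, covariates) fitted during
#' tuning.
#'
#' @param object A `prs_model`.
#' @param cohort A `genotype_cohort`.
#' @param covariates Covariate matrix matching the one used in tuning.
#' @param score_only Return the raw polygenic score instead of the linear
#'   prediction.
#' @param ... Unused.
#' @return Named numeric vector of predictions (or scores).
#' @export
predict.prs_model <- function(object, cohort, covariates = NULL,
                              score_only = FALSE, ...) {
  sc <- prs_score(cohort, object$weights)
  if (score_only) return(sc)
  design0 <- if (is.null(covariates)) matrix(0, length(sc), 0) else
    as.matrix(covariates)
  X <- cbind(1, score = sc, design0)
  stats::setNames(as.vector(X %*% object$lm_coef), names(sc))
}

#' @export
print.prs_model <- function(x, ...) {
  cat(sprintf(
    "prs_model: window %g kb, clump r2 %g, p < %g; %d variants, train MSE %.4f\n",
    x$window_kb, x$clump_r2, x$p_threshold, nrow(x$weights), x$train_mse))
  invisible(x)
}
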