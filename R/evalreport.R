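#' Percentage of variance explained
#'
#' `PVE = (1 - var(y0 - yhat) / var(y0)) * 100`, with the sample
#' (`n - 1`) variance in both numerator and denominator — the ratio is
#' invariant to that convention as long as it is used consistently. A model
#' worse than the mean predictor yields a negative PVE; it is reported, not
#' clipped.
#'
#' @param y0 Observed (adjusted) phenotype.
#' @param yhat Model predictions, same length.
#' @return PVE in percent (at most 100).
#' @export
pve <- function(y0, yhat) {
  if (length(y0) != length(yhat)) stop("y0 and yhat differ in length", call. = FALSE)
  if (length(y0) < 2) stop("need at least 2 observations", call. = FALSE)
  v0 <- stats::var(y0)
  if (v0 == 0) stop("var(y0) is zero; PVE undefined", call. = FALSE)
  (1 - stats::var(y0 - yhat) / v0) * 100
}

#' Relative PVE increase between two models
#'
#' `(pve2 - pve1) / pve1 * 100`: the percent improvement of model 2 over
#' model 1.
#'
#' @param pve1 Baseline PVE (non-zero).
#' @param pve2 Comparison PVE.
#' @return Relative increase in percent.
#' @export
relative_pve <- function(pve1, pve2) {
  if (pve1 == 0) stop("baseline PVE is zero; relative PVE undefined", call. = FALSE)
  (pve2 - pve1) / pve1 * 100
}

#' Train/test split of a cohort
#'
#' Random split stratified by population group. In `"unrelated"` mode,
#' training samples related to any test sample (kinship `K/2 >= threshold`)
#' are dropped from the training set, so the training set may contain
#' relatives of each other but none of the test set.
#'
#' @param cohort A `genotype_cohort`.
#' @param test_frac Held-out fraction in `(0, 1)` (default 0.2).
#' @param seed Integer seed.
#' @param K Kinship matrix (twice the kinship), required for
#'   `mode = "unrelated"`.
#' @param mode `"random"` or `"unrelated"`.
#' @param threshold Kinship cut for `"unrelated"` mode (default 0.0625).
#' @return An object of class `cohort_split` with `train_ids`, `test_ids`,
#'   `dropped_ids`, `seed`, and `mode`.
#' @export
split_train_test <- function(cohort, test_frac = 0.2, seed = 1L, K = NULL,
                             mode = c("random", "unrelated"),
                             threshold = 0.0625) {
  mode <- match.arg(mode)
  assert_cohort(cohort)
  if (!(test_frac > 0 && test_frac < 1)) stop_field("test_frac", "must lie in (0, 1)")
  if (mode == "unrelated" && is.null(K)) {
    stop_field("K", "kinship matrix required in unrelated mode")
  }
  ids <- cohort$samples$id
  test_ids <- with_rng(seed, {
    unlist(lapply(split(ids, cohort$samples$group), function(g) {
      sample(g, round(length(g) * test_frac))
    }), use.names = FALSE)
  })
  train_ids <- setdiff(ids, test_ids)
  dropped <- character()
  if (mode == "unrelated") {
    kin <- K[train_ids, test_ids, drop = FALSE] / 2
    related <- rowSums(kin >= threshold) > 0
    dropped <- train_ids[related]
    train_ids <- train_ids[!related]
  }
  structure(list(train_ids = train_ids, test_ids = sort(test_ids),
                 dropped_ids = dropped, seed = as.integer(seed), mode = mode,
                 test_frac = test_frac),
            class = "cohort_split")
}

#' Group-stratified evaluation report
#'
#' PVE of every model within every evaluation group of the test set, plus
#' the pooled PVE, and the pairwise relative-PVE table on the pooled
#' values. Supports both the pooled-trained and group-trained regimes: pass
#' whichever predictions belong to the models under comparison.
#'
#' @param predictions Named list of prediction vectors, all aligned with
#'   `y0`.
#' @param y0 Observed adjusted phenotype of the evaluation samples.
#' @param groups Group label per evaluation sample.
#' @param heritability Optional `heritability_estimate` for context.
#' @param split Optional `cohort_split` manifest.
#' @return An object of class `evaluation_report` with `pve_table` (model x
#'   group data frame), `relative_pve` (matrix, entry `[i, j]` = relative
#'   increase of model j over model i on pooled PVE), `heritability`, and
#'   `split`.
#' @export
stratified_report <- function(predictions, y0, groups,
                              heritability = NULL, split = NULL) {
  stopifnot(is.list(predictions))
  groups <- as.character(groups)
  keep <- !is.na(y0)
  levels_g <- unique(groups[keep])
  models <- names(predictions)
  tab <- data.frame(model = character(), group = character(), pve = numeric(),
                    stringsAsFactors = FALSE)
  for (m in models) {
    yh <- predictions[[m]]
    if (length(yh) != length(y0)) {
      stop(sprintf("predictions for `%s` differ in length from y0", m),
           call. = FALSE)
    }
    for (g in c("pooled", levels_g)) {
      sel <- keep & (g == "pooled" | groups == g)
      if (sum(sel) < 2 || stats::var(y0[sel]) == 0) {
        warning(sprintf("group `%s` too small for PVE; omitted", g), call. = FALSE)
        next
      }
      tab <- rbind(tab, data.frame(model = m, group = g,
                                   pve = pve(y0[sel], yh[sel])))
    }
  }
  pooled <- tab$pve[tab$group == "pooled"]
  names(pooled) <- tab$model[tab$group == "pooled"]
  rel <- matrix(NA_real_, length(pooled), length(pooled),
                dimnames = list(names(pooled), names(pooled)))
  for (i in seq_along(pooled)) for (j in seq_along(pooled)) {
    if (i != j && pooled[i] != 0) rel[i, j] <- relative_pve(pooled[i], pooled[j])
  }
  structure(list(pve_table = tab, relative_pve = rel,
                 heritability = heritability, split = split),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  if (nrow(x$pve_table)) {
    wide <- stats::reshape(x$pve_table, idvar = "model", timevar = "group",
                           direction = "wide")
    names(wide) <- sub("^pve\\.", "", names(wide))
    print(wide, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$heritability)) print(x$heritability)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  h <- report$heritability
  obj <- list(
    pve_table = report$pve_table,
    relative_pve = report$relative_pve,
    heritability = if (!is.null(h)) {
      list(h2 = h$h2, se = h$se, ci95 = h$ci95,
           sigma2_k = h$sigma2_k, sigma2_e = h$sigma2_e, n = h$n)
    },
    split = if (!is.null(report$split)) {
      list(train_ids = report$split$train_ids, test_ids = report$split$test_ids,
           dropped_ids = report$split$dropped_ids, seed = report$split$seed,
           mode = report$split$mode)
    })
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read an evaluation report back from JSON
#'
#' @param path File written by [report_to_json()].
#' @return An `evaluation_report` (heritability reduced to its numbers).
#' @export
report_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  rel <- as.matrix(obj$relative_pve)
  if (length(rel)) {
    dimnames(rel) <- list(unique(obj$pve_table$model), unique(obj$pve_table$model))
  }
  split <- obj$split
  if (!is.null(split)) class(split) <- "cohort_split"
  structure(list(pve_table = as.data.frame(obj$pve_table), relative_pve = rel,
                 heritability = obj$heritability, split = split),
            class = "evaluation_report")
}
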