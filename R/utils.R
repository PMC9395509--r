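# Internal helpers shared across modules.

# Run `expr` under a private RNG stream, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# All derived stream seeds stay below .Machine$integer.max.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean-impute missing allele counts per variant; optionally with fixed means
# (e.g. training-set means when building test-set features).
impute_genotypes <- function(G, means = NULL) {
  if (is.null(means)) means <- colMeans(G, na.rm = TRUE)
  means[is.nan(means)] <- 0
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- means[idx[, 2]]
  storage.mode(G) <- "double"
  G
}

is_genotype_cohort <- function(x) inherits(x, "genotype_cohort")

assert_cohort <- function(x) {
  if (!is_genotype_cohort(x)) stop("expected a `genotype_cohort` object", call. = FALSE)
  invisible(x)
}

# Required columns of a summary-statistics table.
SUMSTATS_COLS <- c("id", "chrom", "pos", "a1", "a2", "beta", "se", "p", "n")

assert_sumstats <- function(ss) {
  missing_cols <- setdiff(setdiff(SUMSTATS_COLS, "id"), names(ss))
  if (length(missing_cols)) {
    stop("summary statistics lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(ss$p <= 0 | ss$p > 1, na.rm = TRUE)) {
    stop("summary statistics p-values must lie in (0, 1]", call. = FALSE)
  }
  invisible(ss)
}

#' Subset a genotype cohort by sample ids
#'
#' @param cohort A `genotype_cohort`.
#' @param sample_ids Character vector of sample ids to keep (order kept as
#'   in the cohort).
#' @return The subsetted `genotype_cohort`.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  assert_cohort(cohort)
  sel <- cohort$samples$id %in% sample_ids
  structure(list(genotypes = cohort$genotypes[sel, , drop = FALSE],
                 variants = cohort$variants,
                 samples = cohort$samples[sel, , drop = FALSE]),
            class = "genotype_cohort")
}
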