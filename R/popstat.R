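#' Filter variants by pooled minor allele frequency and orient effect alleles
#'
#' Recomputes the pooled allele frequency from the genotype matrix, flips
#' every variant whose counted allele is the major one (allele counts
#' `g -> 2 - g`, allele columns swapped) so the counted/effect allele is
#' always the minor allele, then keeps variants with pooled MAF at or above
#' `floor`.
#'
#' @param cohort A `genotype_cohort`.
#' @param floor MAF floor (default 0.01); `0` keeps every variant.
#' @return The filtered, re-oriented `genotype_cohort`; the ids of flipped
#'   variants are recorded in `attr(, "flipped")` (any external per-variant
#'   weights should be negated for those ids).
#' @export
filter_maf <- function(cohort, floor = 0.01) {
  assert_cohort(cohort)
  G <- cohort$genotypes
  f <- colMeans(G, na.rm = TRUE) / 2
  f[is.nan(f)] <- 0
  flip <- f > 0.5
  if (any(flip)) {
    G[, flip] <- 2L - G[, flip]
    tmp <- cohort$variants$a1[flip]
    cohort$variants$a1[flip] <- cohort$variants$a2[flip]
    cohort$variants$a2[flip] <- tmp
  }
  maf <- pmin(f, 1 - f)
  cohort$variants$maf <- unname(maf)
  keep <- maf >= floor
  if (!any(keep)) warning("no variant passes the MAF floor", call. = FALSE)
  cohort$genotypes <- G[, keep, drop = FALSE]
  cohort$variants <- cohort$variants[keep, , drop = FALSE]
  rownames(cohort$variants) <- NULL
  attr(cohort, "flipped") <- cohort$variants$id[cohort$variants$id %in%
                                                  names(which(flip))]
  cohort
}

#' Marginal single-variant GWAS
#'
#' One ordinary-least-squares test per variant: the phenotype regressed on
#' the allele count plus covariates. Missing genotypes are mean-imputed per
#' variant; samples with a missing phenotype or covariate are dropped.
#' Implemented by projecting genotypes and phenotype off the covariate
#' design (Frisch-Waugh-Lovell), which gives the same estimate, standard
#' error, and t-based p-value as the full per-variant regression.
#'
#' @param cohort A `genotype_cohort`.
#' @param y Numeric phenotype vector aligned with `cohort$samples`.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @return Summary-statistics data frame (`id, chrom, pos, a1, a2, beta, se,
#'   p, n, monomorphic`); monomorphic variants get `beta = 0, p = 1`.
#' @export
marginal_gwas <- function(cohort, y, covariates = NULL) {
  assert_cohort(cohort)
  y <- as.numeric(y)
  ok <- !is.na(y)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    ok <- ok & rowSums(is.na(C)) == 0
    X <- cbind(`(Intercept)` = 1, C[ok, , drop = FALSE])
  } else {
    X <- matrix(1, sum(ok), 1)
  }
  G <- impute_genotypes(cohort$genotypes[ok, , drop = FALSE])
  yy <- y[ok]
  n <- length(yy)
  p_cov <- qr(X)$rank
  qrX <- qr(X)
  Gt <- qr.resid(qrX, G)
  yt <- qr.resid(qrX, yy)
  gss <- colSums(Gt^2)
  mono <- gss < 1e-12
  gss[mono] <- 1
  beta <- colSums(Gt * yt) / gss
  df <- n - p_cov - 1L
  rss <- sum(yt^2) - beta^2 * gss
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / gss)
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- 2 * stats::pt(-abs(tstat), df)
  p <- pmin(pmax(p, 1e-300), 1)
  beta[mono] <- 0; se[mono] <- NA_real_; p[mono] <- 1
  out <- cohort$variants[, c("id", "chrom", "pos", "a1", "a2")]
  out$beta <- unname(beta)
  out$se <- unname(se)
  out$p <- unname(p)
  out$n <- n
  out$monomorphic <- unname(mono)
  rownames(out) <- NULL
  out
}

#' Align summary statistics to a cohort's variants
#'
#' Matches on chromosome, position, and allele pair (either order). When the
#' summary-statistics effect allele is the cohort's other allele, the effect
#' size is negated so it always refers to the cohort's counted allele.
#'
#' @param sumstats Summary-statistics data frame.
#' @param cohort A `genotype_cohort`.
#' @return The aligned subset with `id` replaced by the cohort's variant id
#'   and `beta` oriented to the cohort's effect allele.
#' @export
align_sumstats <- function(sumstats, cohort) {
  assert_sumstats(sumstats)
  assert_cohort(cohort)
  v <- cohort$variants
  key_c <- paste(v$chrom, v$pos)
  key_s <- paste(sumstats$chrom, sumstats$pos)
  m <- match(key_s, key_c)
  hit <- !is.na(m)
  ss <- sumstats[hit, , drop = FALSE]
  vi <- v[m[hit], , drop = FALSE]
  same <- ss$a1 == vi$a1 & ss$a2 == vi$a2
  swapped <- ss$a1 == vi$a2 & ss$a2 == vi$a1
  keep <- same | swapped
  ss <- ss[keep, , drop = FALSE]
  vi <- vi[keep, , drop = FALSE]
  sw <- swapped[keep]
  ss$beta[sw] <- -ss$beta[sw]
  ss$a1 <- vi$a1
  ss$a2 <- vi$a2
  ss$id <- vi$id
  rownames(ss) <- NULL
  ss
}

#' Candidate SNP filter by GWAS p-value
#'
#' Returns the cohort variant ids whose aligned summary-statistics p-value
#' is strictly below `threshold` (default `1e-4`), the inclusion rule for
#' the ensemble's candidate set.
#'
#' @param sumstats Summary statistics (aligned or alignable to the cohort).
#' @param cohort A `genotype_cohort`.
#' @param threshold Strict p-value threshold.
#' @return Character vector of variant ids.
#' @export
candidate_filter <- function(sumstats, cohort, threshold = 1e-4) {
  ss <- align_sumstats(sumstats, cohort)
  ids <- ss$id[ss$p < threshold]
  if (!length(ids)) warning("no variant passes the candidate p-value filter",
                            call. = FALSE)
  ids
}

#' Genetic relationship matrix
#'
#' Standard GRM on centered, frequency-scaled allele counts:
#' `K = Z Z' / M` with `Z[, v] = (g_v - 2 p_v) / sqrt(2 p_v (1 - p_v))`.
#' Missing genotypes are mean-imputed per variant; monomorphic variants are
#' dropped. Entry `(i, j)` estimates twice the kinship coefficient.
#'
#' In a multi-ancestry cohort the standard GRM mixes ancestry with
#' relatedness: samples sharing a population group sit at a positive offset
#' that can exceed a third-degree kinship cut. `adjust_pcs > 0` projects the
#' top principal components out of `Z` before forming the matrix, a
#' light-weight ancestry adjustment that keeps close relatives visible while
#' zeroing the group offset (full ancestry-robust kinship estimation is a
#' method of its own and out of scope here).
#'
#' @param cohort A `genotype_cohort` (MAF-filtered).
#' @param adjust_pcs Number of leading principal components to project out
#'   (default 0 = the plain GRM).
#' @return An n-by-n symmetric matrix with sample ids as dimnames.
#' @export
compute_grm <- function(cohort, adjust_pcs = 0) {
  assert_cohort(cohort)
  G <- impute_genotypes(cohort$genotypes)
  p <- colMeans(G) / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic variants; cannot build a GRM", call. = FALSE)
  G <- G[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(G, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  if (adjust_pcs > 0) {
    U <- top_left_singular(Z, min(adjust_pcs, dim(Z)))
    Z <- Z - U %*% crossprod(U, Z)
  }
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(rownames(G), rownames(G))
  K
}

#' Greedy selection of a pairwise-unrelated sample set
#'
#' The GRM holds twice the kinship coefficient, so a pair violates the cut
#' when `K[i, j] / 2 >= threshold`. Repeatedly drops the sample involved in
#' the most remaining violating pairs (ties broken toward the smaller sample
#' id) until none remain; the returned set is verified against the threshold
#' before returning.
#'
#' @param K GRM from [compute_grm()] (twice the kinship).
#' @param threshold Kinship cut, default 0.0625 (third-degree relatives).
#' @return Character vector of retained sample ids.
#' @export
select_unrelated <- function(K, threshold = 0.0625) {
  ids <- rownames(K) %||% as.character(seq_len(nrow(K)))
  A <- (K / 2) >= threshold
  diag(A) <- FALSE
  active <- rep(TRUE, nrow(K))
  deg <- rowSums(A)
  while (any(deg[active] > 0)) {
    cand <- which(active & deg == max(deg[active]))
    drop <- cand[order(ids[cand])][1]
    active[drop] <- FALSE
    deg <- deg - A[, drop]
    deg[drop] <- 0
  }
  kept <- which(active)
  stopifnot(all(K[kept, kept][upper.tri(diag(length(kept)))] / 2 < threshold))
  ids[kept]
}

#' Genotype principal components
#'
#' Top-`k` principal components of the standardized, mean-imputed genotype
#' matrix. The sign of each component is fixed so its largest-magnitude
#' variant loading is positive. The returned object carries the loadings and
#' the standardization constants so new samples can be projected onto the
#' same axes with [predict.genotype_pcs()].
#'
#' @param cohort A `genotype_cohort` (MAF-filtered).
#' @param k Number of components, `0 <= k <= min(n, M)`.
#' @return An object of class `genotype_pcs` with `scores` (n-by-k),
#'   `rotation`, `center`, `scale`, and `ids` (variants used).
#' @export
compute_pcs <- function(cohort, k = 5) {
  assert_cohort(cohort)
  G <- impute_genotypes(cohort$genotypes)
  sds <- apply(G, 2, stats::sd)
  keep <- sds > 0
  G <- G[, keep, drop = FALSE]
  if (k > min(nrow(G), ncol(G))) {
    stop(sprintf("k = %d exceeds min(n, M) = %d", k, min(nrow(G), ncol(G))),
         call. = FALSE)
  }
  ctr <- colMeans(G)
  scl <- sds[keep]
  if (k == 0) {
    scores <- matrix(0, nrow(G), 0, dimnames = list(rownames(G), NULL))
    return(structure(list(scores = scores,
                          rotation = matrix(0, ncol(G), 0),
                          center = ctr, scale = scl, ids = colnames(G)),
                     class = "genotype_pcs"))
  }
  Z <- scale(G, center = ctr, scale = scl)
  sv <- svd(Z, nu = k, nv = k)
  rotation <- sv$v
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  for (i in seq_len(k)) {
    j <- which.max(abs(rotation[, i]))
    if (rotation[j, i] < 0) {
      rotation[, i] <- -rotation[, i]
      scores[, i] <- -scores[, i]
    }
  }
  dimnames(scores) <- list(rownames(G), paste0("PC", seq_len(k)))
  dimnames(rotation) <- list(colnames(G), paste0("PC", seq_len(k)))
  structure(list(scores = scores, rotation = rotation, center = ctr,
                 scale = scl, ids = colnames(G)),
            class = "genotype_pcs")
}

#' Project new samples onto fitted principal components
#'
#' @param object A `genotype_pcs` object.
#' @param cohort A `genotype_cohort` containing the fitted variants.
#' @param ... Unused.
#' @return Score matrix for the new samples.
#' @export
predict.genotype_pcs <- function(object, cohort, ...) {
  assert_cohort(cohort)
  miss <- setdiff(object$ids, cohort$variants$id)
  if (length(miss)) stop("cohort lacks fitted PC variant(s): ",
                         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  G <- impute_genotypes(cohort$genotypes[, object$ids, drop = FALSE],
                        means = object$center)
  Z <- scale(G, center = object$center, scale = object$scale)
  out <- Z %*% object$rotation
  rownames(out) <- rownames(G)
  out
}

# Restricted log-likelihood of (sigma2_k, sigma2_e) in the eigenbasis of K.
# yt, Xt are U'y and U'X; d the eigenvalues of K. Constant terms dropped.
reml_loglik_eigen <- function(s_k, s_e, yt, Xt, d) {
  v <- s_e + s_k * d
  if (any(v <= 0)) return(-Inf)
  XtW <- Xt / v
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  ld <- determinant(XtWX, logarithm = TRUE)$modulus
  -0.5 * (sum(log(v)) + as.numeric(ld) + sum(r^2 / v))
}

#' REML heritability from a kinship matrix
#'
#' Fits the variance-component model `y = X beta + e`,
#' `cov(e) = sigma2_e I + sigma2_k K`, by restricted maximum likelihood and
#' reports the narrow-sense heritability
#' `h2 = sigma2_k / (sigma2_k + sigma2_e)`. A single eigendecomposition of
#' `K` makes every likelihood evaluation cheap; the restricted likelihood is
#' profiled over `h2` on a grid and refined with Brent's method. The
#' standard error comes from the observed-information matrix of
#' `(sigma2_k, sigma2_e)` (numerical Hessian) with the delta method, and the
#' 95% CI is `h2 +/- 1.96 se`, truncated to `[0, 1]`.
#'
#' @param y Numeric phenotype (adjusted scale recommended).
#' @param K Kinship matrix holding twice the kinship coefficients.
#' @param covariates Optional covariate matrix/data frame (an intercept is
#'   always included).
#' @return An object of class `heritability_estimate`: `sigma2_k`,
#'   `sigma2_e`, `h2`, `se`, `ci95`, `loglik`, `n`.
#' @export
reml_h2 <- function(y, K, covariates = NULL) {
  ok <- !is.na(y)
  y <- y[ok]
  K <- K[ok, ok, drop = FALSE]
  n <- length(y)
  X <- if (is.null(covariates)) matrix(1, n, 1) else {
    cbind(1, as.matrix(covariates)[ok, , drop = FALSE])
  }
  eg <- eigen(K, symmetric = TRUE)
  d <- eg$values
  if (max(d) - min(d) < 1e-8 * max(abs(d), 1)) {
    stop(paste("kinship matrix is numerically proportional to the identity;",
               "sigma2_k and sigma2_e are not identifiable"), call. = FALSE)
  }
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  p <- qr(X)$rank
  # profile restricted likelihood over h2, sigma2_total profiled out
  prof <- function(h2) {
    w <- (1 - h2) + h2 * d
    if (any(w <= 0)) return(-Inf)
    XtW <- Xt / w
    XtWX <- crossprod(Xt, XtW)
    beta <- solve(XtWX, crossprod(XtW, yt))
    r <- yt - Xt %*% beta
    s2 <- sum(r^2 / w) / (n - p)
    ld <- as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
    -0.5 * ((n - p) * log(s2) + sum(log(w)) + ld + (n - p))
  }
  grid <- seq(0, 0.99, by = 0.01)
  ll <- vapply(grid, prof, 0)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- min(0.999, grid[min(length(grid), i + 1)])
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-8)
  h2 <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  w <- (1 - h2) + h2 * d
  XtW <- Xt / w
  beta <- solve(crossprod(Xt, XtW), crossprod(XtW, yt))
  s2 <- sum((yt - Xt %*% beta)^2 / w) / (n - p)
  s_k <- h2 * s2
  s_e <- (1 - h2) * s2
  # observed information in (sigma2_k, sigma2_e) -> delta method for h2
  f <- function(par) reml_loglik_eigen(par[1], par[2], yt, Xt, d)
  par <- c(s_k, s_e)
  h <- pmax(1e-4, 1e-3 * abs(par))
  H <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) {
    ea <- eb <- c(0, 0); ea[a] <- h[a]; eb[b] <- h[b]
    H[a, b] <- (f(par + ea + eb) - f(par + ea - eb) -
                  f(par - ea + eb) + f(par - ea - eb)) / (4 * h[a] * h[b])
  }
  se <- tryCatch({
    V <- solve(-H)
    g <- c(s_e, -s_k) / (s_k + s_e)^2
    sqrt(max(0, as.numeric(t(g) %*% V %*% g)))
  }, error = function(e) NA_real_)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else
    pmin(pmax(h2 + c(-1.96, 1.96) * se, 0), 1)
  structure(list(sigma2_k = s_k, sigma2_e = s_e, h2 = h2, se = se,
                 ci95 = ci, loglik = f(par), n = n),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("REML heritability: h2 = %.3f (SE %.3f, 95%% CI %.3f-%.3f), n = %d\n",
              x$h2, x$se, x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}

# Top-k left singular vectors of Z by deterministic subspace iteration;
# plenty accurate for projecting out leading ancestry axes.
top_left_singular <- function(Z, k, iters = 30) {
  V0 <- with_rng(1L, matrix(rnorm(ncol(Z) * k), ncol(Z), k))
  Q <- qr.Q(qr(Z %*% V0))
  for (i in seq_len(iters)) {
    Q <- qr.Q(qr(Z %*% crossprod(Z, Q)))
  }
  Q
}
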