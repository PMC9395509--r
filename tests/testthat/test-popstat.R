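test_that("MAF filtering drops rare variants and orients to the minor allele", {
  G <- cbind(v1 = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L),  # f = 0.05
             v2 = c(2L, 2L, 2L, 1L, 2L, 2L, 2L, 2L, 1L, 2L),  # f = 0.9 -> flip
             v3 = c(0L, 1L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 1L))  # f = 0.45
  co <- make_cohort(G, a1 = c("A", "C", "G"), a2 = c("G", "T", "T"))
  out <- filter_maf(co, floor = 0.08)
  expect_identical(out$variants$id, c("v2", "v3"))
  # v2 counts complemented, alleles swapped
  expect_identical(unname(out$genotypes[, "v2"]),
                   c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L))
  expect_identical(out$variants$a1[1], "T")
  expect_identical(out$variants$a2[1], "C")
  # floor = 0 keeps everything; double orientation is the identity
  all1 <- filter_maf(co, floor = 0)
  expect_identical(all1$variants$id, co$variants$id)
  all2 <- filter_maf(all1, floor = 0)
  expect_identical(all1$genotypes, all2$genotypes)
  expect_equal(all1$variants, all2$variants)
  # MAF 0.005 is below the default floor
  G2 <- cbind(v1 = c(1L, rep(0L, 99)), v2 = rep(c(0L, 1L, 2L, 1L), 25))
  co2 <- make_cohort(G2)
  expect_identical(filter_maf(co2)$variants$id, "v2")
})

test_that("marginal GWAS matches per-variant OLS and flags monomorphic sites", {
  set.seed(3)
  n <- 120
  G <- cbind(v1 = sample(0:2, n, TRUE), v2 = sample(0:2, n, TRUE),
             v3 = rep(1L, n))
  co <- make_cohort(G)
  y <- 2 * G[, "v1"]
  ss <- marginal_gwas(co, y)
  expect_equal(ss$beta[1], 2, tolerance = 1e-10)
  expect_lt(ss$p[1], 1e-250)
  expect_true(ss$p[1] > 0)  # clamped into (0, 1]
  # monomorphic variant: effect 0, p 1
  expect_identical(ss$beta[3], 0)
  expect_identical(ss$p[3], 1)
  expect_true(ss$monomorphic[3])
  # agrees with lm() including covariates
  age <- rnorm(n, 50, 10)
  y2 <- 0.3 * G[, "v2"] + 0.1 * age + rnorm(n)
  ss2 <- marginal_gwas(co, y2, covariates = cbind(age = age))
  ref <- summary(lm(y2 ~ G[, "v2"] + age))$coefficients[2, ]
  expect_equal(ss2$beta[2], unname(ref["Estimate"]), tolerance = 1e-10)
  expect_equal(ss2$se[2], unname(ref["Std. Error"]), tolerance = 1e-10)
  expect_equal(ss2$p[2], unname(ref["Pr(>|t|)"]), tolerance = 1e-10)
})

test_that("GWAS type-I error is near nominal on null variants", {
  spec <- cohort_spec(n_per_group = c(1000, 1000), group_labels = c("a", "b"),
                      n_variants = 1000, n_chromosomes = 4, fst = 0,
                      ld_rho = 0, seed = 17)
  co <- simulate_genotypes(spec)
  set.seed(18)
  y <- rnorm(nrow(co$genotypes))
  ss <- marginal_gwas(co, y)
  frac <- mean(ss$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("GWAS effect estimates cover planted effects at the 2-SE level", {
  # nominal coverage of +/- 2 SE is 95.4%; assert a conservative 90% floor
  # over 200 planted variants so the check is statistically stable
  spec <- cohort_spec(n_per_group = c(600, 600), group_labels = c("a", "b"),
                      n_variants = 200, n_chromosomes = 4, fst = 0,
                      ld_rho = 0, seed = 19)
  co <- simulate_genotypes(spec)
  beta <- rnorm(200, 0, 0.1)
  set.seed(20)
  y <- as.vector(co$genotypes %*% beta) + rnorm(nrow(co$genotypes))
  ss <- marginal_gwas(co, y)
  # marginal slope for independent variants equals the per-variant beta
  covered <- abs(ss$beta - beta) <= 2 * ss$se
  expect_gte(mean(covered), 0.90)
})

test_that("candidate filter is strict and alignment flips swapped alleles", {
  G <- matrix(sample(0:2, 50 * 4, TRUE), 50, 4)
  co <- make_cohort(G, a1 = c("A", "C", "A", "T"), a2 = c("G", "T", "C", "C"))
  ss <- make_sumstats(co, p = c(1e-5, 1e-4, 0.5, 2e-5))
  # swap alleles of the first variant: beta must come back negated
  ss$a1[1] <- "G"; ss$a2[1] <- "A"; ss$beta[1] <- 0.4
  al <- align_sumstats(ss, co)
  expect_equal(al$beta[al$id == "v001"], -0.4)
  expect_identical(al$a1[al$id == "v001"], "A")
  cand <- candidate_filter(ss, co, threshold = 1e-4)
  expect_setequal(cand, c("v001", "v004"))  # p = 1e-4 excluded (strict)
  expect_identical(candidate_filter(ss, co, threshold = 1), co$variants$id)
  ss_far <- ss
  ss_far$pos <- ss_far$pos + 7L
  expect_warning(out <- candidate_filter(ss_far, co), "no variant")
  expect_length(out, 0)
})

test_that("the GRM behaves like twice the kinship", {
  spec <- cohort_spec(n_per_group = c(150, 150), group_labels = c("a", "b"),
                      n_variants = 900, n_chromosomes = 3, fst = 0,
                      ld_rho = 0, seed = 23)
  co <- simulate_genotypes(spec)
  K <- compute_grm(co)
  M <- ncol(co$genotypes)
  # unrelated samples: off-diagonals shrink like 1/sqrt(M)
  off <- K[upper.tri(K)]
  expect_lt(mean(abs(off)), 3 / sqrt(M))
  # Gram construction: positive semi-definite
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # a duplicated sample row: off-diagonal to the twin equals the diagonal
  co2 <- co
  co2$genotypes <- rbind(co$genotypes, dup = co$genotypes[1, ])
  co2$samples <- rbind(co$samples,
                       data.frame(id = "dup", group = "a", study = "STUDY1",
                                  age = 50, sex = "F"))
  K2 <- compute_grm(co2)
  expect_equal(K2["dup", rownames(co$genotypes)[1]], K2["dup", "dup"],
               ignore_attr = TRUE)
})

test_that("greedy unrelated selection enforces the kinship threshold", {
  # no violating pair: everyone kept
  K0 <- diag(5) + 0.01
  rownames(K0) <- colnames(K0) <- paste0("S", 1:5)
  expect_setequal(select_unrelated(K0), paste0("S", 1:5))
  # one sib pair (kinship 0.25 -> K = 0.5): exactly one of the two dropped
  K1 <- diag(6)
  rownames(K1) <- colnames(K1) <- paste0("S", 1:6)
  K1[1, 2] <- K1[2, 1] <- 0.5
  kept <- select_unrelated(K1)
  expect_length(kept, 5)
  expect_length(intersect(kept, c("S1", "S2")), 1)
})

test_that("greedy unrelated set is near the brute-force optimum", {
  brute_best <- function(A) {
    n <- nrow(A)
    edges <- which(A & upper.tri(A), arr.ind = TRUE)
    masks <- 0:(2^n - 1)
    bad <- rep(FALSE, length(masks))
    for (e in seq_len(nrow(edges))) {
      em <- bitwOr(bitwShiftL(1L, edges[e, 1] - 1L),
                   bitwShiftL(1L, edges[e, 2] - 1L))
      bad <- bad | (bitwAnd(masks, em) == em)
    }
    sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0), 0)
    max(sizes[!bad])
  }
  set.seed(29)
  for (trial in 1:100) {
    n <- 12
    A <- matrix(FALSE, n, n)
    pairs <- which(upper.tri(A))
    rel <- sample(pairs, rbinom(1, length(pairs), 0.12))
    A[rel] <- TRUE
    A <- A | t(A)
    K <- diag(n)
    K[A] <- 0.5
    rownames(K) <- colnames(K) <- sprintf("S%02d", 1:n)
    kept <- select_unrelated(K)
    expect_gte(length(kept), brute_best(A) - 1)
  }
})

test_that("principal components separate simulated populations", {
  spec <- cohort_spec(n_per_group = c(150, 150), group_labels = c("a", "b"),
                      n_variants = 400, n_chromosomes = 4, fst = 0.3, seed = 31)
  co <- filter_maf(simulate_genotypes(spec))
  pcs <- compute_pcs(co, 5)
  grp <- as.numeric(co$samples$group == "a")
  expect_gt(abs(cor(pcs$scores[, 1], grp)), 0.9)
  # zero mean per component; deterministic sign convention
  expect_lt(max(abs(colMeans(pcs$scores))), 1e-10)
  j <- apply(pcs$rotation, 2, function(col) col[which.max(abs(col))])
  expect_true(all(j > 0))
  # k = 0 and k too large
  expect_identical(ncol(compute_pcs(co, 0)$scores), 0L)
  expect_error(compute_pcs(co, 10000), "exceeds")
  # projection of the training cohort reproduces the scores
  proj <- predict(pcs, co)
  expect_equal(unname(proj), unname(pcs$scores), tolerance = 1e-8)
})

test_that("REML refuses an identity kinship and matches a brute-force grid", {
  set.seed(37)
  expect_error(reml_h2(rnorm(60), diag(60)), "identifiable")

  # independent dense-algebra restricted likelihood, maximized on a grid
  n <- 50
  K <- kronecker(diag(n / 5), matrix(0.4, 5, 5))
  diag(K) <- 1
  rownames(K) <- colnames(K) <- sprintf("S%02d", 1:n)
  ch <- chol(0.6 * K + 0.4 * diag(n))
  y <- as.vector(t(ch) %*% rnorm(n))
  X <- matrix(1, n, 1)
  loglik_dense <- function(sk, se) {
    V <- sk * K + se * diag(n)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              t(r) %*% Vi %*% r)[1]
  }
  grid <- expand.grid(sk = seq(0.02, 2, length.out = 60),
                      se = seq(0.02, 2, length.out = 60))
  ll <- mapply(loglik_dense, grid$sk, grid$se)
  est <- reml_h2(y, K)
  # the estimator's optimum must be at least as good as the best grid point
  expect_gte(loglik_dense(est$sigma2_k, est$sigma2_e), max(ll) - 1e-6)
  expect_equal(loglik_dense(est$sigma2_k, est$sigma2_e) / max(ll), 1,
               tolerance = 5e-4)
  expect_equal(est$h2, est$sigma2_k / (est$sigma2_k + est$sigma2_e))
  expect_true(all(est$ci95 >= 0 & est$ci95 <= 1))
})
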