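test_that("strand-ambiguous variants are removed in either allele order", {
  co <- make_cohort(matrix(sample(0:2, 40 * 5, TRUE), 40, 5),
                    a1 = c("A", "A", "C", "G", "T"),
                    a2 = c("T", "G", "G", "C", "A"))
  ss <- make_sumstats(co)
  out <- remove_ambiguous(ss)
  expect_setequal(out$id, "v002")  # A/G is the only unambiguous pair
  expect_warning(remove_ambiguous(ss[c(1, 3, 4, 5), ]), "ambiguous")
})

test_that("LD r2 matches squared Pearson correlation of allele counts", {
  set.seed(41)
  g1 <- sample(0:2, 500, TRUE, prob = c(0.5, 0.4, 0.1))
  G <- cbind(v1 = g1, v2 = g1, v3 = 2L - g1, v4 = sample(0:2, 500, TRUE),
             v5 = rep(1L, 500))
  co <- make_cohort(G)
  expect_equal(ld_r2(co, "v1", "v2"), 1)
  expect_equal(ld_r2(co, "v1", "v3"), 1)  # complement has |r| = 1
  expect_warning(r2m <- ld_r2(co, "v1", "v5"), "monomorphic")
  expect_identical(r2m, 0)
  # independent simulated variants: average r2 is tiny
  spec <- cohort_spec(n_per_group = c(2500, 2500), group_labels = c("a", "b"),
                      n_variants = 60, n_chromosomes = 2, fst = 0,
                      ld_rho = 0, seed = 43)
  cos <- simulate_genotypes(spec)
  r2s <- sapply(seq(1, 59, by = 2), function(j) {
    ld_r2(cos, cos$variants$id[j], cos$variants$id[j + 1])
  })
  expect_lt(mean(r2s), 0.01)
})

test_that("clumping keeps the hand-worked index set", {
  # three SNPs at 100, 200, 1e6 bp; v1-v2 in LD (r2 > 0.1), v3 independent
  set.seed(47)
  n <- 400
  g1 <- sample(0:2, n, TRUE, prob = c(0.36, 0.48, 0.16))
  flip <- runif(n) < 0.2
  g2 <- ifelse(flip, sample(0:2, n, TRUE), g1)
  g3 <- sample(0:2, n, TRUE, prob = c(0.49, 0.42, 0.09))
  co <- make_cohort(cbind(v1 = g1, v2 = as.integer(g2), v3 = g3),
                    pos = c(100L, 200L, 1000000L))
  expect_gt(ld_r2(co, "v1", "v2"), 0.1)      # precondition of the example
  expect_lt(ld_r2(co, "v1", "v3"), 0.1)
  ss <- make_sumstats(co, p = c(1e-8, 1e-6, 1e-3))
  expect_identical(clump(ss, co, window_kb = 500, clump_r2 = 0.1),
                   c("v1", "v3"))
  # narrow window: v2 is out of range of v1, so all three survive
  expect_identical(clump(ss, co, window_kb = 0.05, clump_r2 = 0.1),
                   c("v1", "v2", "v3"))
  # single SNP clumps to itself; empty input stays empty
  expect_identical(clump(ss[1, ], co, 250, 0.1), "v1")
  expect_identical(clump(ss[0, ], co, 250, 0.1), character())
})

test_that("greedy clumping matches an exhaustive reference on random instances", {
  # reference: precompute the full r2 matrix, then walk the p-ordered list
  # removing neighbours explicitly
  clump_reference <- function(ss, co, window_kb, r2max) {
    ord <- order(ss$p, ss$chrom, ss$pos)
    ss <- ss[ord, ]
    G <- co$genotypes[, ss$id, drop = FALSE]
    R2 <- suppressWarnings(cor(G))^2
    R2[is.na(R2)] <- 0
    alive <- rep(TRUE, nrow(ss))
    out <- character()
    for (i in seq_len(nrow(ss))) {
      if (!alive[i]) next
      out <- c(out, ss$id[i])
      for (j in seq_len(nrow(ss))) {
        if (j == i || !alive[j]) next
        if (ss$chrom[j] == ss$chrom[i] &&
            abs(ss$pos[j] - ss$pos[i]) <= window_kb * 1000 &&
            R2[i, j] > r2max) {
          alive[j] <- FALSE
        }
      }
      alive[i] <- FALSE
    }
    out
  }
  set.seed(53)
  for (trial in 1:100) {
    m <- sample(2:10, 1)
    n <- 150
    base <- sample(0:2, n, TRUE)
    G <- sapply(seq_len(m), function(j) {
      if (runif(1) < 0.5) {
        mix <- runif(n) < runif(1, 0.1, 0.9)
        as.integer(ifelse(mix, sample(0:2, n, TRUE), base))
      } else sample(0:2, n, TRUE)
    })
    colnames(G) <- sprintf("s%02d", seq_len(m))
    co <- make_cohort(G, chrom = sample(1:2, m, TRUE),
                      pos = sort(sample(seq(1e4, 8e5, by = 1e4), m)))
    co$variants$pos <- ave(co$variants$pos, co$variants$chrom,
                           FUN = function(p) sort(p))
    ss <- make_sumstats(co, p = runif(m, 1e-8, 0.5))
    w <- sample(c(50, 250, 500), 1)
    r2 <- sample(c(0.1, 0.2, 0.3), 1)
    expect_identical(clump(ss, co, w, r2), clump_reference(ss, co, w, r2))
  }
})

test_that("clumped variants respect the pairwise r2/window constraint", {
  spec <- cohort_spec(n_per_group = c(400, 400), group_labels = c("a", "b"),
                      n_variants = 150, n_chromosomes = 3, ld_rho = 0.8,
                      ld_block_len = 8, seed = 59)
  co <- simulate_genotypes(spec)
  ss <- make_sumstats(co, p = runif(150, 1e-6, 0.5))
  kept <- clump(ss, co, window_kb = 250, clump_r2 = 0.2)
  v <- co$variants[match(kept, co$variants$id), ]
  for (i in seq_along(kept)) {
    for (j in seq_len(i - 1)) {
      if (v$chrom[i] == v$chrom[j] && abs(v$pos[i] - v$pos[j]) <= 250000) {
        expect_lte(ld_r2(co, kept[i], kept[j]), 0.2)
      }
    }
  }
})

test_that("scores are oriented weighted allele-count sums", {
  G <- rbind(c(2L, 0L, 1L), c(1L, 1L, 0L), c(0L, 2L, 2L), c(2L, NA, 1L))
  colnames(G) <- c("v1", "v2", "v3")
  co <- make_cohort(G, a1 = c("A", "C", "G"), a2 = c("G", "T", "T"))
  w <- data.frame(id = c("v1", "v2", "v3"), a1 = c("A", "T", "G"),
                  beta = c(0.5, 0.2, -0.1))
  # v2 weight refers to the other allele -> sign flips; missing v2 count for
  # sample 4 contributes the column mean (1)
  sc <- prs_score(co, w)
  mean_v2 <- mean(c(0, 1, 2))
  expected <- c(0.5 * 2 - 0.2 * 0 - 0.1 * 1,
                0.5 * 1 - 0.2 * 1 - 0.1 * 0,
                0.5 * 0 - 0.2 * 2 - 0.1 * 2,
                0.5 * 2 - 0.2 * mean_v2 - 0.1 * 1)
  expect_equal(unname(sc), expected)
  # one variant, weight 0.5, genotype 2 -> 1.0
  expect_equal(unname(prs_score(co, w[1, ])[1]), 1.0)
  # all-zero weights -> all-zero scores
  w0 <- transform(w, beta = 0)
  expect_true(all(prs_score(co, w0) == 0))
  # linearity in the weights
  w2 <- transform(w, beta = c(0.1, -0.3, 0.7))
  wsum <- transform(w, beta = beta + w2$beta)
  expect_equal(prs_score(co, wsum), prs_score(co, w) + prs_score(co, w2))
  # allele mismatch is an error naming the variant
  wbad <- transform(w, a1 = c("C", "T", "G"))
  expect_error(prs_score(co, wbad), "v1")
})

test_that("grid tuning minimizes training MSE and degenerates sensibly", {
  set.seed(61)
  spec <- cohort_spec(n_per_group = c(500, 500), group_labels = c("a", "b"),
                      n_variants = 120, n_chromosomes = 4, ld_rho = 0.4,
                      seed = 67)
  arch <- random_architecture(spec, n_additive = 10, add_sd = 0.3,
                              target_h2 = 0.5, covariate_effects = list(),
                              seed = 68)
  co <- filter_maf(simulate_genotypes(spec))
  tr <- simulate_trait(co, arch, seed = 69)
  ss <- make_discovery_sumstats(spec, arch, n_discovery = 4000, seed = 70)
  y <- rank_normalize(tr$phenotype)
  names(y) <- co$samples$id
  # grid of size 1 returns that cell
  g1 <- list(window_kb = 250, clump_r2 = 0.2, p_thresholds = 0.01)
  m1 <- suppressWarnings(tune_ct(ss, co, y, grid = g1))
  expect_equal(m1$window_kb, 250)
  expect_equal(m1$clump_r2, 0.2)
  expect_equal(m1$p_threshold, 0.01)
  # selected cell attains the minimum recorded MSE, and scores are
  # recomputable from the weights (dot-product check)
  m <- suppressWarnings(tune_ct(ss, co, y))
  expect_equal(m$train_mse, min(m$grid$train_mse, na.rm = TRUE))
  expect_equal(m$scores, prs_score(co, m$weights))
  expect_true(all(m$weights$p < m$p_threshold))
  # every retained weight survived clumping at the selected cell
  kept <- clump(remove_ambiguous(align_sumstats(ss, co)), co,
                m$window_kb, m$clump_r2)
  expect_true(all(m$weights$id %in% kept))
  # a PRS built from impossible thresholds errors out
  g_bad <- list(window_kb = 250, clump_r2 = 0.1, p_thresholds = 1e-300)
  expect_error(suppressWarnings(tune_ct(ss, co, y, grid = g_bad)), "empty")
})
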