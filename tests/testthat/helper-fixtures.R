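# In-code fixtures shared across test files; everything is generated at
# test time, nothing is read from disk.

# Build a genotype_cohort from a raw allele-count matrix.
make_cohort <- function(G, chrom = NULL, pos = NULL, a1 = NULL, a2 = NULL,
                        group = NULL, age = NULL, sex = NULL) {
  n <- nrow(G)
  M <- ncol(G)
  if (is.null(colnames(G))) colnames(G) <- sprintf("v%03d", seq_len(M))
  if (is.null(rownames(G))) rownames(G) <- sprintf("S%03d", seq_len(n))
  f <- colMeans(G, na.rm = TRUE) / 2
  variants <- data.frame(
    id = colnames(G),
    chrom = chrom %||% rep(1L, M),
    pos = pos %||% seq(1000L, by = 1000L, length.out = M),
    a1 = a1 %||% rep("A", M),
    a2 = a2 %||% rep("G", M),
    maf = unname(pmin(f, 1 - f)),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    id = rownames(G),
    group = group %||% rep("groupA", n),
    study = rep("STUDY1", n),
    age = age %||% rep(50, n),
    sex = sex %||% rep("F", n),
    stringsAsFactors = FALSE)
  structure(list(genotypes = G, variants = variants, samples = samples),
            class = "genotype_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small sumstats table aligned with a cohort's variants, with given p/beta.
make_sumstats <- function(cohort, beta = NULL, p = NULL, n = 1000) {
  v <- cohort$variants
  data.frame(id = v$id, chrom = v$chrom, pos = v$pos, a1 = v$a1, a2 = v$a2,
             beta = beta %||% rep(0.1, nrow(v)),
             se = rep(0.05, nrow(v)),
             p = p %||% rep(0.5, nrow(v)),
             n = n, stringsAsFactors = FALSE)
}

# End-to-end simulated scenario used by the heavier model tests: returns
# train/test cohorts, adjusted phenotype, PCs, PRS inputs, and candidates.
sim_scenario <- function(rep_seed, n_per_group = c(1334, 1333, 1333),
                         n_variants = 400, n_additive = 0, n_epistatic = 8,
                         add_sd = 0.12, epi_sd = 0.3, target_h2 = 0.5,
                         n_discovery = 6000, group_weights = c(0.7, 0.2, 0.1),
                         permute = FALSE) {
  spec <- cohort_spec(n_per_group = n_per_group, n_variants = n_variants,
                      n_chromosomes = 10, fst = 0.1, ld_block_len = 10,
                      ld_rho = 0.5, seed = rep_seed)
  arch <- random_architecture(spec, n_additive = n_additive,
                              n_epistatic = n_epistatic, add_sd = add_sd,
                              epi_sd = epi_sd, target_h2 = target_h2,
                              seed = rep_seed + 50)
  cohort <- simulate_genotypes(spec)
  trait <- simulate_trait(cohort, arch, seed = rep_seed + 100)
  ss <- make_discovery_sumstats(spec, arch, n_discovery = n_discovery,
                                group_weights = group_weights,
                                seed = rep_seed + 200)
  cohort <- filter_maf(cohort)
  dat <- cohort$samples
  dat$trait <- trait$phenotype
  adj <- suppressWarnings(harmonize(dat, "trait"))
  y <- adj$values
  if (permute) {
    set.seed(rep_seed + 300)
    y <- sample(y)
    names(y) <- cohort$samples$id
  }
  split <- split_train_test(cohort, 0.2, seed = rep_seed + 400)
  ctr <- subset_cohort(cohort, split$train_ids)
  cte <- subset_cohort(cohort, split$test_ids)
  tr <- cohort$samples$id %in% split$train_ids
  pcs <- compute_pcs(ctr, 5)
  list(spec = spec, arch = arch, cohort = cohort, sumstats = ss,
       ctr = ctr, cte = cte, y_tr = y[tr], y_te = y[!tr],
       pcs_tr = pcs$scores, pcs_te = predict(pcs, cte), pcs = pcs)
}

# Ensemble config sized for the test suite: a compact penalty grid and a
# reduced tree cap keep runs fast while the fixed booster settings stay at
# their defaults.
test_ensemble_config <- function(seed, ...) {
  ensemble_config(alpha_grid = 10^seq(-2.5, -1, length.out = 3),
                  max_trees = 1500, seed = seed, ...)
}

expect_cohort_equal <- function(a, b) {
  expect_identical(a$genotypes, b$genotypes)
  expect_equal(a$variants, b$variants)
  expect_equal(a$samples, b$samples)
}
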