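#' Specification of a simulated multi-ancestry cohort
#'
#' Describes the genotype panel and sample composition for the bundled
#' simulator: the number of samples per population group, the variant panel
#' size and its layout over chromosomes, the per-group differentiation from a
#' shared ancestral population (Balding-Nichols \eqn{F_{ST}}-style), and the
#' strength of linkage disequilibrium within blocks of consecutive variants.
#'
#' @param n_per_group Integer vector, samples per population group.
#' @param group_labels Character vector of group names, one per entry of
#'   `n_per_group`.
#' @param n_variants Total number of variants on the panel.
#' @param n_chromosomes Number of chromosomes the panel is spread over.
#' @param fst Per-group differentiation parameter(s) in `[0, 1)`; recycled to
#'   the number of groups. `0` means all groups share the ancestral
#'   frequencies.
#' @param ld_block_len Number of consecutive variants per LD block.
#' @param ld_rho Latent AR(1) correlation within an LD block, in `(-1, 1)`.
#' @param seed Integer seed; fixes the variant panel and all sampling.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(1000, 1000, 1000),
                        group_labels = c("groupA", "groupB", "groupC"),
                        n_variants = 1000,
                        n_chromosomes = 10,
                        fst = 0.1,
                        ld_block_len = 10,
                        ld_rho = 0.6,
                        seed = 1L) {
  if (length(group_labels) != length(n_per_group)) {
    stop_field("group_labels", "must match the length of n_per_group")
  }
  if (any(n_per_group < 1)) stop_field("n_per_group", "every group needs >= 1 sample")
  fst <- rep_len(fst, length(n_per_group))
  if (any(fst < 0 | fst >= 1)) stop_field("fst", "must lie in [0, 1)")
  if (abs(ld_rho) >= 1) stop_field("ld_rho", "must lie in (-1, 1)")
  if (n_variants < n_chromosomes) stop_field("n_variants", "need >= n_chromosomes variants")
  if (ld_block_len < 1) stop_field("ld_block_len", "must be >= 1")
  structure(
    list(n_per_group = as.integer(n_per_group), group_labels = group_labels,
         n_variants = as.integer(n_variants), n_chromosomes = as.integer(n_chromosomes),
         fst = fst, ld_block_len = as.integer(ld_block_len), ld_rho = ld_rho,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# The variant panel (positions, alleles, ancestral and per-group allele
# frequencies, LD-block ids) is a pure function of the spec seed, so the
# analysis cohort and any discovery cohort drawn later share one panel.
sim_variant_panel <- function(spec) {
  with_rng(derive_seed(spec$seed, 0L), {
    M <- spec$n_variants
    G <- length(spec$group_labels)
    chrom <- sort(rep_len(seq_len(spec$n_chromosomes), M))
    pos <- unlist(lapply(split(seq_len(M), chrom), function(ix) {
      cumsum(sample(1000:20000, length(ix), replace = TRUE))
    }), use.names = FALSE)
    # allele pairs drawn over all distinct ordered pairs, ambiguous ones included
    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, M, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), "")
    p0 <- runif(M, 0.05, 0.5)
    freq <- matrix(0, G, M, dimnames = list(spec$group_labels, NULL))
    for (g in seq_len(G)) {
      f <- spec$fst[g]
      freq[g, ] <- if (f == 0) p0 else
        rbeta(M, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
    }
    # keep frequencies away from fixation so every variant stays polymorphic
    freq <- pmin(pmax(freq, 0.01), 0.99)
    # blocks never span a chromosome boundary
    block <- stats::ave(seq_len(M), chrom, FUN = function(ix) {
      (seq_along(ix) - 1L) %/% spec$ld_block_len
    })
    block <- as.integer(interaction(chrom, block, drop = TRUE))
    list(variants = data.frame(
           id = sprintf("v%05d", seq_len(M)), chrom = as.integer(chrom),
           pos = as.integer(pos), a1 = unname(a1), a2 = unname(a2),
           stringsAsFactors = FALSE),
         freq = freq, block = block)
  })
}

# One haplotype per call: latent AR(1) Gaussian per sample along the panel,
# reset at block boundaries, thresholded at the frequency-matched quantile.
sim_haplotypes <- function(n, freq_g, block, rho) {
  M <- length(freq_g)
  H <- matrix(0L, n, M)
  z <- rnorm(n)
  thr <- qnorm(freq_g)
  H[, 1] <- (z < thr[1]) + 0L
  if (M > 1) {
    a <- sqrt(1 - rho^2)
    for (v in 2:M) {
      z <- if (block[v] == block[v - 1L]) rho * z + a * rnorm(n) else rnorm(n)
      H[, v] <- (z < thr[v]) + 0L
    }
  }
  H
}

sim_genotypes_from_panel <- function(panel, spec, n_per_group, seed) {
  with_rng(seed, {
    Gn <- length(spec$group_labels)
    mats <- vector("list", Gn)
    for (g in seq_len(Gn)) {
      n <- n_per_group[g]
      mats[[g]] <- sim_haplotypes(n, panel$freq[g, ], panel$block, spec$ld_rho) +
        sim_haplotypes(n, panel$freq[g, ], panel$block, spec$ld_rho)
    }
    G <- do.call(rbind, mats)
    n_tot <- nrow(G)
    samples <- data.frame(
      id = sprintf("S%05d", seq_len(n_tot)),
      group = rep(spec$group_labels, n_per_group),
      study = sample(c("STUDY1", "STUDY2", "STUDY3"), n_tot, replace = TRUE),
      age = pmin(pmax(round(rnorm(n_tot, 50, 16)), 18), 95),
      sex = sample(c("F", "M"), n_tot, replace = TRUE),
      stringsAsFactors = FALSE)
    rownames(G) <- samples$id
    colnames(G) <- panel$variants$id
    variants <- panel$variants
    f <- colMeans(G) / 2
    variants$maf <- pmin(f, 1 - f)
    structure(list(genotypes = G, variants = variants, samples = samples),
              class = "genotype_cohort")
  })
}

#' Simulate a multi-ancestry genotype cohort
#'
#' Draws per-group allele frequencies around shared ancestral frequencies
#' using the Balding-Nichols Beta model with per-group differentiation
#' `fst`, and induces linkage disequilibrium by thresholding a latent
#' within-block AR(1) Gaussian at frequency-matched quantiles (two
#' independent haplotypes per individual). The panel itself (positions,
#' alleles, frequencies) is a pure function of `spec$seed`, so cohorts drawn
#' from the same spec share variants.
#'
#' @param spec A [cohort_spec()].
#' @param n_per_group Optional override of the per-group sample counts
#'   (used internally for discovery cohorts).
#' @param stream Integer stream offset separating independent cohorts drawn
#'   from the same panel.
#' @return A `genotype_cohort`: a samples-by-variants allele-count matrix in
#'   `{0, 1, 2}` plus variant and sample metadata. Pooled MAF is recorded
#'   per variant.
#' @export
simulate_genotypes <- function(spec, n_per_group = NULL, stream = 1L) {
  if (!inherits(spec, "cohort_spec")) stop_field("spec", "must be a cohort_spec")
  panel <- sim_variant_panel(spec)
  sim_genotypes_from_panel(panel, spec, n_per_group %||% spec$n_per_group,
                           derive_seed(spec$seed, stream))
}

#' @export
print.genotype_cohort <- function(x, ...) {
  cat(sprintf("genotype_cohort: %d samples x %d variants, %d chromosome(s), groups: %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$variants$chrom)),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

#' Trait architecture for the simulator
#'
#' Collects the genetic and non-genetic components of a simulated
#' quantitative trait: additive per-allele effects, dominance deviations
#' (applied to heterozygotes), pairwise epistatic effects on the product of
#' allele counts, joint-carrier ("haplotype-like") effects on unphased
#' counts, the target narrow+non-additive genetic variance fraction, fixed
#' covariate effects, a logistic medication-use model on the raw trait, and
#' a phenotype missingness rate.
#'
#' @param additive Named numeric vector of per-allele effects (names are
#'   variant ids).
#' @param dominance Named numeric vector of dominance deviations added for
#'   heterozygous genotypes.
#' @param epistatic_pairs Data frame with columns `id1`, `id2`, `effect`;
#'   each row contributes `effect * g1 * g2`.
#' @param haplotype_effects List of `list(ids =, effect =)`; each contributes
#'   `effect` when every listed variant carries at least one effect allele
#'   (the closest unphased analogue of a haplotype effect).
#' @param target_h2 Fraction of the (genetic + noise) variance that is
#'   genetic, in `[0, 1)`. Covariate effects sit on top of this and are
#'   removed again during harmonization.
#' @param covariate_effects List with optional elements `age`, `sex`
#'   (added for males), and `study` (named vector of study effects).
#' @param med_model List with `intercept` and `slope` of a logistic model
#'   for medication use on the standardized raw trait, or `NULL` for no
#'   medication use.
#' @param missing_rate Fraction of phenotypes set missing at random.
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(additive = numeric(),
                               dominance = numeric(),
                               epistatic_pairs = NULL,
                               haplotype_effects = list(),
                               target_h2 = 0.5,
                               covariate_effects = list(),
                               med_model = NULL,
                               missing_rate = 0) {
  if (target_h2 < 0 || target_h2 >= 1) stop_field("target_h2", "must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop_field("missing_rate", "must lie in [0, 1)")
  if (is.null(epistatic_pairs)) {
    epistatic_pairs <- data.frame(id1 = character(), id2 = character(),
                                  effect = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(additive = additive, dominance = dominance,
                 epistatic_pairs = epistatic_pairs,
                 haplotype_effects = haplotype_effects,
                 target_h2 = target_h2, covariate_effects = covariate_effects,
                 med_model = med_model, missing_rate = missing_rate),
            class = "trait_architecture")
}

arch_variant_ids <- function(arch) {
  unique(c(names(arch$additive), names(arch$dominance),
           arch$epistatic_pairs$id1, arch$epistatic_pairs$id2,
           unlist(lapply(arch$haplotype_effects, `[[`, "ids"))))
}

# Raw genetic value of every sample under an architecture (no rescaling).
genetic_value <- function(cohort, arch) {
  G <- cohort$genotypes
  val <- numeric(nrow(G))
  if (length(arch$additive)) {
    val <- val + as.vector(G[, names(arch$additive), drop = FALSE] %*% arch$additive)
  }
  if (length(arch$dominance)) {
    val <- val + as.vector((G[, names(arch$dominance), drop = FALSE] == 1L) %*%
                             arch$dominance)
  }
  ep <- arch$epistatic_pairs
  for (k in seq_len(nrow(ep))) {
    val <- val + ep$effect[k] * G[, ep$id1[k]] * G[, ep$id2[k]]
  }
  for (h in arch$haplotype_effects) {
    carrier <- rowSums(G[, h$ids, drop = FALSE] >= 1L) == length(h$ids)
    val <- val + h$effect * carrier
  }
  val
}

#' Simulate a quantitative trait on a cohort
#'
#' Builds the genetic value (additive + dominance + epistatic + joint-carrier
#' components), chooses the Gaussian noise variance so that
#' `var(genetic) / (var(genetic) + var(noise))` equals `target_h2`, then adds
#' fixed covariate effects (age, sex, study). Medication-use flags are drawn
#' from the architecture's logistic model on the standardized raw trait, and
#' phenotypes are set missing at `missing_rate`.
#'
#' @param cohort A `genotype_cohort`.
#' @param arch A [trait_architecture()]; must reference only cohort variants.
#' @param seed Integer seed for noise, medication, and missingness draws.
#' @return A list of class `sim_trait` with elements `phenotype`,
#'   `med_flags`, `genetic_value`, and `sigma2_e`.
#' @export
simulate_trait <- function(cohort, arch, seed = 1L) {
  assert_cohort(cohort)
  unknown <- setdiff(arch_variant_ids(arch), cohort$variants$id)
  if (length(unknown)) {
    stop("architecture references unknown variant id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  gval <- genetic_value(cohort, arch)
  n <- length(gval)
  with_rng(seed, {
    vg <- stats::var(gval)
    h2 <- arch$target_h2
    if (h2 == 0 || vg == 0) {
      contrib <- 0
      sigma2_e <- if (vg > 0) vg else 1
    } else {
      contrib <- 1
      sigma2_e <- vg * (1 - h2) / h2
    }
    y <- contrib * gval + rnorm(n, 0, sqrt(sigma2_e))
    ce <- arch$covariate_effects
    if (!is.null(ce$age)) y <- y + ce$age * cohort$samples$age
    if (!is.null(ce$sex)) y <- y + ce$sex * (cohort$samples$sex == "M")
    if (!is.null(ce$study)) {
      y <- y + unname(ce$study[cohort$samples$study])
    }
    med <- rep(FALSE, n)
    if (!is.null(arch$med_model)) {
      pr <- stats::plogis(arch$med_model$intercept +
                            arch$med_model$slope * as.vector(scale(y)))
      med <- runif(n) < pr
    }
    if (arch$missing_rate > 0) y[runif(n) < arch$missing_rate] <- NA_real_
    names(y) <- cohort$samples$id
    names(med) <- cohort$samples$id
    structure(list(phenotype = y, med_flags = med, genetic_value = gval,
                   sigma2_e = sigma2_e),
              class = "sim_trait")
  })
}

#' Simulate GWAS summary statistics from an independent discovery cohort
#'
#' Draws a fresh cohort from the same variant panel as `spec` (so variant
#' ids, positions, and alleles line up with the analysis cohort) with group
#' sampling proportions `group_weights` — concentrating the weights on one
#' group emulates an ancestry-skewed discovery GWAS. The trait is simulated
#' under `arch`, and marginal per-variant regressions adjusted for age and
#' sex produce the summary statistics. The discovery samples come from a
#' random-number stream disjoint from the analysis cohort's, so no sample is
#' shared.
#'
#' @param spec The [cohort_spec()] shared with the analysis cohort.
#' @param arch The [trait_architecture()] generating the trait.
#' @param n_discovery Discovery sample size (>= 2).
#' @param group_weights Sampling proportions per group; must sum to 1.
#' @param seed Integer seed for the discovery stream.
#' @return A summary-statistics data frame with columns
#'   `id, chrom, pos, a1, a2, beta, se, p, n`.
#' @export
make_discovery_sumstats <- function(spec, arch, n_discovery = 10000,
                                    group_weights = NULL, seed = 1000L) {
  if (n_discovery < 2) stop_field("n_discovery", "must be >= 2")
  Gn <- length(spec$group_labels)
  group_weights <- group_weights %||% rep(1 / Gn, Gn)
  if (abs(sum(group_weights) - 1) > 1e-8) {
    stop_field("group_weights", "must sum to 1")
  }
  # largest-remainder apportionment of n_discovery over groups
  raw <- n_discovery * group_weights
  n_g <- floor(raw)
  rem <- n_discovery - sum(n_g)
  if (rem > 0) {
    bump <- order(raw - n_g, decreasing = TRUE)[seq_len(rem)]
    n_g[bump] <- n_g[bump] + 1
  }
  panel <- sim_variant_panel(spec)
  disc <- sim_genotypes_from_panel(panel, spec, as.integer(n_g),
                                   derive_seed(seed, 90000L))
  trait <- simulate_trait(disc, arch, seed = derive_seed(seed, 90001L))
  covars <- stats::model.matrix(~ age + sex, disc$samples)[, -1, drop = FALSE]
  marginal_gwas(disc, trait$phenotype, covariates = covars)
}

#' Draw a random trait architecture on a cohort spec's variant panel
#'
#' Convenience generator for simulation studies: picks causal variants from
#' the panel (restricted to reasonably common ones, pooled frequency in
#' `[0.15, 0.85]`, so signals are detectable at realistic sample sizes) and
#' assigns Gaussian effect sizes. Additive, dominance, pairwise-epistatic,
#' and joint-carrier components can be mixed freely; `target_h2` fixes the
#' overall genetic variance fraction.
#'
#' @param spec A [cohort_spec()].
#' @param n_additive,n_dominance,n_epistatic,n_haplotype Component counts
#'   (`n_epistatic` counts variant pairs; `n_haplotype` counts variant
#'   triples with a joint-carrier effect).
#' @param add_sd,dom_sd,epi_sd,hap_sd Effect-size standard deviations; the
#'   relative sizes set how the genetic variance splits across components.
#' @param target_h2,covariate_effects,med_model,missing_rate Passed through
#'   to [trait_architecture()].
#' @param seed Integer seed for the draw.
#' @return A [trait_architecture()].
#' @export
random_architecture <- function(spec, n_additive = 20, n_dominance = 0,
                                n_epistatic = 0, n_haplotype = 0,
                                add_sd = 0.15, dom_sd = 0.15,
                                epi_sd = 0.3, hap_sd = 0.5,
                                target_h2 = 0.5,
                                covariate_effects = list(age = 0.02, sex = 0.2),
                                med_model = NULL, missing_rate = 0,
                                seed = 1L) {
  panel <- sim_variant_panel(spec)
  fbar <- colMeans(panel$freq)
  pool <- panel$variants$id[fbar >= 0.15 & fbar <= 0.85]
  need <- n_additive + n_dominance + 2 * n_epistatic + 3 * n_haplotype
  if (need > length(pool)) {
    stop_field("n_additive", "panel has too few common variants for the architecture")
  }
  with_rng(derive_seed(seed, 555L), {
    ids <- sample(pool, need)
    take <- function(k) {
      if (k == 0) return(character())
      out <- ids[seq_len(k)]
      ids <<- ids[-seq_len(k)]
      out
    }
    additive <- stats::setNames(rnorm(n_additive, 0, add_sd), take(n_additive))
    dominance <- stats::setNames(rnorm(n_dominance, 0, dom_sd), take(n_dominance))
    epi <- if (n_epistatic > 0) {
      data.frame(id1 = take(n_epistatic), id2 = take(n_epistatic),
                 effect = rnorm(n_epistatic, 0, epi_sd) +
                   epi_sd * sign(rnorm(n_epistatic)),
                 stringsAsFactors = FALSE)
    } else NULL
    hap <- lapply(seq_len(n_haplotype), function(i) {
      list(ids = take(3), effect = rnorm(1, 0, hap_sd) + hap_sd)
    })
    trait_architecture(additive = additive, dominance = dominance,
                       epistatic_pairs = epi, haplotype_effects = hap,
                       target_h2 = target_h2,
                       covariate_effects = covariate_effects,
                       med_model = med_model, missing_rate = missing_rate)
  })
}
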