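test_that("contrast codings reduce to the classical orthogonal partition at equal frequencies", {
  cod <- genotype_codes(c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_equal(cod$a, c(-1, -1, 0, 0, 1, 1))
  # dominance ~ (-1/2, +1/2, -1/2) up to scale
  expect_equal(cod$d / max(cod$d), c(-0.5, -0.5, 1, 1, -0.5, -0.5))
})

test_that("codings are orthogonal to the constant and to each other under observed frequencies", {
  set.seed(10)
  for (rep in 1:20) {
    g <- polymorphic_locus(50, runif(1, 0.15, 0.5))
    cod <- genotype_codes(g)
    expect_lt(abs(sum(cod$a)), 1e-10)
    expect_lt(abs(sum(cod$d)), 1e-10)
    expect_lt(abs(sum(cod$a * cod$d)), 1e-10)
  }
})

test_that("a two-class locus leaves the dominance contrast undefined and flags dependent effects", {
  g1 <- rep(c(0L, 1L), 20)              # only classes {0,1}
  g2 <- rep(c(0L, 1L, 2L, 1L), 10)
  cod <- genotype_codes(g1)
  expect_null(cod$d)
  expect_equal(cod$n_classes, 2L)
  des <- build_pair_design(g1, g2)
  expect_setequal(names(des$untestable), c("DA", "DD"))
  expect_setequal(colnames(des$ia), c("AA", "AD"))
  res <- test_pair(des, rnorm(40))
  expect_false(any(res$effects$testable[res$effects$effect %in% c("DA", "DD")]))
})

test_that("pairs with a monomorphic locus are skipped with a reason", {
  expect_error(build_pair_design(rep(0L, 30), rep(c(0L, 1L, 2L), 10)),
               class = "epi_skip")
})

test_that("a noise-free purely additive surface yields zero interaction SS and P = 1", {
  set.seed(12)
  pr <- pair_with_full_cells(120, 0.4, 0.35)
  y <- 2 + 1.5 * pr$g1 - 0.7 * pr$g2
  des <- build_pair_design(pr$g1, pr$g2)
  res <- test_pair(des, y)
  expect_equal(res$overall$p, 1)
  expect_true(all(res$effects$ss[res$effects$testable] == 0))
  expect_true(all(res$effects$p[res$effects$testable] == 1))
})

test_that("balanced 3x3 layout: AA SS equals the classical linear-by-linear contrast SS", {
  r <- 6  # equal cell counts
  g1 <- rep(rep(0:2, each = 3), r)
  g2 <- rep(rep(0:2, times = 3), r)
  set.seed(13)
  y <- 1 + 0.4 * g1 - 0.2 * g2 + 0.5 * (g1 - 1) * (g2 - 1) + rnorm(9 * r)
  des <- build_pair_design(as.integer(g1), as.integer(g2))
  res <- test_pair(des, y)
  # textbook two-way ANOVA contrast: weights (-1,0,1) x (-1,0,1) on cell means
  cell_means <- tapply(y, list(g1, g2), mean)
  w <- outer(c(-1, 0, 1), c(-1, 0, 1))
  L <- sum(w * cell_means)
  ss_ll <- L^2 / (sum(w^2) / r)
  expect_equal(res$effects$ss[res$effects$effect == "AA"], ss_ll,
               tolerance = 1e-10)
})

test_that("in a frequency-balanced crossed design the four 1-df SS sum to the overall interaction SS", {
  # cell counts exactly proportional to the product of the marginals, and the
  # whole layout replicated in each family, so all contrast columns are
  # mutually orthogonal and the decomposition is exact
  m1 <- c(3, 2, 1); m2 <- c(1, 2, 3)
  g1 <- integer(0); g2 <- integer(0)
  for (i in 0:2) for (j in 0:2) {
    g1 <- c(g1, rep(i, 2 * m1[i + 1] * m2[j + 1]))
    g2 <- c(g2, rep(j, 2 * m1[i + 1] * m2[j + 1]))
  }
  fam <- rep(1:2, times = length(g1) / 2)  # families as replicate blocks
  set.seed(14)
  y <- rnorm(length(g1)) + 0.3 * g1 * g2
  des <- build_pair_design(as.integer(g1), as.integer(g2), family = fam)
  res <- test_pair(des, y)
  overall_ss <- res$overall$ss
  expect_equal(sum(res$effects$ss), overall_ss,
               tolerance = 1e-8 * overall_ss)
})

test_that("test_pair matches the lm model-comparison oracle on random small designs", {
  set.seed(15)
  for (rep in 1:30) {
    n <- 80
    pr <- pair_with_full_cells(n, runif(1, 0.2, 0.5), runif(1, 0.2, 0.5))
    fam <- sample(1:3, n, replace = TRUE)
    y <- rnorm(n) + 0.2 * pr$g1 + 0.3 * (pr$g1 == 1) * (pr$g2 == 1)
    des <- build_pair_design(pr$g1, pr$g2, family = fam)
    res <- test_pair(des, y)
    orc <- lm_overall_oracle(pr$g1, pr$g2, fam, y)
    expect_equal(res$overall$F, orc$F, tolerance = 1e-8)
    expect_equal(res$overall$p, orc$p, tolerance = 1e-8)
    expect_equal(res$overall$df1, orc$df1)
  }
})

test_that("per-effect marginal SS match an lm drop1 oracle", {
  set.seed(16)
  for (rep in 1:10) {
    n <- 100
    pr <- pair_with_full_cells(n, 0.4, 0.3)
    fam <- sample(1:4, n, replace = TRUE)
    y <- rnorm(n)
    des <- build_pair_design(pr$g1, pr$g2, family = fam)
    res <- test_pair(des, y)
    d <- data.frame(y = y, fam = factor(fam), a1 = des$a1, d1 = des$d1,
                    a2 = des$a2, d2 = des$d2,
                    AA = des$ia[, "AA"], AD = des$ia[, "AD"],
                    DA = des$ia[, "DA"], DD = des$ia[, "DD"])
    fit <- lm(y ~ fam + a1 + d1 + a2 + d2 + AA + AD + DA + DD, d)
    dr <- drop1(fit, scope = ~ AA + AD + DA + DD, test = "F")
    expect_equal(res$effects$ss, dr$`Sum of Sq`[-1], tolerance = 1e-8)
    expect_equal(res$effects$p, dr$`Pr(>F)`[-1], tolerance = 1e-8)
  }
})

test_that("a planted AA effect is the most significant of the four effects in most replicates", {
  wins <- vapply(1:50, function(s) {
    set.seed(700 + s)
    pr <- pair_with_full_cells(500, 0.4, 0.4)
    c1 <- genotype_codes(pr$g1); c2 <- genotype_codes(pr$g2)
    y <- 0.35 * c1$a * c2$a + rnorm(500)
    res <- test_pair(build_pair_design(pr$g1, pr$g2), y)
    which.min(res$effects$p) == 1L
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("Bonferroni arithmetic over all pairs", {
  bf <- bonferroni_pairs(45611, alpha = 0.05, tests_per_pair = 4)
  expect_equal(bf$n_tests, 4 * choose(45611, 2))
  expect_equal(bf$n_tests / 1e9, 4.16, tolerance = 0.001)
  expect_equal(bf$threshold / 1e-11, 1.20, tolerance = 0.002)
  expect_equal(bonferroni_pairs(2, tests_per_pair = 1)$threshold, 0.05)
  expect_equal(bonferroni_pairs(100)$threshold, 0.05 / 19800)
})

test_that("contribution rate is SS over total corrected SS, in percent", {
  y <- c(1, 2, 3, 4, 10)
  tss <- sum((y - mean(y))^2)
  expect_equal(contribution_rate(0, y), 0)
  expect_equal(contribution_rate(tss, y), 100)
  expect_equal(contribution_rate(tss / 8, y), 12.5)
  expect_error(contribution_rate(1, c(2, 2, 2)), "zero")
})

test_that("run_scan recovers a planted pair with its effect type and nothing else", {
  cfg <- sim_config(n_individuals = 400, n_families = 4, n_snps = 30,
                    maf_law = c(0.25, 0.5), missing_rate = 0.01, seed = 80)
  geno <- generate_genotypes(cfg)
  beta <- effect_size_for_contribution(geno, 5, 20, "AA", 15, 1.25)
  cfg$planted_effects <- list(planted_epistasis(5, 20, "AA", beta))
  phen <- generate_phenotypes(geno, cfg)
  scan <- run_scan(geno$genotypes, geno$map, phen$y, phen$family,
                   threshold = 1e-8)
  sig <- scan$significant
  expect_equal(nrow(sig), 1L)
  expect_setequal(c(sig$snp1, sig$snp2), c("snp0005", "snp0020"))
  expect_equal(sig$effect_type, "AA")
  expect_gt(sig$c_pct, 10)
})

test_that("run_scan on pure noise controls the familywise error", {
  null_hits <- vapply(1:3, function(s) {
    cfg <- sim_config(n_individuals = 200, n_families = 4, n_snps = 50,
                      maf_law = c(0.2, 0.5), missing_rate = 0, seed = 900 + s)
    geno <- generate_genotypes(cfg)
    phen <- generate_phenotypes(geno, cfg)
    thr <- bonferroni_pairs(50)$threshold
    nrow(run_scan(geno$genotypes, geno$map, phen$y, phen$family,
                  threshold = thr)$significant)
  }, numeric(1))
  expect_lte(sum(null_hits > 0), 1)
})

test_that("scan results are invariant to individual order and locus swap flips AD/DA", {
  cfg <- sim_config(n_individuals = 300, n_families = 3, n_snps = 6,
                    maf_law = 0.4, missing_rate = 0, seed = 83)
  geno <- generate_genotypes(cfg)
  beta <- effect_size_for_contribution(geno, 2, 4, "AD", 12, 1.25)
  cfg$planted_effects <- list(planted_epistasis(2, 4, "AD", beta))
  phen <- generate_phenotypes(geno, cfg)

  scan <- run_scan(geno$genotypes, geno$map, phen$y, phen$family,
                   threshold = 1e-6)
  perm <- sample(nrow(geno$genotypes))
  scan_p <- run_scan(geno$genotypes[perm, ], geno$map, phen$y[perm],
                     phen$family[perm], threshold = 1e-6)
  expect_equal(scan$significant, scan_p$significant, tolerance = 1e-9)

  # swapping the two loci's columns (and map rows) exchanges AD and DA
  des <- build_pair_design(geno$genotypes[, 2], geno$genotypes[, 4], phen$family)
  des_sw <- build_pair_design(geno$genotypes[, 4], geno$genotypes[, 2], phen$family)
  r1 <- test_pair(des, phen$y)
  r2 <- test_pair(des_sw, phen$y)
  expect_equal(r1$effects$p[r1$effects$effect == "AD"],
               r2$effects$p[r2$effects$effect == "DA"], tolerance = 1e-9)
  expect_equal(r1$overall$F, r2$overall$F, tolerance = 1e-9)
})

test_that("empty or degenerate scans raise explicit errors", {
  expect_error(run_scan(matrix(integer(0), 0, 0), phenotype = numeric(0)),
               "at least 2 SNPs")
  g <- cbind(a = rep(0L, 10), b = rep(c(0L, 1L, 2L), length.out = 10))
  scan <- run_scan(g, phenotype = rnorm(10), threshold = 0.05)
  expect_equal(nrow(scan$skipped), 1L)
  expect_match(scan$skipped$reason, "genotype classes")
})

test_that("random family mode agrees with fixed absorption on a strong planted signal", {
  cfg <- sim_config(n_individuals = 400, n_families = 5,
                    family_variance = 0.5, n_snps = 6, maf_law = 0.4,
                    missing_rate = 0, seed = 86)
  geno <- generate_genotypes(cfg)
  beta <- effect_size_for_contribution(geno, 1, 3, "AA", 10, 1.5)
  cfg$planted_effects <- list(planted_epistasis(1, 3, "AA", beta))
  phen <- generate_phenotypes(geno, cfg)
  des <- build_pair_design(geno$genotypes[, 1], geno$genotypes[, 3], phen$family)
  rf <- test_pair(des, phen$y, family_mode = "fixed")
  rr <- test_pair(des, phen$y, family_mode = "random")
  expect_equal(which.min(rf$effects$p), which.min(rr$effects$p))
  expect_lt(rf$effects$p[1], 1e-6)
  expect_lt(rr$effects$p[1], 1e-6)
  # family-adjusted denominator excludes the family variance, so the
  # random-mode contribution is at least the fixed-mode one
  expect_gte(rr$effects$c_pct[1], rf$effects$c_pct[1] - 1e-8)
})

test_that("single-locus scan: monomorphic SNPs skipped, planted additive effect recovered, null P uniform", {
  # monomorphic skip
  g <- cbind(mono = rep(0L, 30), ok = rep(c(0L, 1L, 2L), 10))
  res <- single_locus_scan(g, phenotype = rnorm(30))
  expect_equal(res$snp, "ok")
  expect_equal(attr(res, "skipped")$snp, "mono")

  # planted additive SNP at ~1.5% variance, 20 seeds
  recov <- vapply(1:20, function(s) {
    cfg <- sim_config(n_individuals = 1000, n_families = 4, n_snps = 8,
                      maf_law = 0.3, missing_rate = 0, seed = 300 + s)
    geno <- generate_genotypes(cfg)
    a <- genotype_codes(geno$genotypes[, 2])$a
    target_beta <- sqrt(0.015 / 0.985 * 1.25 / var(a))
    cfg$planted_effects <- list(
      planted_epistasis(2, 3, "AA", 0, main_a_i = target_beta))
    phen <- generate_phenotypes(geno, cfg)
    res <- single_locus_scan(geno$genotypes, geno$map, phen$y, phen$family)
    res$c_pct[res$snp == "snp0002"]
  }, numeric(1))
  expect_lt(abs(mean(recov) - 1.5), 0.4)

  # null phenotype: P-values uniform by Kolmogorov-Smirnov at the 1% level
  set.seed(17)
  gg <- make_geno(300, runif(2000, 0.1, 0.5), seed = 17)
  y <- rnorm(300)
  res <- single_locus_scan(gg, phenotype = y)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})
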