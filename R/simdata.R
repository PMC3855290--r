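#' Configuration of a synthetic family-structured cohort
#'
#' Defines the generative model mirrored on the analysis side: a quantitative
#' trait `y = mu + main effects + planted epistatic contrast products +
#' family effect + e`, with family a Gaussian random effect (one draw per
#' family) and `e` Gaussian residual noise, over biallelic SNP genotypes with
#' a controllable minor-allele-frequency law, optional Hardy-Weinberg
#' disequilibrium and optional block linkage disequilibrium.
#'
#' The defaults emulate the study design this generator stands in for: 475
#' individuals from a line-cross population with family structure (family
#' count and sizes are free parameters of the design, here 10 equal
#' families), a MAF spectrum uniform on \[0.05, 0.5\] (the post-QC floor),
#' unit residual variance and a modest family variance.
#'
#' @param n_individuals cohort size.
#' @param n_families number of equal-sized families (assigned at random).
#' @param family_variance variance of the per-family Gaussian effect
#'   (trait units squared).
#' @param residual_variance variance of the residual.
#' @param grand_mean population mean of the trait.
#' @param n_snps number of markers.
#' @param maf_law minor-allele-frequency law: a single value in (0, 0.5]
#'   (all SNPs share it), a length-2 range in (0, 0.5] for uniform draws,
#'   or a function `n -> n MAFs`.
#' @param hwd_coefficient per-SNP Hardy-Weinberg departure `D`: genotype
#'   frequencies are `p^2 + D`, `2pq - 2D`, `q^2 + D` for 0/1/2 copies of
#'   the minor allele (frequency `q`).  Feasible iff
#'   `-min(p^2, q^2) <= D <= p*q`.
#' @param ld_blocks optional list of blocks, each `list(snps =, r2 =)`:
#'   column indices simulated as one LD block with target pairwise `r2`.
#' @param planted_effects list of [planted_epistasis()] objects.
#' @param missing_rate independent per-call missing-genotype probability.
#' @param n_chromosomes markers are split evenly over this many chromosomes
#'   with strictly increasing positions (mean spacing ~17 kb, jittered).
#' @param seed integer seed; with a fixed seed all outputs are bit-identical
#'   across runs.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 475, n_families = 10,
                       family_variance = 0.25, residual_variance = 1,
                       grand_mean = 0, n_snps = 500,
                       maf_law = c(0.05, 0.5), hwd_coefficient = 0,
                       ld_blocks = NULL, planted_effects = list(),
                       missing_rate = 0.01, n_chromosomes = 1, seed = 1) {
  stopifnot(
    n_individuals >= 2 * n_families, n_families >= 1,
    family_variance >= 0, residual_variance >= 0,
    n_snps >= 1, missing_rate >= 0, missing_rate < 1,
    n_chromosomes >= 1
  )
  if (is.numeric(maf_law)) {
    if (!all(maf_law > 0 & maf_law <= 0.5)) {
      stop("maf_law values must lie in (0, 0.5]")
    }
  } else if (!is.function(maf_law)) {
    stop("maf_law must be numeric or a function")
  }
  for (pe in planted_effects) {
    if (!inherits(pe, "planted_epistasis")) {
      stop("planted_effects must be a list of planted_epistasis() objects")
    }
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_families = as.integer(n_families),
      family_variance = family_variance,
      residual_variance = residual_variance,
      grand_mean = grand_mean,
      n_snps = as.integer(n_snps),
      maf_law = maf_law,
      hwd_coefficient = hwd_coefficient,
      ld_blocks = ld_blocks,
      planted_effects = planted_effects,
      missing_rate = missing_rate,
      n_chromosomes = as.integer(n_chromosomes),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' A planted two-locus epistatic effect
#'
#' The planted effect enters the phenotype as `effect_size` times the product
#' of the frequency-orthogonal contrast codings ([genotype_codes()]) named by
#' `effect_type`, so planted and estimated effects are commensurable.
#' Optional main effects at each locus multiply the additive (`main_a_*`) and
#' dominance (`main_d_*`) codes.
#'
#' @param snp_i,snp_j SNP identifiers or column indices, distinct.
#' @param effect_type one of `"AA"`, `"AD"`, `"DA"`, `"DD"`.
#' @param effect_size trait units per unit of the contrast product.
#' @param main_a_i,main_d_i,main_a_j,main_d_j optional main-effect sizes.
#' @return object of class `planted_epistasis`.
#' @export
planted_epistasis <- function(snp_i, snp_j, effect_type, effect_size,
                              main_a_i = 0, main_d_i = 0,
                              main_a_j = 0, main_d_j = 0) {
  effect_type <- match.arg(effect_type, c("AA", "AD", "DA", "DD"))
  if (identical(snp_i, snp_j)) stop("snp_i and snp_j must differ")
  structure(
    list(snp_i = snp_i, snp_j = snp_j, effect_type = effect_type,
         effect_size = effect_size,
         main_a_i = main_a_i, main_d_i = main_d_i,
         main_a_j = main_a_j, main_d_j = main_d_j),
    class = "planted_epistasis"
  )
}

draw_mafs <- function(maf_law, n) {
  if (is.function(maf_law)) {
    q <- maf_law(n)
  } else if (length(maf_law) == 1L) {
    q <- rep(maf_law, n)
  } else {
    q <- stats::runif(n, min(maf_law), max(maf_law))
  }
  if (!all(q > 0 & q <= 0.5)) stop("drawn MAFs must lie in (0, 0.5]")
  q
}

#' Generate genotypes and a marker map
#'
#' Draws per-SNP minor-allele frequencies from the configured law and samples
#' genotypes from the Hardy-Weinberg-disequilibrium frequencies
#' `p^2 + D, 2pq - 2D, q^2 + D`.  LD blocks are simulated by copying a
#' founder haplotype signal with a per-site mutation probability tuned to the
#' target `r2` (sites in a block share the block's first MAF and are in HWE).
#' Missing calls are masked independently at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (individuals x SNPs integer matrix, codes
#'   0/1/2 and `NA`), `map` (data.frame `snp`, `chrom`, `pos`, strictly
#'   increasing positions per chromosome) and `maf` (drawn frequencies).
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps
  q <- draw_mafs(config$maf_law, m)
  D <- config$hwd_coefficient
  p <- 1 - q
  bad <- which(D < -pmin(p^2, q^2) - 1e-12 | D > p * q + 1e-12)
  if (length(bad)) {
    stop(sprintf(
      paste0("hwd_coefficient D = %g is infeasible for MAF %.4f ",
             "(needs -min(p^2, q^2) = %.4f <= D <= p*q = %.4f); ",
             "a genotype frequency would be negative"),
      D, q[bad[1]], -min(p[bad[1]]^2, q[bad[1]]^2), p[bad[1]] * q[bad[1]]))
  }

  G <- matrix(0L, n, m)
  in_block <- rep(FALSE, m)
  if (!is.null(config$ld_blocks)) {
    for (b in config$ld_blocks) {
      idx <- b$snps
      stopifnot(all(idx >= 1 & idx <= m), b$r2 >= 0, b$r2 <= 1)
      in_block[idx] <- TRUE
      qb <- q[idx[1]]
      q[idx] <- qb
      # allele copied from the founder haplotype with prob 1 - mu, else
      # redrawn: hap correlation (1-mu)^2, genotype r2 = (1-mu)^4
      mu <- 1 - b$r2^(1 / 4)
      anchor1 <- stats::rbinom(n, 1L, qb)
      anchor2 <- stats::rbinom(n, 1L, qb)
      for (s in idx) {
        keep1 <- stats::runif(n) >= mu
        keep2 <- stats::runif(n) >= mu
        h1 <- ifelse(keep1, anchor1, stats::rbinom(n, 1L, qb))
        h2 <- ifelse(keep2, anchor2, stats::rbinom(n, 1L, qb))
        G[, s] <- as.integer(h1 + h2)
      }
    }
  }
  loose <- which(!in_block)
  for (s in loose) {
    probs <- c(p[s]^2 + D, 2 * p[s] * q[s] - 2 * D, q[s]^2 + D)
    probs <- pmax(probs, 0)
    G[, s] <- sample(0:2, n, replace = TRUE, prob = probs)
  }
  if (config$missing_rate > 0) {
    G[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  }
  snp_ids <- sprintf("snp%04d", seq_len(m))
  dimnames(G) <- list(sprintf("ind%04d", seq_len(n)), snp_ids)
  chrom <- as.character(rep(seq_len(config$n_chromosomes),
                            each = ceiling(m / config$n_chromosomes)))[seq_len(m)]
  pos <- numeric(m)
  for (cc in unique(chrom)) {
    ii <- which(chrom == cc)
    pos[ii] <- cumsum(sample(5000:30000, length(ii), replace = TRUE))
  }
  map <- data.frame(snp = snp_ids, chrom = chrom, pos = pos,
                    stringsAsFactors = FALSE)
  list(genotypes = G, map = map, maf = q)
}

# contrast value of one locus for every individual: codes computed on the
# observed (non-missing) calls; missing calls contribute the mean (zero)
planted_code <- function(g, which = c("a", "d")) {
  which <- match.arg(which)
  ok <- !is.na(g)
  if (length(unique(g[ok])) < 2L) return(NULL)  # monomorphic
  cod <- genotype_codes(g[ok])
  v <- if (which == "a") cod$a else cod$d
  if (is.null(v)) return(NULL)
  out <- numeric(length(g))
  out[ok] <- v
  out
}

#' Generate phenotypes with planted epistatic architecture
#'
#' Builds `y = mu + main effects + planted contrast products + family draw +
#' Gaussian error`.  Planted contrasts use the same frequency-orthogonal
#' codings as the analysis side, computed on the realized genotypes, so the
#' realized contribution of each planted pair (percent of the total corrected
#' sum of squares, the same scale as [contribution_rate()]) is reported in
#' the `"planted"` attribute.  A planted SNP that is monomorphic in the
#' realized sample triggers a warning and contributes nothing.
#'
#' @param geno result of [generate_genotypes()] (or a compatible list).
#' @param config the same [sim_config()].
#' @return data.frame `id`, `family`, `y` with attribute `planted`, a
#'   data.frame of the planted pairs and their realized contributions.
#' @export
generate_phenotypes <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  G <- geno$genotypes
  n <- nrow(G)
  set.seed(config$seed + 1L)
  fam <- factor(sample(rep(seq_len(config$n_families), length.out = n)))
  fam_eff <- stats::rnorm(config$n_families, 0, sqrt(config$family_variance))
  y <- rep(config$grand_mean, n) + fam_eff[as.integer(fam)]

  resolve <- function(s) {
    if (is.character(s)) match(s, colnames(G)) else as.integer(s)
  }
  planted <- list()
  terms <- list()
  for (pe in config$planted_effects) {
    i <- resolve(pe$snp_i); j <- resolve(pe$snp_j)
    if (is.na(i) || is.na(j)) stop("planted SNP not present in the genotype matrix")
    a_i <- planted_code(G[, i], "a"); d_i <- planted_code(G[, i], "d")
    a_j <- planted_code(G[, j], "a"); d_j <- planted_code(G[, j], "d")
    for (me in list(c("main_a_i", "a_i"), c("main_d_i", "d_i"),
                    c("main_a_j", "a_j"), c("main_d_j", "d_j"))) {
      sz <- pe[[me[1]]]
      v <- get(me[2])
      if (sz != 0 && !is.null(v)) y <- y + sz * v
    }
    u <- switch(pe$effect_type,
                AA = list(a_i, a_j), AD = list(a_i, d_j),
                DA = list(d_i, a_j), DD = list(d_i, d_j))
    if (is.null(u[[1]]) || is.null(u[[2]])) {
      warning(sprintf(
        "planted %s effect at (%s, %s): required contrast undefined in the realized sample; effect contributes nothing",
        pe$effect_type, colnames(G)[i], colnames(G)[j]))
      term <- numeric(n)
    } else {
      term <- pe$effect_size * u[[1]] * u[[2]]
    }
    y <- y + term
    terms[[length(terms) + 1L]] <- term
    planted[[length(planted) + 1L]] <- data.frame(
      snp_i = colnames(G)[i], snp_j = colnames(G)[j],
      effect_type = pe$effect_type, effect_size = pe$effect_size,
      stringsAsFactors = FALSE)
  }
  y <- y + stats::rnorm(n, 0, sqrt(config$residual_variance))

  out <- data.frame(id = rownames(G), family = fam, y = y,
                    stringsAsFactors = FALSE)
  if (length(planted)) {
    planted <- do.call(rbind, planted)
    tss <- sum((y - mean(y))^2)
    planted$realized_contribution_pct <- vapply(terms, function(t) {
      100 * sum((t - mean(t))^2) / tss
    }, numeric(1))
  } else {
    planted <- data.frame(snp_i = character(0), snp_j = character(0),
                          effect_type = character(0), effect_size = numeric(0),
                          realized_contribution_pct = numeric(0),
                          stringsAsFactors = FALSE)
  }
  attr(out, "planted") <- planted
  out
}

#' Effect size that plants a target contribution rate
#'
#' Given realized genotypes, solves for the effect size beta such that the
#' planted contrast product explains approximately `target_pct` percent of
#' the total phenotypic variance when the remaining variance (family +
#' residual + other effects) is `background_variance`:
#' `beta^2 v / (beta^2 v + background) = target`, with `v` the sample
#' variance of the contrast product.
#'
#' @param geno a [generate_genotypes()] result.
#' @param snp_i,snp_j SNP ids or column indices.
#' @param effect_type one of AA/AD/DA/DD.
#' @param target_pct target contribution in percent.
#' @param background_variance variance not attributable to this effect.
#' @return numeric effect size.
#' @export
effect_size_for_contribution <- function(geno, snp_i, snp_j, effect_type,
                                         target_pct, background_variance) {
  stopifnot(target_pct > 0, target_pct < 100, background_variance > 0)
  effect_type <- match.arg(effect_type, c("AA", "AD", "DA", "DD"))
  G <- geno$genotypes
  resolve <- function(s) if (is.character(s)) match(s, colnames(G)) else as.integer(s)
  i <- resolve(snp_i); j <- resolve(snp_j)
  u1 <- planted_code(G[, i], if (substr(effect_type, 1, 1) == "A") "a" else "d")
  u2 <- planted_code(G[, j], if (substr(effect_type, 2, 2) == "A") "a" else "d")
  if (is.null(u1) || is.null(u2)) stop("required contrast undefined at a planted locus")
  v <- stats::var(u1 * u2)
  if (v <= 0) stop("contrast product has zero variance")
  f <- target_pct / 100
  sqrt(f / (1 - f) * background_variance / v)
}
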