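#' Frequency-orthogonal additive and dominance codings for one locus
#'
#' Computes the contrast codings that carry the Kempthorne-style partition of
#' genotypic effects at a biallelic locus.  The additive code is the
#' minor-allele count centred by its observed mean; the dominance code is the
#' heterozygosity indicator orthogonalised (Gram-Schmidt) against the constant
#' and additive columns under the *observed* genotype frequencies, so the
#' partition stays valid under Hardy-Weinberg disequilibrium.  With only two
#' genotype classes observed the dominance contrast is confounded with the
#' additive one and is returned as `NULL`.
#'
#' @param g integer vector of genotype codes 0/1/2 (minor-allele counts),
#'   no missing values.
#' @return list with elements `a` (additive code), `d` (dominance code or
#'   `NULL`), and `n_classes` (number of genotype classes observed).
#' @examples
#' genotype_codes(c(0, 0, 1, 1, 2, 2))
#' @export
genotype_codes <- function(g) {
  g <- as.integer(g)
  if (anyNA(g) || !all(g %in% 0:2)) {
    stop("genotype codes must be 0, 1 or 2 with no missing values")
  }
  n_classes <- length(unique(g))
  a <- g - mean(g)
  if (n_classes < 3L) {
    return(list(a = a, d = NULL, n_classes = n_classes))
  }
  h <- as.numeric(g == 1L)
  d <- h - mean(h)
  d <- d - sum(d * a) / sum(a * a) * a
  list(a = a, d = d, n_classes = n_classes)
}

#' Build the two-locus design for one SNP pair
#'
#' Restricts to individuals with complete genotypes at both loci, computes
#' per-locus additive/dominance codings via [genotype_codes()], and forms the
#' four interaction columns `a1*a2`, `a1*d2`, `d1*a2`, `d1*d2` (the AA, AD,
#' DA, DD one-degree-of-freedom epistatic contrasts).  Effects whose contrast
#' requires an undefined dominance code are flagged untestable rather than
#' imputed.
#'
#' @param g1,g2 genotype code vectors (0/1/2/`NA`) for the two loci, same
#'   length.
#' @param family optional factor (or coercible) of family labels, same length.
#' @param keep optional logical vector of additional individuals to retain
#'   (e.g. non-missing phenotype); combined with genotype completeness.
#' @return an object of class `pair_design`: complete-case indices, family
#'   factor, codes `a1,d1,a2,d2`, interaction column matrix `ia` (subset of
#'   columns AA/AD/DA/DD), and `untestable`, a named character vector of
#'   reasons for effects that cannot be estimated.
#' @seealso [test_pair()]
#' @export
build_pair_design <- function(g1, g2, family = NULL, keep = NULL) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (!is.null(keep)) ok <- ok & keep
  idx <- which(ok)
  if (length(idx) < 3L) {
    stop_skip("fewer than 3 complete observations for the pair")
  }
  c1 <- genotype_codes(g1[idx])
  c2 <- genotype_codes(g2[idx])
  if (c1$n_classes < 2L) stop_skip("locus 1 has fewer than 2 genotype classes")
  if (c2$n_classes < 2L) stop_skip("locus 2 has fewer than 2 genotype classes")

  ia <- list(AA = c1$a * c2$a)
  untestable <- character(0)
  if (!is.null(c2$d)) {
    ia$AD <- c1$a * c2$d
  } else {
    untestable["AD"] <- "dominance undefined at locus 2 (<3 genotype classes)"
  }
  if (!is.null(c1$d)) {
    ia$DA <- c1$d * c2$a
  } else {
    untestable["DA"] <- "dominance undefined at locus 1 (<3 genotype classes)"
  }
  if (!is.null(c1$d) && !is.null(c2$d)) {
    ia$DD <- c1$d * c2$d
  } else {
    untestable["DD"] <- "dominance undefined at one or both loci"
  }
  fam <- if (is.null(family)) NULL else factor(family[idx])
  structure(
    list(
      keep = idx, n = length(idx), family = fam,
      a1 = c1$a, d1 = c1$d, a2 = c2$a, d2 = c2$d,
      ia = do.call(cbind, ia),
      n_classes = c(locus1 = c1$n_classes, locus2 = c2$n_classes),
      untestable = untestable
    ),
    class = "pair_design"
  )
}

# condition used to flag pairs that cannot be tested; run_scan() catches it
stop_skip <- function(msg) {
  cond <- structure(
    class = c("epi_skip", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

# least-squares residual sum of squares via pivoted QR; returns rank too
.rss <- function(X, y) {
  qx <- qr(X)
  r <- qx$rank
  res <- qr.resid(qx, y)
  list(rss = sum(res^2), rank = r, qr = qx)
}

#' Test the two-locus interaction for one SNP pair
#'
#' Fits the model `y = mu + family + SNP1 + SNP2 + SNP1 x SNP2 + e` on the
#' pair's complete cases.  The overall interaction test is the
#' model-comparison F between the full model (additive + dominance codes at
#' both loci plus the estimable interaction columns) and the main-effects
#' model; each per-effect test is the one-degree-of-freedom F on that
#' interaction column's marginal sum of squares in the full model.
#' Contribution rates express each effect's sum of squares as a percentage of
#' the total corrected sum of squares of the phenotype.
#'
#' The family effect is absorbed as fixed covariates by default.  With
#' `family_mode = "random"` a one-way random intercept is fitted by REML
#' (via \pkg{lme4}) and the same contrasts are tested on the family-adjusted
#' phenotype.
#'
#' @param design a [build_pair_design()] result.
#' @param y numeric phenotype vector for *all* individuals (subset internally
#'   by the design's complete-case indices) or, if its length equals
#'   `design$n`, taken as already subset.
#' @param family_mode `"fixed"` (default) or `"random"`.
#' @return object of class `pair_epistasis`: `n_used`, `overall` (list with
#'   `F`, `df1`, `df2`, `p`), per-effect table `effects` (data.frame with
#'   `effect`, `ss`, `F`, `p`, `c_pct`, `testable`), `tss`, and `untestable`
#'   reasons.
#' @export
test_pair <- function(design, y, family_mode = c("fixed", "random")) {
  family_mode <- match.arg(family_mode)
  stopifnot(inherits(design, "pair_design"))
  if (length(y) == design$n) {
    yy <- as.numeric(y)
  } else {
    yy <- as.numeric(y)[design$keep]
  }
  if (anyNA(yy)) stop_skip("missing phenotype among the pair's complete cases")

  fam <- design$family
  if (family_mode == "random" && !is.null(fam) && nlevels(fam) > 1L) {
    fit <- lme4::lmer(yy ~ 1 + (1 | fam), REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    yy <- yy - as.numeric(predict(fit, re.form = NULL) - predict(fit, re.form = NA))
    famX <- NULL
  } else if (!is.null(fam) && nlevels(fam) > 1L) {
    famX <- stats::model.matrix(~fam)[, -1, drop = FALSE]
  } else {
    famX <- NULL
  }

  main <- cbind(`(Intercept)` = 1, famX, a1 = design$a1, a2 = design$a2)
  if (!is.null(design$d1)) main <- cbind(main, d1 = design$d1)
  if (!is.null(design$d2)) main <- cbind(main, d2 = design$d2)
  full <- cbind(main, design$ia)

  f_full <- .rss(full, yy)
  f_main <- .rss(main, yy)
  # drop aliased interaction columns from the working design: with an
  # unobserved genotype cell the four columns span fewer than 4 dimensions,
  # and a redundant column left in place would absorb the marginal SS of the
  # one being tested
  p_main0 <- ncol(main)
  pivot_used0 <- f_full$qr$pivot[seq_len(f_full$rank)]
  aliased <- which(!((p_main0 + seq_len(ncol(design$ia))) %in% pivot_used0))
  if (length(aliased)) {
    design$untestable[colnames(design$ia)[aliased]] <-
      "interaction column aliased in the full design"
    design$ia <- design$ia[, -aliased, drop = FALSE]
    full <- cbind(main, design$ia)
    f_full <- .rss(full, yy)
  }
  df2 <- design$n - f_full$rank
  if (df2 < 1L) stop_skip("no residual degrees of freedom in the full model")
  tss <- sum((yy - mean(yy))^2)
  if (tss <= 0) stop_skip("phenotype has zero variance among complete cases")

  df1 <- f_full$rank - f_main$rank
  ss_int <- max(f_main$rss - f_full$rss, 0)
  mse <- f_full$rss / df2
  overall <- ftest(ss_int, df1, mse, df2, tss)

  # columns of the interaction block actually estimable (not aliased)
  p_main <- ncol(main)
  pivot_used <- f_full$qr$pivot[seq_len(f_full$rank)]
  ia_names <- colnames(design$ia)
  est <- vapply(seq_along(ia_names), function(j) (p_main + j) %in% pivot_used,
                logical(1))
  names(est) <- ia_names

  all_types <- c("AA", "AD", "DA", "DD")
  eff <- data.frame(
    effect = all_types, ss = NA_real_, F = NA_real_, p = NA_real_,
    c_pct = NA_real_, testable = FALSE, stringsAsFactors = FALSE
  )
  untest <- design$untestable
  for (k in seq_along(all_types)) {
    type <- all_types[k]
    if (!type %in% ia_names) next
    if (!est[type]) {
      untest[type] <- "interaction column aliased in the full design"
      next
    }
    drop_col <- which(colnames(full) == type)
    f_red <- .rss(full[, -drop_col, drop = FALSE], yy)
    ss_k <- max(f_red$rss - f_full$rss, 0)
    t_k <- ftest(ss_k, 1L, mse, df2, tss)
    eff$ss[k] <- t_k$ss
    eff$F[k] <- t_k$F
    eff$p[k] <- t_k$p
    eff$c_pct[k] <- 100 * t_k$ss / tss
    eff$testable[k] <- TRUE
  }

  structure(
    list(
      n_used = design$n,
      overall = overall,
      effects = eff,
      tss = tss,
      untestable = untest,
      family_mode = family_mode
    ),
    class = "pair_epistasis"
  )
}

# F statistic with a numerically-sane zero-SS convention: an interaction sum
# of squares indistinguishable from rounding noise gives F = 0, P = 1 (the
# noise-free purely additive surface must report P = 1, not NaN).
ftest <- function(ss, df1, mse, df2, tss) {
  tol <- 1e-12 * max(tss, 1)
  if (df1 < 1L) return(list(ss = 0, df1 = df1, df2 = df2, F = NA_real_, p = NA_real_))
  if (ss <= tol) return(list(ss = 0, df1 = df1, df2 = df2, F = 0, p = 1))
  if (mse <= tol / max(df2, 1)) {
    return(list(ss = ss, df1 = df1, df2 = df2, F = Inf, p = 0))
  }
  Fv <- (ss / df1) / mse
  list(ss = ss, df1 = df1, df2 = df2, F = Fv,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' @export
print.pair_epistasis <- function(x, ...) {
  cat(sprintf("Two-locus interaction test (n = %d, family mode: %s)\n",
              x$n_used, x$family_mode))
  cat(sprintf("  overall: F(%d, %d) = %.4g, P = %.3g\n",
              x$overall$df1, x$overall$df2, x$overall$F, x$overall$p))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Bonferroni correction for an exhaustive pairwise scan
#'
#' The number of tests is `tests_per_pair * n_snps * (n_snps - 1) / 2` (four
#' per pair when each of the AA/AD/DA/DD effects is thresholded separately);
#' the familywise threshold is `alpha` divided by that count.
#'
#' @param n_snps number of markers entering the scan (>= 2).
#' @param alpha familywise significance level.
#' @param tests_per_pair tests per SNP pair (default 4, one per epistatic
#'   effect type).
#' @return list with `n_tests` and `threshold`.
#' @examples
#' bonferroni_pairs(45611)  # ~4.16e9 tests, threshold ~1.2e-11
#' @export
bonferroni_pairs <- function(n_snps, alpha = 0.05, tests_per_pair = 4) {
  stopifnot(n_snps >= 2, alpha > 0, alpha < 1, tests_per_pair >= 1)
  n_tests <- tests_per_pair * n_snps * (n_snps - 1) / 2
  list(n_tests = n_tests, threshold = alpha / n_tests)
}

#' Contribution rate of a one-degree-of-freedom effect
#'
#' Expresses an effect's sum of squares as a percentage of the total
#' corrected sum of squares of the phenotype, i.e. the percent of phenotypic
#' variation explained by that effect.
#'
#' @param effect_ss non-negative sum of squares of the effect.
#' @param y phenotype vector (>= 2 values, non-zero variance).
#' @return percentage in `[0, 100]` (can exceed 100 only for an SS larger
#'   than the phenotypic SS, which a nested model cannot produce).
#' @export
contribution_rate <- function(effect_ss, y) {
  stopifnot(effect_ss >= 0, length(y) >= 2)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) stop("phenotype variance is zero; contribution rate undefined")
  100 * effect_ss / tss
}

#' Exhaustive pairwise epistasis scan
#'
#' Runs [test_pair()] over all SNP pairs (optionally restricted), keeps every
#' effect with `P < threshold` (strict), and returns one record per
#' significant effect in deterministic order (chrom1, pos1, chrom2, pos2,
#' effect type).  Each pair is canonicalised so that locus 1 precedes locus 2
#' in genome order; the AD/DA labels swap consistently with the loci.
#' Skipped pairs are logged, never aborted on.
#'
#' @param genotypes individuals x SNPs matrix of codes 0/1/2/`NA` with column
#'   names, or a list with elements `genotypes` and `map`.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (one row per
#'   genotype column); taken from `genotypes$map` when a list is given.
#' @param phenotype numeric vector, one value per individual (`NA` allowed).
#' @param families optional family labels per individual.
#' @param threshold significance threshold on per-effect P-values; defaults
#'   to [bonferroni_pairs()] at `alpha` over the scanned panel.
#' @param alpha,tests_per_pair passed to [bonferroni_pairs()] when
#'   `threshold` is `NULL`.
#' @param family_mode passed to [test_pair()].
#' @param pairs optional 2-column matrix of SNP column indices to test
#'   instead of all pairs.
#' @param max_pairs optional cap on the number of pairs tested (first
#'   `max_pairs` in column order), for desk-scale restriction.
#' @param all_results if `TRUE`, also return the per-pair overall test for
#'   every tested pair (memory permitting).
#' @return object of class `epi_scan`: `significant` (data.frame in the
#'   significant-pair table schema: chrom1, snp1, pos1, chrom2, snp2, pos2,
#'   effect_type, n_used, F, p_value, c_pct), `skipped` (data.frame of pair,
#'   reason), `n_pairs_tested`, `n_snps`, `threshold`, and optionally
#'   `overall`.
#' @export
run_scan <- function(genotypes, map = NULL, phenotype, families = NULL,
                     threshold = NULL, alpha = 0.05, tests_per_pair = 4,
                     family_mode = c("fixed", "random"),
                     pairs = NULL, max_pairs = Inf, all_results = FALSE) {
  family_mode <- match.arg(family_mode)
  if (is.list(genotypes) && !is.matrix(genotypes)) {
    if (is.null(map)) map <- genotypes$map
    genotypes <- genotypes$genotypes
  }
  if (is.null(genotypes) || ncol(genotypes) < 2L || nrow(genotypes) < 1L) {
    stop("need a genotype matrix with at least 2 SNPs and 1 individual")
  }
  if (is.null(map)) {
    map <- data.frame(snp = colnames(genotypes),
                      chrom = "1", pos = seq_len(ncol(genotypes)))
  }
  stopifnot(nrow(map) == ncol(genotypes))
  m <- ncol(genotypes)
  if (is.null(threshold)) {
    threshold <- bonferroni_pairs(m, alpha, tests_per_pair)$threshold
  }
  keep_y <- !is.na(phenotype)

  if (is.null(pairs)) {
    pairs <- t(utils::combn(m, 2L))
  }
  if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), , drop = FALSE]

  sig <- vector("list", 64L)
  n_sig <- 0L
  skipped <- list()
  overall <- if (all_results) vector("list", nrow(pairs)) else NULL

  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    res <- tryCatch(
      {
        des <- build_pair_design(genotypes[, i], genotypes[, j],
                                 family = families, keep = keep_y)
        test_pair(des, phenotype[des$keep], family_mode = family_mode)
      },
      epi_skip = function(e) e
    )
    if (inherits(res, "epi_skip")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        snp1 = map$snp[i], snp2 = map$snp[j],
        reason = conditionMessage(res), stringsAsFactors = FALSE
      )
      next
    }
    if (all_results) {
      overall[[r]] <- data.frame(
        snp1 = map$snp[i], snp2 = map$snp[j], n_used = res$n_used,
        F = res$overall$F, p_value = res$overall$p, stringsAsFactors = FALSE
      )
    }
    hits <- res$effects[res$effects$testable & !is.na(res$effects$p) &
                          res$effects$p < threshold, , drop = FALSE]
    if (nrow(hits) == 0L) next
    # canonical locus order: locus 1 first in genome order
    swap <- genome_after(map$chrom[i], map$pos[i], map$chrom[j], map$pos[j])
    ii <- if (swap) j else i
    jj <- if (swap) i else j
    type <- hits$effect
    if (swap) type <- chartr_effect(type)
    n_sig <- n_sig + 1L
    if (n_sig > length(sig)) sig <- c(sig, vector("list", length(sig)))
    sig[[n_sig]] <- data.frame(
      chrom1 = as.character(map$chrom[ii]), snp1 = map$snp[ii], pos1 = map$pos[ii],
      chrom2 = as.character(map$chrom[jj]), snp2 = map$snp[jj], pos2 = map$pos[jj],
      effect_type = type, n_used = res$n_used,
      F = hits$F, p_value = hits$p, c_pct = hits$c_pct,
      stringsAsFactors = FALSE
    )
  }

  sig <- sig[seq_len(n_sig)]
  sig <- if (n_sig > 0L) do.call(rbind, sig) else data.frame(
    chrom1 = character(0), snp1 = character(0), pos1 = numeric(0),
    chrom2 = character(0), snp2 = character(0), pos2 = numeric(0),
    effect_type = character(0), n_used = integer(0),
    F = numeric(0), p_value = numeric(0), c_pct = numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(sig) > 0L) {
    o <- order(chrom_rank(sig$chrom1), sig$pos1,
               chrom_rank(sig$chrom2), sig$pos2,
               match(sig$effect_type, c("AA", "AD", "DA", "DD")))
    sig <- sig[o, , drop = FALSE]
    rownames(sig) <- NULL
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(snp1 = character(0), snp2 = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  structure(
    list(
      significant = sig, skipped = skipped,
      n_pairs_tested = nrow(pairs) - nrow(skipped),
      n_snps = m, threshold = threshold,
      overall = if (all_results) do.call(rbind, overall) else NULL
    ),
    class = "epi_scan"
  )
}

# swap AD <-> DA when the loci of a pair are exchanged
chartr_effect <- function(type) {
  out <- type
  out[type == "AD"] <- "DA"
  out[type == "DA"] <- "AD"
  out
}

# is locus (c1, p1) after locus (c2, p2) in genome order?
genome_after <- function(c1, p1, c2, p2) {
  r1 <- chrom_rank(c1); r2 <- chrom_rank(c2)
  r1 > r2 || (r1 == r2 && p1 > p2)
}

#' @export
print.epi_scan <- function(x, ...) {
  cat(sprintf(
    "Pairwise epistasis scan: %d SNPs, %d pairs tested, threshold P < %.3g\n",
    x$n_snps, x$n_pairs_tested, x$threshold))
  cat(sprintf("  %d significant effect records, %d pairs skipped\n",
              nrow(x$significant), nrow(x$skipped)))
  invisible(x)
}

#' Single-locus association scan
#'
#' One-locus counterpart of the pairwise model (`y = mu + family + SNP + e`,
#' no interaction): per SNP the genotypic F-test (additive + dominance
#' degrees of freedom against the family-only model) and the contribution
#' rate of the genotypic sum of squares.
#'
#' @inheritParams run_scan
#' @return data.frame with one row per testable SNP: `snp`, `chrom`, `pos`,
#'   `n_used`, `df1`, `F`, `p_value`, `c_pct`; skipped SNPs (monomorphic or
#'   degenerate) are listed in the `skipped` attribute.
#' @export
single_locus_scan <- function(genotypes, map = NULL, phenotype,
                              families = NULL,
                              family_mode = c("fixed", "random")) {
  family_mode <- match.arg(family_mode)
  if (is.list(genotypes) && !is.matrix(genotypes)) {
    if (is.null(map)) map <- genotypes$map
    genotypes <- genotypes$genotypes
  }
  if (is.null(map)) {
    map <- data.frame(snp = colnames(genotypes),
                      chrom = "1", pos = seq_len(ncol(genotypes)))
  }
  keep_y <- !is.na(phenotype)
  out <- vector("list", ncol(genotypes))
  skipped <- list()
  for (k in seq_len(ncol(genotypes))) {
    g <- genotypes[, k]
    ok <- !is.na(g) & keep_y
    idx <- which(ok)
    if (length(idx) < 3L || length(unique(g[idx])) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        snp = map$snp[k], reason = "monomorphic or too few complete cases",
        stringsAsFactors = FALSE)
      next
    }
    cod <- genotype_codes(g[idx])
    yy <- as.numeric(phenotype[idx])
    fam <- if (is.null(families)) NULL else factor(families[idx])
    if (family_mode == "random" && !is.null(fam) && nlevels(fam) > 1L) {
      fit <- lme4::lmer(yy ~ 1 + (1 | fam), REML = TRUE,
                        control = lme4::lmerControl(calc.derivs = FALSE))
      yy <- yy - as.numeric(predict(fit, re.form = NULL) - predict(fit, re.form = NA))
      base <- cbind(`(Intercept)` = rep(1, length(idx)))
    } else if (!is.null(fam) && nlevels(fam) > 1L) {
      base <- cbind(1, stats::model.matrix(~fam)[, -1, drop = FALSE])
    } else {
      base <- cbind(`(Intercept)` = rep(1, length(idx)))
    }
    fullX <- cbind(base, a = cod$a)
    if (!is.null(cod$d)) fullX <- cbind(fullX, d = cod$d)
    f_full <- .rss(fullX, yy)
    f_base <- .rss(base, yy)
    df2 <- length(idx) - f_full$rank
    if (df2 < 1L) next
    tss <- sum((yy - mean(yy))^2)
    tst <- ftest(max(f_base$rss - f_full$rss, 0), f_full$rank - f_base$rank,
                 f_full$rss / df2, df2, tss)
    out[[k]] <- data.frame(
      snp = map$snp[k], chrom = as.character(map$chrom[k]), pos = map$pos[k],
      n_used = length(idx), df1 = tst$df1, F = tst$F, p_value = tst$p,
      c_pct = 100 * tst$ss / tss, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- data.frame(
    snp = character(0), chrom = character(0), pos = numeric(0),
    n_used = integer(0), df1 = integer(0), F = numeric(0),
    p_value = numeric(0), c_pct = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  res
}
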