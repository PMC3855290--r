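# Shared helpers: small genotype builders and independent brute-force
# oracles used across test files.

# genotype matrix with given per-SNP MAFs (HWE), no missingness
make_geno <- function(n, mafs, seed = 1) {
  set.seed(seed)
  g <- vapply(mafs, function(q) {
    sample(0:2, n, replace = TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }, integer(n))
  colnames(g) <- sprintf("s%03d", seq_along(mafs))
  rownames(g) <- sprintf("i%03d", seq_len(n))
  g
}

# resample one locus until all three genotype classes are present
polymorphic_locus <- function(n, q) {
  repeat {
    g <- sample(0:2, n, replace = TRUE,
                prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    if (length(unique(g)) == 3L) return(g)
  }
}

# a pair of loci with every one of the 9 two-locus cells occupied
pair_with_full_cells <- function(n, q1, q2) {
  repeat {
    g1 <- polymorphic_locus(n, q1)
    g2 <- polymorphic_locus(n, q2)
    if (all(table(g1, g2) > 0)) return(list(g1 = g1, g2 = g2))
  }
}

# brute-force interval union: quadratic sweep, merging overlap or touching
brute_merge <- function(starts, ends) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  rs <- starts[1]; re <- ends[1]
  out <- list()
  for (k in seq_along(starts)[-1]) {
    if (starts[k] <= re + 1) {
      re <- max(re, ends[k])
    } else {
      out[[length(out) + 1L]] <- c(rs, re)
      rs <- starts[k]; re <- ends[k]
    }
  }
  out[[length(out) + 1L]] <- c(rs, re)
  do.call(rbind, out)
}

# brute-force point-in-interval hits (inclusive ends), double loop
brute_hits <- function(pts_chrom, pts_pos, iv_chrom, iv_start, iv_end) {
  hits <- NULL
  for (i in seq_along(pts_pos)) {
    for (j in seq_along(iv_start)) {
      if (pts_chrom[i] == iv_chrom[j] &&
          pts_pos[i] >= iv_start[j] && pts_pos[i] <= iv_end[j]) {
        hits <- rbind(hits, c(i, j))
      }
    }
  }
  hits
}

# lm()-based model-comparison oracle for the overall two-locus interaction:
# full genotype-class crossing vs main effects, family as fixed covariates
lm_overall_oracle <- function(g1, g2, fam, y) {
  d <- data.frame(y = y, g1 = factor(g1), g2 = factor(g2))
  fml_full <- if (is.null(fam)) y ~ g1 * g2 else y ~ fam + g1 * g2
  fml_main <- if (is.null(fam)) y ~ g1 + g2 else y ~ fam + g1 + g2
  if (!is.null(fam)) d$fam <- factor(fam)
  a <- stats::anova(stats::lm(fml_main, d), stats::lm(fml_full, d))
  list(F = a$F[2], p = a$`Pr(>F)`[2], df1 = a$Df[2])
}
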