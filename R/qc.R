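#' Marker quality control: MAF floor and monomorphic loci
#'
#' Removes markers whose minor allele frequency (computed on non-missing
#' calls) is below `maf_floor`, and monomorphic markers (fewer than two
#' observed genotype classes).  The floor is inclusive on the retained side:
#' "MAF less than the floor" is removed, so a marker at exactly the floor is
#' kept.  The filter runs markers-first in the standard pipeline order
#' (markers, then individuals); it is idempotent.
#'
#' @param geno list with `genotypes` (individuals x SNPs, codes 0/1/2/`NA`)
#'   and optionally `map`, or a bare genotype matrix.
#' @param maf_floor minimum retained MAF (default 0.05).
#' @return list with the filtered `genotypes` (and `map`), plus `report`, a
#'   `qc_report` of the removal counts.
#' @export
filter_markers <- function(geno, maf_floor = 0.05) {
  g <- if (is.matrix(geno)) geno else geno$genotypes
  map <- if (is.matrix(geno)) NULL else geno$map
  stopifnot(maf_floor >= 0, maf_floor <= 0.5)
  m <- ncol(g)
  stats <- marker_stats(g)
  mono <- stats$n_classes < 2L
  low <- !mono & stats$maf < maf_floor
  keep <- !mono & !low
  if (!any(keep)) {
    stop("all markers removed by QC (MAF floor ", maf_floor, ")")
  }
  out <- list(
    genotypes = g[, keep, drop = FALSE],
    map = if (is.null(map)) NULL else map[keep, , drop = FALSE],
    report = qc_report(
      n_snps_in = m,
      n_snps_removed_maf = sum(low),
      n_snps_removed_monomorphic = sum(mono),
      n_individuals_removed_missing = 0L,
      n_snps_out = sum(keep),
      n_individuals_out = nrow(g)
    )
  )
  if (!is.null(out$map)) rownames(out$map) <- NULL
  out
}

# per-marker MAF on non-missing calls plus observed genotype-class count
marker_stats <- function(g) {
  nobs <- colSums(!is.na(g))
  freq <- colSums(g, na.rm = TRUE) / (2 * pmax(nobs, 1L))
  maf <- pmin(freq, 1 - freq)
  n_classes <- apply(g, 2, function(x) length(unique(x[!is.na(x)])))
  maf[nobs == 0] <- 0
  n_classes[nobs == 0] <- 0L
  data.frame(maf = maf, n_classes = n_classes, n_obs = nobs)
}

#' Individual quality control: missing-genotype rate
#'
#' Removes individuals whose fraction of missing genotype calls is
#' `max_missing` or more (the boundary individual at exactly the threshold
#' is removed).
#'
#' @inheritParams filter_markers
#' @param max_missing removal threshold on the missing fraction
#'   (default 0.05).
#' @return as [filter_markers()].
#' @export
filter_individuals <- function(geno, max_missing = 0.05) {
  g <- if (is.matrix(geno)) geno else geno$genotypes
  map <- if (is.matrix(geno)) NULL else geno$map
  stopifnot(max_missing > 0, max_missing <= 1)
  miss <- rowMeans(is.na(g))
  keep <- miss < max_missing
  if (!any(keep)) stop("all individuals removed by QC (missingness >= ",
                       max_missing, ")")
  list(
    genotypes = g[keep, , drop = FALSE],
    map = map,
    report = qc_report(
      n_snps_in = ncol(g),
      n_snps_removed_maf = 0L,
      n_snps_removed_monomorphic = 0L,
      n_individuals_removed_missing = sum(!keep),
      n_snps_out = ncol(g),
      n_individuals_out = sum(keep)
    )
  )
}

qc_report <- function(n_snps_in, n_snps_removed_maf,
                      n_snps_removed_monomorphic,
                      n_individuals_removed_missing,
                      n_snps_out, n_individuals_out) {
  rep <- list(
    n_snps_in = as.integer(n_snps_in),
    n_snps_removed_maf = as.integer(n_snps_removed_maf),
    n_snps_removed_monomorphic = as.integer(n_snps_removed_monomorphic),
    n_individuals_removed_missing = as.integer(n_individuals_removed_missing),
    n_snps_out = as.integer(n_snps_out),
    n_individuals_out = as.integer(n_individuals_out)
  )
  stopifnot(
    rep$n_snps_out == rep$n_snps_in - rep$n_snps_removed_maf -
      rep$n_snps_removed_monomorphic,
    all(unlist(rep) >= 0)
  )
  structure(rep, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker/individual QC report\n")
  cat(sprintf("  markers in:                 %d\n", x$n_snps_in))
  cat(sprintf("  removed, MAF below floor:   %d\n", x$n_snps_removed_maf))
  cat(sprintf("  removed, monomorphic:       %d\n", x$n_snps_removed_monomorphic))
  cat(sprintf("  individuals removed:        %d\n", x$n_individuals_removed_missing))
  cat(sprintf("  markers out:                %d\n", x$n_snps_out))
  cat(sprintf("  individuals out:            %d\n", x$n_individuals_out))
  invisible(x)
}

#' Write a QC report as plain text and YAML
#'
#' @param report a `qc_report`.
#' @param path output path; a `.yaml` sidecar with the raw counts is written
#'   next to it.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  con <- file(path, open = "wt")
  sink(con); on.exit({ sink(); close(con) })
  print(report)
  sink(); close(con); on.exit()
  yaml::write_yaml(unclass(report), paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' Composite linkage disequilibrium r-squared between two markers
#'
#' Squared Pearson correlation of genotype codes over complete cases
#' (the composite-LD convention; no phase is inferred).  Used to motivate the
#' 0.2 Mb annotation window.
#'
#' @param snp_a,snp_b genotype code vectors (0/1/2/`NA`) of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(snp_a, snp_b) {
  stopifnot(length(snp_a) == length(snp_b))
  ok <- !is.na(snp_a) & !is.na(snp_b)
  if (sum(ok) < 2L) stop("need at least 2 complete observations")
  a <- snp_a[ok]; b <- snp_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("r2 undefined: a locus is monomorphic among complete cases")
  }
  stats::cor(a, b)^2
}
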