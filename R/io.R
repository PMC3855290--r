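#' Read genotypes from a plain matrix, PLINK-style ped/map, or VCF
#'
#' All readers return minor-allele-count codes computed per site: whichever
#' allele is rarer among the observed calls is counted, so a site whose
#' counted/ALT allele turns out to be the major one is flipped (ties are left
#' as counted).  This makes the three formats interchangeable.
#'
#' @param path file path: a tab-separated matrix (individuals x SNPs, header
#'   of SNP ids, first column individual id), a ped/map prefix or `.ped`
#'   path, or a `.vcf` file.
#' @param format `"matrix"`, `"ped"` or `"vcf"`; guessed from the extension
#'   when missing.
#' @return list with `genotypes` (integer matrix, codes 0/1/2/`NA`) and
#'   `map` (data.frame `snp`, `chrom`, `pos`).
#' @export
read_genotypes <- function(path, format = c("guess", "matrix", "ped", "vcf")) {
  format <- match.arg(format)
  if (format == "guess") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vcf = "vcf", ped = "ped", map = "ped", "matrix")
  }
  switch(format,
         matrix = read_genotype_matrix(path),
         ped = read_ped(path),
         vcf = read_vcf(path))
}

#' @rdname read_genotypes
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stop("no such genotype file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(g) <- "integer"
  rownames(g) <- as.character(tab[[1]])
  list(genotypes = g,
       map = data.frame(snp = colnames(g), chrom = "1",
                        pos = seq_len(ncol(g)), stringsAsFactors = FALSE))
}

#' Write genotypes as a plain tab-separated matrix
#'
#' @param geno list with `genotypes` (and optionally `map`), or a matrix.
#' @param path output path.
#' @export
write_genotype_matrix <- function(geno, path) {
  g <- if (is.matrix(geno)) geno else geno$genotypes
  df <- data.frame(id = rownames(g), g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote genotype matrix: ", path, " (", nrow(g), " x ", ncol(g), ")")
  invisible(path)
}

# flip codes so that the counted allele is the minor one per site
.minorize <- function(g) {
  freq <- colMeans(g, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  g[, flip] <- 2L - g[, flip]
  g
}

#' Write genotypes as PLINK-style ped/map files
#'
#' Alleles are written as `A` (major, code 0 homozygote) and `B` (minor);
#' missing calls as `0 0`.  The `.map` file carries chromosome, SNP id, a
#' zero genetic distance and the bp position.
#'
#' @param geno list with `genotypes` and `map`.
#' @param prefix output prefix; `.ped` and `.map` are appended.
#' @param phenotypes optional data.frame `id`, `family`, `y` used to fill
#'   the family and phenotype columns.
#' @export
write_ped <- function(geno, prefix, phenotypes = NULL) {
  g <- geno$genotypes
  map <- geno$map
  stopifnot(!is.null(map), nrow(map) == ncol(g))
  al <- function(code) {
    out <- matrix("0", nrow(g), 2)
    out[which(code == 0L), ] <- "A"
    out[which(code == 1L), 1] <- "A"; out[which(code == 1L), 2] <- "B"
    out[which(code == 2L), ] <- "B"
    out
  }
  allele_cols <- vector("list", ncol(g))
  for (j in seq_len(ncol(g))) allele_cols[[j]] <- al(g[, j])
  alleles <- do.call(cbind, allele_cols)
  ids <- rownames(g) %||% sprintf("ind%04d", seq_len(nrow(g)))
  fam <- rep("FAM0", nrow(g)); phe <- rep(-9, nrow(g))
  if (!is.null(phenotypes)) {
    i <- match(ids, phenotypes$id)
    fam <- ifelse(is.na(i), fam, paste0("FAM", phenotypes$family[i]))
    phe <- ifelse(is.na(i), phe, phenotypes$y[i])
  }
  ped <- cbind(fam, ids, 0, 0, 0, phe, alleles)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(map$chrom, map$snp, 0, map$pos),
    paste0(prefix, ".map"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  message("wrote ped/map: ", prefix, ".{ped,map}")
  invisible(prefix)
}

#' @rdname read_genotypes
#' @export
read_ped <- function(path) {
  prefix <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path)) stop("no such ped file: ", ped_path)
  if (!file.exists(map_path)) stop("no such map file: ", map_path)
  map <- utils::read.table(map_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  map <- data.frame(snp = as.character(map[[2]]), chrom = as.character(map[[1]]),
                    pos = as.numeric(map[[4]]), stringsAsFactors = FALSE)
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m) {
    stop(sprintf("ped/map mismatch: %d SNPs in map but %d allele columns in ped",
                 m, ncol(ped) - 6))
  }
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  g <- (a1 == "B") + (a2 == "B")
  g[a1 == "0" | a2 == "0"] <- NA
  storage.mode(g) <- "integer"
  dimnames(g) <- list(ped[[2]], map$snp)
  list(genotypes = .minorize(g), map = map)
}

#' Write genotypes as a minimal VCF
#'
#' One biallelic record per SNP (`REF = A` major allele, `ALT = B` minor),
#' unphased diploid `GT` calls, missing as `./.`.
#'
#' @inheritParams write_ped
#' @param path output `.vcf` path.
#' @export
write_vcf <- function(geno, path) {
  g <- geno$genotypes
  map <- geno$map
  stopifnot(!is.null(map), nrow(map) == ncol(g))
  gt <- matrix("./.", ncol(g), nrow(g))
  codes <- c("0/0", "0/1", "1/1")
  for (i in seq_len(nrow(g))) {
    known <- !is.na(g[i, ])
    gt[known, i] <- codes[g[i, known] + 1L]
  }
  ids <- rownames(g) %||% sprintf("ind%04d", seq_len(nrow(g)))
  body <- cbind(map$chrom, format(map$pos, scientific = FALSE, trim = TRUE),
                map$snp, "A", "B", ".", "PASS", ".", "GT", gt)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  message("wrote VCF: ", path)
  invisible(path)
}

#' @rdname read_genotypes
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "ALT"]) > 1 | fix[, "ALT"] == "*"
  if (any(multi)) {
    message(sum(multi), " non-biallelic VCF record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  # count ALT alleles regardless of phase separator
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  g <- matrix(NA_integer_, ncol(gt), nrow(gt))  # individuals x SNPs
  for (j in seq_len(nrow(gt))) g[, j] <- count_alt(gt[j, ])
  dimnames(g) <- list(colnames(gt), rownames(gt))
  map <- data.frame(snp = rownames(gt), chrom = as.character(fix[, "CHROM"]),
                    pos = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE)
  list(genotypes = .minorize(g), map = map)
}

#' Write a phenotype table
#'
#' Tab-separated `id`, `family`, `y` columns.
#'
#' @param phenotypes data.frame `id`, `family`, `y`.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.table(phenotypes[, c("id", "family", "y")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message("wrote phenotypes: ", path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such phenotype file: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Load a significant-pair table
#'
#' Parses the published table schema: first/second chromosome, SNP names,
#' epistatic effect type, P-value and contribution rate in percent.
#' P-values in plain scientific notation (`1.20e-11`) and in typeset form
#' (`1.20×10^−11`, including the typographic minus sign) parse identically;
#' contribution values may carry a `%` sign.
#'
#' @param path tab-separated file whose header contains (in order) the
#'   columns chrom1, snp1, chrom2, snp2, effect type, P, c.
#' @return data.frame `chrom1`, `snp1`, `chrom2`, `snp2`, `effect_type`,
#'   `p_value`, `c_pct`.
#' @export
load_pair_table <- function(path) {
  if (!file.exists(path)) stop("no such pair table: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(tab) < 7L) stop("pair table needs 7 columns, found ", ncol(tab))
  out <- data.frame(
    chrom1 = tab[[1]], snp1 = tab[[2]], chrom2 = tab[[3]], snp2 = tab[[4]],
    effect_type = toupper(trimws(tab[[5]])),
    p_value = parse_scientific(tab[[6]]),
    c_pct = suppressWarnings(as.numeric(sub("%$", "", trimws(tab[[7]])))),
    stringsAsFactors = FALSE
  )
  bad <- which(!out$effect_type %in% c("AA", "AD", "DA", "DD") |
                 is.na(out$p_value) | is.na(out$c_pct))
  if (length(bad)) {
    stop("unparseable pair-table row(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Parse numbers in plain or typeset scientific notation
#'
#' Accepts `"1.20e-11"`, `"1.20E-11"`, `"1.20×10^−11"` (typographic
#' multiplication and minus signs) and plain decimals.
#'
#' @param x character vector.
#' @return numeric vector (`NA` where unparseable).
#' @export
parse_scientific <- function(x) {
  x <- trimws(x)
  x <- gsub("−", "-", x)            # typographic minus
  x <- gsub("×\\s*10\\^?", "e", x)  # "×10^" -> "e"
  x <- gsub("\\^", "", gsub("[{}]", "", x))
  suppressWarnings(as.numeric(x))
}

#' The shipped 52-pair significant-interaction fixture
#'
#' The published table of genome-wide significant pairwise epistatic SNP
#' pairs for abdominal fat weight (52 rows: chromosomes, SNP ids, effect
#' type, P-value, contribution rate), shipped as a plain-text fixture for
#' the network and annotation stages.
#'
#' @return data.frame in the [load_pair_table()] schema.
#' @export
afw_pairs <- function() {
  load_pair_table(system.file("extdata", "afw_significant_pairs.tsv",
                              package = "epinetscan", mustWork = TRUE))
}

#' Reconstructed marker positions for the 52-pair fixture (synthetic)
#'
#' Positions of the 68 SNPs in the significant-pair fixture.  These are
#' *reconstructed*, not measured: exact where a published single-SNP
#' 0.4 Mb region pins the SNP at its centre, exact at the extreme SNPs of
#' each multi-SNP region (from the region's union endpoints), interpolated
#' for interior SNPs, and invented (within plausible chromosome lengths)
#' for SNPs absent from the region table.  Suitable for exercising the
#' window/merging geometry; not a genome annotation resource.
#'
#' @return data.frame `snp`, `chrom`, `pos`, `derivation`.
#' @export
afw_snp_map <- function() {
  p <- system.file("extdata", "afw_snp_positions_synthetic.tsv",
                   package = "epinetscan", mustWork = TRUE)
  utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
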