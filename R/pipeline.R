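#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (or a YAML file) naming the inputs
#' and settings of an end-to-end run.  Two modes exist: a full run
#' (genotypes + phenotypes, QC, scan, network, annotation) and a fixture
#' run (`pair_table` given: the scan is skipped and the network/annotation
#' stages run directly from a significant-pair table, decoupling the
#' deterministic downstream stages from the stochastic scan).
#'
#' Recognised fields: `genotypes`, `genotype_format`, `phenotypes`,
#' `pair_table`, `snp_positions`, `qtl_bed`, `gene_bed`,
#' `pathway_map`, `maf_floor`, `max_missing`, `alpha`, `tests_per_pair`,
#' `threshold`, `family_mode`, `max_pairs`, `min_subnet_nodes`,
#' `fragment_half_width`, `out_dir`, `seed`.
#'
#' @param config list or path to a YAML file.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    genotype_format = "guess", maf_floor = 0.05, max_missing = 0.05,
    alpha = 0.05, tests_per_pair = 4, threshold = NULL,
    family_mode = "fixed", max_pairs = Inf, min_subnet_nodes = 3,
    fragment_half_width = 200000, out_dir = "results", seed = 1
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  stopifnot(config$alpha > 0, config$alpha < 1)
  fixture_mode <- !is.null(config$pair_table)
  if (!fixture_mode && (is.null(config$genotypes) || is.null(config$phenotypes))) {
    stop("config needs either pair_table (fixture mode) or genotypes + phenotypes")
  }
  for (nm in c("genotypes", "phenotypes", "pair_table", "snp_positions",
               "qtl_bed", "gene_bed", "pathway_map")) {
    p <- config[[nm]]
    if (!is.null(p) && !file.exists(p) && !file.exists(paste0(p, ".ped"))) {
      stop("configured ", nm, " path does not exist: ", p)
    }
  }
  config$fixture_mode <- fixture_mode
  structure(config, class = c("run_config", "list"))
}

#' Run the full analysis pipeline
#'
#' QC -> pairwise scan -> Bonferroni threshold -> network -> subnet
#' importance -> annotation, writing each stage's artifacts under
#' `out_dir`: a QC report, the significant-pair table, viewer-ready network
#' exports, the subnet summary table, the region report and a run log.
#' In fixture mode ([run_config()]) the scan is skipped and the pair table
#' is loaded from disk.  Given a seed, result tables are byte-identical
#' across runs.
#'
#' @param config a [run_config()] (or list / YAML path coercible to one).
#' @return invisible list with the stage results (`qc`, `scan` or `pairs`,
#'   `network`, `subnets`, `subnet_table`, `regions`, `qtl_hits`,
#'   `pathways`, `paths`).
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat("", file = log_path)
  set.seed(config$seed)
  out <- list(paths = character(0))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  if (config$fixture_mode) {
    pairs <- stage("load_pairs", load_pair_table(config$pair_table))
    logf("fixture mode: loaded %d significant pair records from %s",
         nrow(pairs), config$pair_table)
  } else {
    geno <- stage("read_genotypes",
                  read_genotypes(config$genotypes, config$genotype_format))
    phen <- stage("read_phenotypes", read_phenotypes(config$phenotypes))
    logf("inputs: %d individuals x %d SNPs, %d phenotype rows",
         nrow(geno$genotypes), ncol(geno$genotypes), nrow(phen))

    qm <- stage("qc_markers", filter_markers(geno, config$maf_floor))
    qi <- stage("qc_individuals", filter_individuals(qm, config$max_missing))
    logf("QC: %d -> %d markers (MAF %d, monomorphic %d removed); %d -> %d individuals",
         qm$report$n_snps_in, qm$report$n_snps_out,
         qm$report$n_snps_removed_maf, qm$report$n_snps_removed_monomorphic,
         qm$report$n_individuals_out, qi$report$n_individuals_out)
    qc_path <- file.path(config$out_dir, "qc_report.txt")
    write_qc_report(qi$report, qc_path)
    out$qc <- qi$report
    out$paths["qc"] <- qc_path

    ids <- rownames(qi$genotypes)
    phen <- phen[match(ids, phen$id), , drop = FALSE]
    thr <- config$threshold
    if (is.null(thr)) {
      bf <- bonferroni_pairs(ncol(qi$genotypes), config$alpha,
                             config$tests_per_pair)
      thr <- bf$threshold
      logf("Bonferroni: %d SNPs -> %.4g tests, threshold P < %.4g",
           ncol(qi$genotypes), bf$n_tests, thr)
    }
    scan <- stage("scan", run_scan(
      qi$genotypes, qi$map, phen$y, phen$family, threshold = thr,
      family_mode = config$family_mode, max_pairs = config$max_pairs))
    logf("scan: %d pairs tested, %d skipped, %d significant effect records",
         scan$n_pairs_tested, nrow(scan$skipped), nrow(scan$significant))
    if (nrow(scan$skipped)) {
      for (r in seq_len(nrow(scan$skipped))) {
        logf("  skipped pair (%s, %s): %s", scan$skipped$snp1[r],
             scan$skipped$snp2[r], scan$skipped$reason[r])
      }
    }
    out$scan <- scan
    pairs <- scan$significant
    sig_path <- file.path(config$out_dir, "significant_pairs.tsv")
    utils::write.table(pairs, sig_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths["significant_pairs"] <- sig_path
  }
  out$pairs <- pairs

  net <- stage("network", build_network(pairs))
  subnets <- stage("subnets", extract_subnets(net, config$min_subnet_nodes))
  st <- subnet_table(subnets)
  logf("network: %d nodes, %d edges, %d subnets with >= %d nodes",
       nrow(net$nodes), nrow(net$edges), length(subnets),
       config$min_subnet_nodes)
  out$network <- net
  out$subnets <- subnets
  out$subnet_table <- st
  exp_paths <- export_network(net, config$out_dir)
  st_path <- file.path(config$out_dir, "subnet_table.tsv")
  utils::write.table(st, st_path, sep = "\t", quote = FALSE, row.names = FALSE)
  out$paths <- c(out$paths, exp_paths, subnet_table = st_path)

  # annotation runs when marker positions are available
  snp_map <- NULL
  if (!is.null(config$snp_positions)) {
    snp_map <- utils::read.table(config$snp_positions, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
  }
  if (!is.null(snp_map)) {
    ann <- annotate_subnets(
      subnets, snp_map,
      qtls = if (is.null(config$qtl_bed)) NULL else read_bed(config$qtl_bed),
      genes = if (is.null(config$gene_bed)) NULL else read_bed(config$gene_bed),
      pathway_map = if (is.null(config$pathway_map)) NULL else
        utils::read.table(config$pathway_map, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE),
      half_width = config$fragment_half_width
    )
    out$regions <- ann$regions
    out$qtl_hits <- ann$qtl_hits
    out$pathways <- ann$pathways
    reg_path <- file.path(config$out_dir, "region_report.tsv")
    utils::write.table(ann$regions, reg_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths["regions"] <- reg_path
    logf("annotation: %d regions across %d subnets%s",
         nrow(ann$regions), length(subnets),
         if (is.null(ann$qtl_hits)) "" else
           sprintf("; %d SNP-QTL hits", nrow(ann$qtl_hits)))
  }
  logf("pipeline complete; artifacts under %s", config$out_dir)
  invisible(out)
}

#' Annotate subnets with regions, QTLs, genes and pathways
#'
#' For every subnet: 0.4 Mb fragments centred on member SNPs, union-merged
#' into regions ([merge_fragments()]); optional SNP-to-QTL mapping, gene
#' assignment per region and pathway tallies per subnet.
#'
#' @param subnets list of `epi_subnet` objects (or a single one).
#' @param snp_map data.frame `snp`, `chrom`, `pos`.
#' @param qtls,genes optional interval data.frames (1-based inclusive;
#'   `genes` needs `gene` = id and logical `coding` or an `id` column).
#' @param pathway_map optional data.frame `gene`, `pathway`.
#' @param half_width fragment half-width in bp.
#' @return list with `regions` (region report: subnet, chrom, start, end,
#'   width, SNP set, gene sets), `qtl_hits`, `pathways`.
#' @export
annotate_subnets <- function(subnets, snp_map, qtls = NULL, genes = NULL,
                             pathway_map = NULL, half_width = 200000) {
  if (inherits(subnets, "epi_subnet")) subnets <- list(subnets)
  if (!is.null(genes) && !"gene" %in% names(genes)) genes$gene <- genes$id
  if (!is.null(genes) && !"coding" %in% names(genes)) genes$coding <- TRUE
  regions <- list()
  gene_sets <- list()
  for (k in seq_along(subnets)) {
    lab <- LETTERS[k]
    snps <- snp_map[snp_map$snp %in% subnets[[k]]$nodes$snp, , drop = FALSE]
    fr <- snp_fragments(snps, half_width)
    if (length(attr(fr, "unmapped"))) {
      message("subnet ", lab, ": unmapped SNPs excluded from regions: ",
              paste(attr(fr, "unmapped"), collapse = ", "))
    }
    reg <- merge_fragments(fr)
    if (!is.null(genes)) {
      reg <- genes_in_regions(reg, genes)
      gene_sets[[lab]] <- setdiff(
        unlist(strsplit(c(reg$genes, reg$noncoding_genes), ",")), "")
    }
    if (nrow(reg)) regions[[length(regions) + 1L]] <- cbind(subnet = lab, reg)
  }
  regions <- if (length(regions)) do.call(rbind, regions) else NULL
  all_snps <- snp_map[snp_map$snp %in%
                        unlist(lapply(subnets, function(s) s$nodes$snp)), ,
                      drop = FALSE]
  qtl_hits <- if (is.null(qtls)) NULL else map_to_qtls(all_snps, qtls)
  pathways <- if (is.null(pathway_map) || !length(gene_sets)) NULL else
    pathway_tally(gene_sets, pathway_map)
  list(regions = regions, qtl_hits = qtl_hits, pathways = pathways)
}
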