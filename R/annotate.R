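#' @import GenomicRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# 1-based inclusive interval data.frame -> GRanges; a shared seqlevel
# universe keeps cross-set overlap calls quiet about disjoint chromosomes
.as_gr <- function(df, seqlevels = NULL) {
  chrom <- as.character(df$chrom)
  if (is.null(seqlevels)) seqlevels <- unique(chrom)
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}

#' Genomic fragment centred on a SNP
#'
#' Builds the window `[pos - half_width, pos + half_width]` (1-based
#' inclusive, clipped at 1) around each mapped SNP — the 0.4 Mb fragment
#' whose half-width matches the distance over which LD (mean composite
#' r-squared > 0.8) justifies assigning genes to a marker.  Unmapped SNPs
#' (missing or `"UN"` chromosome, missing position) are flagged and excluded.
#'
#' @param snps data.frame with columns `snp`, `chrom`, `pos`.
#' @param half_width half window width in bp (default 200,000).
#' @return data.frame of fragments (`chrom`, `start`, `end`, `snp`, `pos`)
#'   with attribute `unmapped` listing excluded SNP ids.
#' @export
snp_fragments <- function(snps, half_width = 200000) {
  stopifnot(all(c("snp", "chrom", "pos") %in% names(snps)), half_width > 0)
  unmapped <- is.na(snps$chrom) | is.na(snps$pos) | snps$chrom %in% c("UN", "")
  ok <- snps[!unmapped, , drop = FALSE]
  out <- data.frame(
    chrom = as.character(ok$chrom),
    start = pmax(1, ok$pos - half_width),
    end = ok$pos + half_width,
    snp = ok$snp,
    pos = ok$pos,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "unmapped") <- snps$snp[unmapped]
  out
}

#' Merge overlapping SNP fragments into regions
#'
#' Per chromosome, overlapping *or touching* fragments (a fragment starting
#' at `end + 1` of another) are merged into their union; each resulting
#' region records its member SNP set.  Every input fragment is contained in
#' exactly one region, and regions on one chromosome are pairwise disjoint
#' and sorted.
#'
#' @param fragments data.frame from [snp_fragments()].
#' @return data.frame with `chrom`, `start`, `end`, `width` (`end - start`),
#'   `n_snps`, `snps` (comma-separated member ids, in position order).
#' @export
merge_fragments <- function(fragments) {
  if (nrow(fragments) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), width = numeric(0),
                      n_snps = integer(0), snps = character(0),
                      stringsAsFactors = FALSE))
  }
  fr <- .as_gr(fragments)
  regions <- GenomicRanges::reduce(fr)  # merges overlapping and adjacent
  hits <- GenomicRanges::findOverlaps(fr, regions)
  snps_by_region <- split(fragments$snp[queryHits(hits)], subjectHits(hits))
  pos_by_region <- split(fragments$pos[queryHits(hits)], subjectHits(hits))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    stringsAsFactors = FALSE
  )
  out$width <- out$end - out$start
  idx <- as.character(seq_len(nrow(out)))
  out$n_snps <- as.integer(lengths(snps_by_region[idx]))
  out$snps <- vapply(idx, function(i) {
    paste(snps_by_region[[i]][order(pos_by_region[[i]])], collapse = ",")
  }, character(1))
  o <- order(chrom_rank(out$chrom), out$start)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map SNPs to QTL intervals
#'
#' A SNP hits a QTL iff its position lies within the interval (inclusive
#' ends) on the same chromosome; a SNP may hit several QTLs and a QTL may
#' hold several SNPs.
#'
#' @param snps data.frame `snp`, `chrom`, `pos`.
#' @param qtls data.frame `chrom`, `start`, `end`, `id` (1-based inclusive;
#'   see [read_bed()] for BED input).
#' @return data.frame of hits: `snp`, `chrom`, `pos`, `qtl`, `qtl_start`,
#'   `qtl_end`.
#' @export
map_to_qtls <- function(snps, qtls) {
  mism <- setdiff(unique(as.character(snps$chrom)),
                  unique(as.character(qtls$chrom)))
  if (length(mism)) {
    message("SNP chromosomes with no QTL intervals: ",
            paste(mism, collapse = ", "))
  }
  lv <- union(unique(as.character(snps$chrom)), unique(as.character(qtls$chrom)))
  sgr <- GenomicRanges::GRanges(factor(as.character(snps$chrom), levels = lv),
                                IRanges::IRanges(snps$pos, snps$pos))
  qgr <- .as_gr(qtls, seqlevels = lv)
  hits <- GenomicRanges::findOverlaps(sgr, qgr)
  out <- data.frame(
    snp = snps$snp[queryHits(hits)],
    chrom = as.character(snps$chrom)[queryHits(hits)],
    pos = snps$pos[queryHits(hits)],
    qtl = qtls$id[subjectHits(hits)],
    qtl_start = qtls$start[subjectHits(hits)],
    qtl_end = qtls$end[subjectHits(hits)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Assign genes to regions
#'
#' A gene belongs to a region iff its interval overlaps the region by at
#' least 1 bp (any-overlap rule) on the same chromosome.  With
#' `by = "snp"` the alternative per-SNP rule is used instead: a gene is
#' selected iff its distance to some member SNP position is strictly smaller
#' than `max_dist`.
#'
#' @param regions data.frame from [merge_fragments()] (needs `chrom`,
#'   `start`, `end`; `snps` required for `by = "snp"`).
#' @param genes data.frame `chrom`, `start`, `end`, `gene` and logical
#'   `coding`.
#' @param by `"region"` (default, any overlap with the merged region) or
#'   `"snp"` (distance to a member SNP below `max_dist`).
#' @param snps data.frame `snp`, `chrom`, `pos`; required for `by = "snp"`.
#' @param max_dist distance bound for `by = "snp"` (default 200,000, strict).
#' @return the `regions` data.frame with added columns `genes` and
#'   `noncoding_genes` (comma-separated, position order; `""` when empty).
#' @export
genes_in_regions <- function(regions, genes, by = c("region", "snp"),
                             snps = NULL, max_dist = 200000) {
  by <- match.arg(by)
  stopifnot(all(c("chrom", "start", "end", "gene", "coding") %in% names(genes)))
  lv <- union(unique(as.character(regions$chrom)),
              unique(as.character(genes$chrom)))
  ggr <- .as_gr(genes, seqlevels = lv)
  pick <- function(sel) {
    sel <- sel[order(genes$start[sel])]
    list(coding = paste(genes$gene[sel][genes$coding[sel]], collapse = ","),
         non = paste(genes$gene[sel][!genes$coding[sel]], collapse = ","))
  }
  if (by == "region") {
    rgr <- .as_gr(regions, seqlevels = lv)
    hits <- GenomicRanges::findOverlaps(rgr, ggr)
    sel_by_region <- split(subjectHits(hits), queryHits(hits))
    res <- lapply(seq_len(nrow(regions)), function(i) {
      pick(sel_by_region[[as.character(i)]] %||% integer(0))
    })
  } else {
    if (is.null(snps)) stop("by = \"snp\" needs the snps data.frame")
    res <- lapply(seq_len(nrow(regions)), function(i) {
      ids <- strsplit(regions$snps[i], ",")[[1]]
      ps <- snps$pos[match(ids, snps$snp)]
      same <- as.character(genes$chrom) == as.character(regions$chrom[i])
      # distance from the SNP point to the gene interval (0 if inside)
      sel <- which(same & vapply(seq_len(nrow(genes)), function(j) {
        any(pmax(genes$start[j] - ps, ps - genes$end[j], 0) < max_dist)
      }, logical(1)))
      pick(sel)
    })
  }
  regions$genes <- vapply(res, `[[`, character(1), "coding")
  regions$noncoding_genes <- vapply(res, `[[`, character(1), "non")
  regions
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tally pathway membership of annotated genes
#'
#' Counts, per pathway, the contributing genes from each gene set using a
#' local gene-to-pathway mapping.  No enrichment statistic is computed —
#' membership counts only.  Genes absent from the mapping are listed, not
#' silently dropped.
#'
#' @param gene_sets character vector of gene ids, or a named list of such
#'   vectors (e.g. one per subnet).
#' @param mapping data.frame with columns `gene`, `pathway` (one row per
#'   membership).
#' @return list with `tally` (data.frame `pathway`, `n_genes`, `genes`, plus
#'   `set` when `gene_sets` is a list) and `unmapped` (character vector).
#' @export
pathway_tally <- function(gene_sets, mapping) {
  stopifnot(all(c("gene", "pathway") %in% names(mapping)))
  if (!is.list(gene_sets)) gene_sets <- list(all = gene_sets)
  tallies <- list()
  unmapped <- character(0)
  for (nm in names(gene_sets)) {
    gs <- unique(gene_sets[[nm]])
    gs <- gs[gs != ""]
    hit <- mapping[mapping$gene %in% gs, , drop = FALSE]
    unmapped <- c(unmapped, setdiff(gs, mapping$gene))
    if (nrow(hit) == 0L) next
    by_path <- split(hit$gene, hit$pathway)
    tallies[[nm]] <- data.frame(
      set = nm,
      pathway = names(by_path),
      n_genes = lengths(by_path),
      genes = vapply(by_path, function(g) paste(sort(unique(g)), collapse = ","),
                     character(1)),
      stringsAsFactors = FALSE
    )
  }
  tally <- if (length(tallies)) do.call(rbind, tallies) else
    data.frame(set = character(0), pathway = character(0),
               n_genes = integer(0), genes = character(0),
               stringsAsFactors = FALSE)
  rownames(tally) <- NULL
  tally <- tally[order(tally$set, -tally$n_genes, tally$pathway), , drop = FALSE]
  rownames(tally) <- NULL
  list(tally = tally, unmapped = sort(unique(unmapped)))
}

#' Read a BED-like interval file as 1-based inclusive intervals
#'
#' BED is 0-based half-open; this reader converts to the 1-based inclusive
#' convention used throughout (start + 1, end unchanged), bit-exactly.
#' A 4th column is taken as the interval id/name and a 5th, when present and
#' equal to `"noncoding"`, marks a non-coding gene.
#'
#' @param path BED file (tab-separated, no header; `#` comments allowed).
#' @return data.frame `chrom`, `start`, `end`, `id` (and `coding` when a
#'   5th column is present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such interval file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(
    chrom = as.character(raw[[1]]),
    start = as.numeric(raw[[2]]) + 1,
    end = as.numeric(raw[[3]]),
    id = if (ncol(raw) >= 4L) as.character(raw[[4]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (ncol(raw) >= 5L) out$coding <- raw[[5]] != "noncoding"
  out
}
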