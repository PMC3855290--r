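test_that("SNP fragments are 0.4 Mb windows centred on the marker, clipped at 1", {
  snps <- data.frame(snp = c("a", "b", "c"), chrom = c("27", "1", "UN"),
                     pos = c(1111875, 100000, 5000))
  fr <- snp_fragments(snps)
  expect_equal(fr$start[fr$snp == "a"], 911875)
  expect_equal(fr$end[fr$snp == "a"], 1311875)
  expect_equal(fr$start[fr$snp == "b"], 1)
  expect_equal(fr$end[fr$snp == "b"], 300000)
  expect_equal(attr(fr, "unmapped"), "c")
})

test_that("every single-SNP fragment from the reconstructed map has width 400,000", {
  m <- afw_snp_map()
  singles <- m[m$derivation == "table4_center", ]
  fr <- snp_fragments(singles)
  expect_true(all(fr$end - fr$start == 400000))
})

test_that("fragment merging takes unions of overlapping and touching windows", {
  fr <- data.frame(chrom = "1",
                   start = c(800000, 900000), end = c(1200000, 1300000),
                   snp = c("a", "b"), pos = c(1000000, 1100000))
  reg <- merge_fragments(fr)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 800000)
  expect_equal(reg$end, 1300000)
  expect_equal(reg$n_snps, 2L)

  # disjoint fragments unchanged
  fr2 <- data.frame(chrom = "1", start = c(1, 1000000),
                    end = c(400001, 1400000), snp = c("a", "b"),
                    pos = c(200001, 1200000))
  expect_equal(nrow(merge_fragments(fr2)), 2L)

  # touching fragments (end + 1 = start) merge; same coordinates on another
  # chromosome do not
  fr3 <- data.frame(chrom = c("1", "1", "2"),
                    start = c(1, 400002, 400002), end = c(400001, 800002, 800002),
                    snp = c("a", "b", "c"), pos = c(200001, 600002, 600002))
  reg3 <- merge_fragments(fr3)
  expect_equal(nrow(reg3), 2L)
  expect_equal(reg3$end[reg3$chrom == "1"], 800002)
})

test_that("the six clustered GGA3 SNPs of the hub subnet merge into the printed 571,801 bp region", {
  m <- afw_snp_map()
  cluster <- m[m$chrom == "3" & m$pos >= 35348152 & m$pos <= 35919953, ]
  expect_equal(nrow(cluster), 6L)
  reg <- merge_fragments(snp_fragments(cluster))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 35348152)
  expect_equal(reg$end, 35919953)
  expect_equal(reg$width, 571801)
  expect_equal(reg$n_snps, 6L)
})

test_that("merging matches a brute-force union oracle on randomized instances", {
  set.seed(30)
  for (rep in 1:20) {
    k <- sample(2:12, 1)
    pos <- sort(sample(1e6:5e6, k))
    fr <- data.frame(chrom = "7", start = pmax(1, pos - 2e5), end = pos + 2e5,
                     snp = paste0("s", seq_len(k)), pos = pos)
    reg <- merge_fragments(fr)
    bf <- brute_merge(fr$start, fr$end)
    expect_equal(reg$start, bf[, 1])
    expect_equal(reg$end, bf[, 2])
    # partition refinement: every fragment inside exactly one region
    containing <- vapply(seq_len(k), function(i) {
      sum(fr$start[i] >= reg$start & fr$end[i] <= reg$end)
    }, numeric(1))
    expect_true(all(containing == 1))
    # regions pairwise disjoint, sorted, and never narrower than one window
    if (nrow(reg) > 1) expect_true(all(reg$start[-1] > reg$end[-nrow(reg)] + 1))
    expect_true(all(reg$width >= 400000))
  }
})

test_that("QTL mapping uses inclusive interval ends and matches a double-loop oracle", {
  qtls <- data.frame(chrom = c("1", "1", "2"), start = c(100, 500, 100),
                     end = c(200, 600, 200), id = c("q1", "q2", "q3"))
  snps <- data.frame(snp = c("s1", "s2", "s3", "s4"),
                     chrom = c("1", "1", "1", "2"),
                     pos = c(100, 200, 300, 150))  # exact start, exact end, outside
  hits <- map_to_qtls(snps, qtls)
  expect_setequal(hits$snp[hits$qtl == "q1"], c("s1", "s2"))
  expect_false("s3" %in% hits$snp)
  expect_equal(hits$qtl[hits$snp == "s4"], "q3")

  set.seed(31)
  snps_r <- data.frame(snp = paste0("s", 1:40),
                       chrom = sample(c("1", "2"), 40, TRUE),
                       pos = sample(1:1000, 40))
  qtls_r <- data.frame(chrom = sample(c("1", "2"), 15, TRUE),
                       start = sample(1:900, 15), id = paste0("q", 1:15))
  qtls_r$end <- qtls_r$start + sample(10:200, 15, TRUE)
  hits_r <- map_to_qtls(snps_r, qtls_r)
  bf <- brute_hits(snps_r$chrom, snps_r$pos, qtls_r$chrom, qtls_r$start,
                   qtls_r$end)
  expect_equal(nrow(hits_r), NROW(bf))
  got <- sort(paste(hits_r$snp, hits_r$qtl))
  want <- sort(paste(snps_r$snp[bf[, 1]], qtls_r$id[bf[, 2]]))
  expect_equal(got, want)
})

test_that("genes are assigned to regions by any overlap, split into coding and non-coding", {
  regions <- data.frame(chrom = "3", start = 1000, end = 2000,
                        snps = "s1", n_snps = 1)
  genes <- data.frame(chrom = "3",
                      start = c(1200, 500, 2000, 2001, 900),
                      end = c(1300, 999, 2400, 2600, 1000),
                      gene = c("IN", "OUT_LEFT", "EDGE1BP", "OUT_RIGHT", "TOUCH"),
                      coding = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- genes_in_regions(regions, genes)
  expect_equal(out$genes, "IN,EDGE1BP")
  expect_equal(out$noncoding_genes, "TOUCH")
})

test_that("the per-SNP distance rule differs from the region rule where regions extend past windows", {
  snps <- data.frame(snp = c("s1", "s2"), chrom = "1", pos = c(1e6, 1.35e6))
  reg <- merge_fragments(snp_fragments(snps))  # one region 0.8e6..1.55e6
  genes <- data.frame(chrom = "1", start = 1519000, end = 1530000,
                      gene = "FARGENE", coding = TRUE)
  by_region <- genes_in_regions(reg, genes)
  expect_equal(by_region$genes, "FARGENE")  # overlaps the merged region
  by_snp <- genes_in_regions(reg, genes, by = "snp", snps = snps)
  expect_equal(by_snp$genes, "FARGENE")     # 169 kb from s2 -> selected
  far <- data.frame(chrom = "1", start = 1551000, end = 1552000,
                    gene = "PASTWINDOW", coding = TRUE)
  expect_equal(genes_in_regions(reg, far, by = "snp", snps = snps)$genes, "")
})

test_that("gene assignment matches a brute-force overlap oracle", {
  set.seed(32)
  regions <- data.frame(chrom = sample(c("1", "2"), 8, TRUE),
                        start = sample(1:5000, 8))
  regions$end <- regions$start + sample(100:1500, 8, TRUE)
  regions$snps <- paste0("s", 1:8); regions$n_snps <- 1
  genes <- data.frame(chrom = sample(c("1", "2"), 30, TRUE),
                      start = sample(1:6000, 30))
  genes$end <- genes$start + sample(10:800, 30, TRUE)
  genes$gene <- paste0("g", 1:30)
  genes$coding <- TRUE
  out <- genes_in_regions(regions, genes)
  for (i in seq_len(nrow(regions))) {
    want <- genes$gene[genes$chrom == regions$chrom[i] &
                         genes$start <= regions$end[i] &
                         genes$end >= regions$start[i]]
    got <- setdiff(strsplit(out$genes[i], ",")[[1]], "")
    expect_setequal(got, want)
  }
})

test_that("pathway tallies count memberships and expose unmapped genes", {
  mapping <- read.delim(system.file("extdata", "afw_gene_pathways_synthetic.tsv",
                                    package = "epinetscan"))
  res <- pathway_tally(c("GRB2", "PDPK1", "PIK3CA", "SOCS3", "NOSUCH"), mapping)
  ins <- res$tally[res$tally$pathway == "Insulin signaling pathway", ]
  expect_equal(ins$n_genes, 4L)
  expect_equal(ins$genes, "GRB2,PDPK1,PIK3CA,SOCS3")
  expect_equal(res$unmapped, "NOSUCH")

  empty <- pathway_tally(c("A", "B"), mapping[0, ])
  expect_equal(nrow(empty$tally), 0L)
  expect_setequal(empty$unmapped, c("A", "B"))

  # brute-force count on a random mapping
  set.seed(33)
  mp <- data.frame(gene = sample(paste0("g", 1:20), 40, TRUE),
                   pathway = sample(paste0("p", 1:6), 40, TRUE))
  mp <- mp[!duplicated(mp), ]
  gs <- sample(paste0("g", 1:25), 12)
  res_r <- pathway_tally(gs, mp)
  for (pw in unique(res_r$tally$pathway)) {
    want <- length(unique(mp$gene[mp$pathway == pw & mp$gene %in% gs]))
    expect_equal(res_r$tally$n_genes[res_r$tally$pathway == pw], want)
  }
})

test_that("BED input converts to 1-based inclusive coordinates exactly", {
  tmp <- tempfile(fileext = ".bed")
  writeLines(c("# comment", "3\t34826540\t35226541\tregA",
               "Z\t0\t100\tregB\tnoncoding"), tmp)
  bed <- read_bed(tmp)
  expect_equal(bed$start, c(34826541, 1))
  expect_equal(bed$end, c(35226541, 100))
  expect_equal(bed$coding, c(TRUE, FALSE))
})
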