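#' Build the SNP-SNP epistasis network from significant pairs
#'
#' Nodes are the distinct SNPs of the significant-pair table; an undirected
#' edge joins every distinct unordered pair.  Parallel records for the same
#' pair (e.g. two effect types both significant) are collapsed to one edge
#' keeping the most significant record.  Self-loops and malformed rows are
#' rejected with their row numbers.
#'
#' @param pairs data.frame with columns `snp1`, `snp2`, `effect_type`,
#'   `p_value`, `c_pct` and optionally `chrom1`, `chrom2` (the
#'   significant-pair table schema of [run_scan()] / [load_pair_table()]).
#' @return object of class `epi_network`: `nodes` (data.frame `snp`,
#'   `chrom`, `degree`, `best_p`, `color_class`), `edges` (data.frame `snp1`,
#'   `snp2`, `effect_type`, `p_value`, `c_pct`, `color_class`) and `graph`
#'   (the underlying \pkg{igraph} object).
#' @export
build_network <- function(pairs) {
  req <- c("snp1", "snp2", "effect_type", "p_value", "c_pct")
  miss <- setdiff(req, names(pairs))
  if (length(miss)) stop("pair table lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(
    is.na(pairs$snp1) | is.na(pairs$snp2) | pairs$snp1 == "" | pairs$snp2 == "" |
      pairs$snp1 == pairs$snp2 |
      !pairs$effect_type %in% c("AA", "AD", "DA", "DD") |
      is.na(pairs$p_value) | pairs$p_value <= 0 | pairs$p_value > 1 |
      is.na(pairs$c_pct) | pairs$c_pct < 0
  )
  if (length(bad)) {
    stop("malformed pair-table rows: ", paste(bad, collapse = ", "))
  }
  edges <- data.frame(
    snp1 = as.character(pairs$snp1), snp2 = as.character(pairs$snp2),
    effect_type = pairs$effect_type, p_value = pairs$p_value,
    c_pct = pairs$c_pct, stringsAsFactors = FALSE
  )
  # canonical unordered key; collapse parallel edges keeping the smallest P
  key <- ifelse(edges$snp1 <= edges$snp2,
                paste(edges$snp1, edges$snp2, sep = "\r"),
                paste(edges$snp2, edges$snp1, sep = "\r"))
  o <- order(key, edges$p_value)
  edges <- edges[o, , drop = FALSE][!duplicated(key[o]), , drop = FALSE]
  rownames(edges) <- NULL
  edges$color_class <- effect_color(edges$effect_type)

  chrom_of <- character(0)
  if (all(c("chrom1", "chrom2") %in% names(pairs))) {
    chrom_of <- c(
      stats::setNames(as.character(pairs$chrom1), as.character(pairs$snp1)),
      stats::setNames(as.character(pairs$chrom2), as.character(pairs$snp2))
    )
  }
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    deg <- igraph::degree(g)
    snps <- names(deg)
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    deg <- integer(0)
    snps <- character(0)
  }
  best_p <- vapply(snps, function(s) {
    min(edges$p_value[edges$snp1 == s | edges$snp2 == s])
  }, numeric(1))
  nodes <- data.frame(
    snp = snps,
    chrom = if (length(chrom_of)) unname(chrom_of[snps]) else
      rep(NA_character_, length(snps)),
    degree = as.integer(deg),
    best_p = best_p,
    color_class = p_color_class(best_p),
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "epi_network")
}

#' Significance color class of a node
#'
#' Bins a P-value into the display classes used for network nodes:
#' `P < 1e-13` red, `P < 1e-12` blue, `P < 1e-11` green, `P < 1e-10` white.
#'
#' @param p numeric vector of P-values.
#' @return character vector of color classes (`NA` above 1e-10).
#' @export
p_color_class <- function(p) {
  cut(p, breaks = c(0, 1e-13, 1e-12, 1e-11, 1e-10, Inf),
      labels = c("red", "blue", "green", "white", NA),
      right = FALSE) |> as.character()
}

# edge color encodes the epistatic effect type
effect_color <- function(type) {
  c(AA = "red", AD = "purple", DA = "orange", DD = "blue")[type] |> unname()
}

#' @export
print.epi_network <- function(x, ...) {
  cat(sprintf("SNP-SNP epistasis network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Extract subnets (connected components) of the epistasis network
#'
#' Components with at least `min_nodes` nodes are retained and labelled
#' deterministically: descending node count, ties broken by the
#' lexicographically smallest member SNP id.
#'
#' @param network an [build_network()] result.
#' @param min_nodes smallest component size retained (default 3, matching a
#'   subnet report that includes 3-node subnets).
#' @return list of `epi_subnet` objects; each carries `nodes`, `edges`,
#'   `n_nodes`, `n_edges`, `greatest_degree`, `topology`, `chromosomes` and
#'   `importance`.
#' @export
extract_subnets <- function(network, min_nodes = 3) {
  stopifnot(inherits(network, "epi_network"))
  if (nrow(network$nodes) == 0L) return(list())
  comp <- igraph::components(network$graph)
  ids <- seq_len(comp$no)
  members <- split(names(comp$membership), comp$membership)
  sizes <- lengths(members)
  keep <- ids[sizes >= min_nodes]
  smallest <- vapply(members, function(m) sort(m)[1], character(1))
  keep <- keep[order(-sizes[keep], smallest[keep])]
  lapply(keep, function(k) {
    snps <- members[[k]]
    nodes <- network$nodes[network$nodes$snp %in% snps, , drop = FALSE]
    edges <- network$edges[network$edges$snp1 %in% snps |
                             network$edges$snp2 %in% snps, , drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    sn <- structure(
      list(nodes = nodes, edges = edges,
           n_nodes = nrow(nodes), n_edges = nrow(edges),
           greatest_degree = max(nodes$degree),
           chromosomes = chrom_span(nodes$chrom)),
      class = "epi_subnet"
    )
    sn$topology <- classify_topology(sn)
    sn$importance <- subnet_importance(sn)
    sn
  })
}

#' Topology label of a connected subnet
#'
#' A connected component is a `"Tree graph"` iff its edge count equals its
#' node count minus one (acyclic); otherwise (edge count >= node count) it
#' contains a cycle and is a `"Loop graph"`.
#'
#' @param subnet an `epi_subnet`, or anything with `n_nodes`/`n_edges`.
#' @return `"Tree graph"` or `"Loop graph"`.
#' @export
classify_topology <- function(subnet) {
  n <- subnet$n_nodes; e <- subnet$n_edges
  if (e < n - 1) stop("subnet is not connected (edges < nodes - 1)")
  if (e == n - 1) "Tree graph" else "Loop graph"
}

#' Entropy-motivated importance score of a subnet
#'
#' Aggregates each edge's significance and contribution:
#' `w = sum over edges of c_i * (-log10 p_i)`, with `c_i` the edge's
#' contribution rate expressed as a proportion (1.25\% -> 0.0125) and `p_i`
#' its P-value.  An edge's term is the information content (-log10 p) of its
#' test weighted by the share of phenotypic variation it explains, so `w` is
#' additive over edges, increasing in each `c_i` and decreasing in each
#' `p_i`.
#'
#' @param subnet an `epi_subnet`, or any object with an `edges` data.frame
#'   carrying `p_value` and `c_pct`.
#' @return non-negative numeric score.
#' @export
subnet_importance <- function(subnet) {
  e <- subnet$edges
  if (any(e$p_value <= 0)) stop("P-values must be positive")
  sum((e$c_pct / 100) * (-log10(e$p_value)))
}

#' @export
print.epi_subnet <- function(x, ...) {
  cat(sprintf(
    "Subnet: %d nodes, %d edges, greatest degree %d, %s, GGA %s, importance %.3f\n",
    x$n_nodes, x$n_edges, x$greatest_degree, x$topology, x$chromosomes,
    x$importance))
  invisible(x)
}

#' Summary table of subnets
#'
#' One row per subnet in the deterministic order of [extract_subnets()],
#' labelled A, B, C, ... : importance, node number, edge number, greatest
#' degree, topology and chromosomes spanned.
#'
#' @param subnets list of `epi_subnet` objects.
#' @return data.frame.
#' @export
subnet_table <- function(subnets) {
  if (!length(subnets)) {
    return(data.frame(subnet = character(0), importance = numeric(0),
                      n_nodes = integer(0), n_edges = integer(0),
                      greatest_degree = integer(0), structure = character(0),
                      chromosomes = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    subnet = LETTERS[seq_along(subnets)],
    importance = vapply(subnets, `[[`, numeric(1), "importance"),
    n_nodes = vapply(subnets, `[[`, numeric(1), "n_nodes"),
    n_edges = vapply(subnets, `[[`, numeric(1), "n_edges"),
    greatest_degree = vapply(subnets, `[[`, numeric(1), "greatest_degree"),
    structure = vapply(subnets, `[[`, character(1), "topology"),
    chromosomes = vapply(subnets, `[[`, character(1), "chromosomes"),
    stringsAsFactors = FALSE
  )
}

#' Export the network for graph viewers
#'
#' Writes a SIF edge file (`snp1 <effect type> snp2`, one line per edge) and
#' tab-separated node- and edge-attribute tables (chromosome, degree,
#' significance color class, effect type).  Empty networks yield empty but
#' valid files.
#'
#' @param network an `epi_network`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisible character vector of the written paths.
#' @export
export_network <- function(network, dir, prefix = "epinet") {
  stopifnot(inherits(network, "epi_network"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  sif <- file.path(dir, paste0(prefix, ".sif"))
  nodes <- file.path(dir, paste0(prefix, "_node_attributes.tsv"))
  edges <- file.path(dir, paste0(prefix, "_edge_attributes.tsv"))
  e <- network$edges
  writeLines(if (nrow(e)) paste(e$snp1, e$effect_type, e$snp2) else character(0),
             sif)
  utils::write.table(network$nodes, nodes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(e, edges, sep = "\t", quote = FALSE, row.names = FALSE)
  for (p in c(sif, nodes, edges)) {
    if (!file.exists(p)) stop("failed to write ", p)
  }
  invisible(c(sif = sif, nodes = nodes, edges = edges))
}
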