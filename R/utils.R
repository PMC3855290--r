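#' Canonical chromosome ordering
#'
#' Chromosome labels in this design mix integers (1..28), linkage groups
#' ("LEG22", "LEG64"), the sex chromosome "Z", unplaced markers "UN" and the
#' pseudo-label "0".  They are ordered numerically first (1..28 ascending),
#' then linkage groups lexicographically, then Z, then UN, then 0.
#'
#' @param chrom character (or coercible) vector of chromosome labels.
#' @return numeric rank usable in `order()`; equal labels get equal ranks.
#' @export
chrom_rank <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  rank <- numeric(length(chrom))
  is_num <- !is.na(num) & num > 0
  rank[is_num] <- num[is_num]
  is_leg <- startsWith(chrom, "LEG")
  # linkage groups after autosomes, ordered by their own number
  legnum <- suppressWarnings(as.numeric(sub("^LEG", "", chrom[is_leg])))
  legnum[is.na(legnum)] <- 0
  rank[is_leg] <- 1000 + legnum
  rank[chrom == "Z"] <- 2000
  rank[chrom == "W"] <- 2001
  rank[chrom == "UN"] <- 3000
  rank[!is.na(num) & num == 0] <- 3001
  other <- !is_num & !is_leg & !chrom %in% c("Z", "W", "UN")
  rank[other & rank == 0] <- 4000 + as.numeric(factor(chrom[other & rank == 0]))
  rank
}

# comma-joined unique chromosome labels in canonical order (Table-3 style)
chrom_span <- function(chrom) {
  u <- unique(as.character(chrom))
  paste(u[order(chrom_rank(u))], collapse = ", ")
}
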