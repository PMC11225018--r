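midpoint_in <- function(chrom, mid, regions) {
  # TRUE where the (chrom, mid) point falls inside some region
  hit <- logical(length(mid))
  by_chr <- split(seq_along(mid), chrom)
  for (ch in names(by_chr)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(r) == 0L) next
    o <- order(r$start)
    s <- r$start[o]
    e <- r$end[o]
    i <- by_chr[[ch]]
    k <- findInterval(mid[i], s)
    hit[i] <- k > 0L & mid[i] < e[pmax(k, 1L)]
  }
  hit
}

#' Fraction of fragments per genomic compartment
#'
#' Each fragment is assigned by its midpoint to the highest-priority
#' compartment containing it (list order = priority), or to `"other"`.
#' Midpoint assignment makes the fractions a true partition summing to 1.
#' Sub-fractions within a compartment (e.g. maternal- versus somatic-type
#' rDNA) are obtained by calling this again on the assigned subset.
#'
#' @param fragments a `FragmentSet`.
#' @param compartments named list of `RegionSet`s, highest priority first.
#' @return list with `fractions` (named, sums to 1), `counts` and the
#'   per-fragment `assignment`.
#' @export
compartment_fractions <- function(fragments, compartments) {
  stopifnot(is.list(compartments), !is.null(names(compartments)))
  n <- nrow(fragments)
  mid <- (fragments$start + fragments$end) %/% 2
  assignment <- rep("other", n)
  unassigned <- rep(TRUE, n)
  for (nm in names(compartments)) {
    hit <- unassigned & midpoint_in(fragments$chrom, mid, compartments[[nm]])
    assignment[hit] <- nm
    unassigned <- unassigned & !hit
  }
  lev <- c(names(compartments), "other")
  counts <- table(factor(assignment, levels = lev))
  list(
    fractions = counts / max(n, 1L),
    counts = counts,
    assignment = assignment
  )
}

#' Annotate peaks as promoter, gene body or intergenic
#'
#' The peak midpoint decides: inside a promoter window (default 1 kb
#' upstream of the TSS, strand-aware) beats inside the gene span, which
#' beats intergenic.
#'
#' @param peaks a `RegionSet`.
#' @param genes a stranded `RegionSet` of gene spans.
#' @param promoter_flank bases upstream of the TSS (default 1000).
#' @return list with per-peak `category` and the category `counts`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_flank = 1000) {
  if (any(genes$strand == ".")) stop("genes must be stranded")
  mid <- (peaks$start + peaks$end) %/% 2
  plus <- genes$strand == "+"
  prom_start <- pmax(ifelse(plus, genes$start - promoter_flank, genes$end), 0)
  prom_end <- ifelse(plus, genes$start, genes$end + promoter_flank)
  ok <- prom_start < prom_end  # a TSS at the chromosome origin has no window
  prom <- region_set(genes$chrom[ok], prom_start[ok], prom_end[ok])
  in_prom <- midpoint_in(peaks$chrom, mid, prom)
  in_gene <- midpoint_in(peaks$chrom, mid, genes)
  category <- ifelse(in_prom, "promoter",
                     ifelse(in_gene, "gene_body", "intergenic"))
  list(
    category = category,
    counts = table(factor(category,
                          levels = c("promoter", "gene_body", "intergenic")))
  )
}
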