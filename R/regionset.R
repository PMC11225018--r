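#' Ordered genomic interval sets (BED semantics)
#'
#' A `RegionSet` is a data frame of half-open, 0-based intervals with BED6
#' columns (`chrom`, `start`, `end`, `name`, `score`, `strand`). It carries
#' peaks, planted truth regions, annotations and enzyme cut sites.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param name feature names (default `"."`).
#' @param score numeric scores (default `0`).
#' @param strand `"+"`, `"-"` or `"."`.
#' @return a `data.frame` of class `RegionSet`.
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer(),
                       name = ".", score = 0, strand = ".") {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (n > 0L) {
    if (any(df$start < 0)) stop("negative start coordinate")
    if (any(df$start >= df$end)) stop("regions must satisfy start < end")
    if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  }
  class(df) <- c("RegionSet", "data.frame")
  attr(df, "sorted") <- FALSE
  df
}

as_region_set <- function(df) {
  region_set(df$chrom, df$start, df$end,
             name = if (is.null(df$name)) "." else df$name,
             score = if (is.null(df$score)) 0 else df$score,
             strand = if (is.null(df$strand)) "." else df$strand)
}

#' Sort a RegionSet by (chrom, start, end)
#' @param regions a `RegionSet`.
#' @export
sort_regions <- function(regions) {
  o <- order(regions$chrom, regions$start, regions$end)
  out <- regions[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("RegionSet", "data.frame")
  attr(out, "sorted") <- TRUE
  out
}

#' Union-merge overlapping or bookended intervals
#'
#' Strand is ignored; the merged set is unstranded. Used to build the total
#' peak set across stages before signal aggregation.
#'
#' @param regions a `RegionSet`.
#' @param gap merge intervals separated by at most `gap` bases (default 0,
#'   i.e. only overlapping/bookended intervals merge).
#' @export
merge_regions <- function(regions, gap = 0) {
  if (nrow(regions) == 0L) return(regions)
  gr <- regions_to_granges(regions)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap + 1L, ignore.strand = TRUE)
  granges_to_regions(red)
}

# RegionSet (0-based half-open) -> GRanges (1-based closed)
regions_to_granges <- function(regions) {
  strand <- ifelse(regions$strand == ".", "*", regions$strand)
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = strand
  )
}

granges_to_regions <- function(gr) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- S4Vectors::mcols(gr)$name
  sc <- S4Vectors::mcols(gr)$score
  region_set(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(nm)) "." else as.character(nm),
    score = if (is.null(sc) || all(is.na(sc))) 0 else ifelse(is.na(sc), 0, sc),
    strand = strand
  )
}

#' Read a BED file into a RegionSet
#' @param path BED3-BED6 file.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  sort_regions(granges_to_regions(gr))
}

#' Write a RegionSet as BED6
#' @param regions a `RegionSet`.
#' @param path output file.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(
    regions$chrom,
    format(regions$start, scientific = FALSE, trim = TRUE),
    format(regions$end, scientific = FALSE, trim = TRUE),
    regions$name,
    regions$score,
    ifelse(regions$strand == ".", ".", regions$strand)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
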