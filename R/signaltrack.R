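#' Binned, strand-resolved coverage tracks
#'
#' A `SignalTrack` stores per-chromosome vectors of binned coverage at a
#' fixed bin size, the strand it represents (`"+"`, `"-"` or `"both"`), and
#' the multiplicative normalization factor already applied to its values.
#'
#' @param values named list of numeric vectors, one per chromosome; vector
#'   `i` must have `ceiling(chrom_length/bin_size)` entries.
#' @param genome a `GenomeRef` supplying chromosome lengths.
#' @param bin_size bin width in bases.
#' @param strand `"+"`, `"-"` or `"both"`.
#' @param norm_factor scale already applied (bookkeeping only).
#' @return an object of class `SignalTrack`.
#' @export
signal_track <- function(values, genome, bin_size, strand = "both",
                         norm_factor = 1) {
  stopifnot(inherits(genome, "GenomeRef"), bin_size >= 1)
  if (!strand %in% c("+", "-", "both")) stop("strand must be +, - or both")
  for (chrom in names(values)) {
    want <- ceiling(genome$chrom_lengths[[chrom]] / bin_size)
    if (length(values[[chrom]]) != want) {
      stop(sprintf("track for %s has %d bins, expected %d",
                   chrom, length(values[[chrom]]), want))
    }
    if (any(values[[chrom]] < 0)) stop("negative coverage in ", chrom)
  }
  structure(
    list(bin_size = as.integer(bin_size), values = values, strand = strand,
         norm_factor = norm_factor,
         chrom_lengths = genome$chrom_lengths[names(values)]),
    class = "SignalTrack"
  )
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf(
    "SignalTrack: %d chromosome(s), bin %d bp, strand %s, norm factor %.4g\n",
    length(x$values), x$bin_size, x$strand, x$norm_factor
  ))
  invisible(x)
}

# mean bin value over the named chromosomes (weighted by bin count)
track_mean <- function(track, chroms = names(track$values)) {
  v <- unlist(track$values[chroms], use.names = FALSE)
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Write a SignalTrack as bedGraph
#'
#' Runs of equal-valued bins are merged; zero-valued runs are omitted, the
#' usual sparse bedGraph convention. The last bin of a chromosome is
#' truncated to the chromosome end.
#'
#' @param track a `SignalTrack`.
#' @param path output file.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- c(0, ends_bin[-length(ends_bin)])
    keep <- r$values != 0
    if (!any(keep)) next
    start <- starts_bin[keep] * track$bin_size
    end <- pmin(ends_bin[keep] * track$bin_size, track$chrom_lengths[[chrom]])
    lines <- sprintf("%s\t%s\t%s\t%s", chrom,
                     format(start, scientific = FALSE, trim = TRUE),
                     format(end, scientific = FALSE, trim = TRUE),
                     format(r$values[keep], scientific = FALSE, trim = TRUE))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a bedGraph into a SignalTrack
#'
#' Every interval must align to the stated bin grid (starts at multiples of
#' `bin_size`; ends at multiples or at the chromosome end), otherwise an
#' error identifies the offending interval.
#'
#' @param path bedGraph file.
#' @param genome a `GenomeRef`.
#' @param bin_size bin width the file is expected to follow.
#' @param strand strand label to attach.
#' @param norm_factor normalization factor to record (bookkeeping).
#' @export
read_bedgraph <- function(path, genome, bin_size, strand = "both",
                          norm_factor = 1) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "bedGraph"),
    error = function(e) stop("malformed bedGraph ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1L
  end <- GenomicRanges::end(gr)
  val <- S4Vectors::mcols(gr)$score
  unknown <- setdiff(unique(chrom), genome$chrom_names)
  if (length(unknown)) stop("bedGraph chromosome not in genome: ", unknown[1L])
  clen <- genome$chrom_lengths[chrom]
  bad <- start %% bin_size != 0 | (end %% bin_size != 0 & end != clen)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("bedGraph interval %s:%d-%d not aligned to %d bp bins",
                 chrom[i], start[i], end[i], bin_size))
  }
  values <- lapply(genome$chrom_names, function(ch) {
    numeric(ceiling(genome$chrom_lengths[[ch]] / bin_size))
  })
  names(values) <- genome$chrom_names
  for (i in seq_along(chrom)) {
    b0 <- start[i] %/% bin_size + 1L
    b1 <- ceiling(end[i] / bin_size)
    values[[chrom[i]]][b0:b1] <- val[i]
  }
  signal_track(values, genome, bin_size, strand = strand,
               norm_factor = norm_factor)
}
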