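#' Restriction enzyme specifications
#'
#' An `EnzymeSpec` holds a recognition motif over the IUPAC alphabet
#' (degenerate codes allowed) and the cut offset within the motif, in
#' bases from the motif start on the top strand.
#'
#' @param name enzyme name.
#' @param motif recognition motif (length >= 3), IUPAC letters.
#' @param cut_offset cut position within the motif, `0 <= offset <= length`.
#' @export
enzyme_spec <- function(name, motif, cut_offset) {
  motif <- toupper(motif)
  if (nchar(motif) < 3) stop("motif length must be >= 3")
  if (cut_offset < 0 || cut_offset > nchar(motif)) {
    stop("cut offset must lie within the motif")
  }
  bad <- setdiff(strsplit(motif, "")[[1L]],
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad)) stop("invalid IUPAC letter(s): ", paste(bad, collapse = ""))
  structure(list(name = name, motif = motif, cut_offset = as.integer(cut_offset)),
            class = "EnzymeSpec")
}

#' Built-in high-frequency cutters used for R-loop fragmentation
#'
#' DdeI (C^TNAG), MseI (T^TAA), NlaIII (CATG^) and MboI (^GATC) — the
#' four-/five-base cutters whose combined digest defines restriction-based
#' R-loop peak boundaries.
#'
#' @param names subset of enzyme names (default all four).
#' @return list of `EnzymeSpec`s.
#' @export
builtin_enzymes <- function(names = c("DdeI", "MseI", "NlaIII", "MboI")) {
  all <- list(
    DdeI = enzyme_spec("DdeI", "CTNAG", 1L),
    MseI = enzyme_spec("MseI", "TTAA", 1L),
    NlaIII = enzyme_spec("NlaIII", "CATG", 4L),
    MboI = enzyme_spec("MboI", "GATC", 0L)
  )
  missing <- setdiff(names, names(all))
  if (length(missing)) stop("unknown enzyme(s): ", paste(missing, collapse = ", "))
  all[names]
}

#' Find restriction cut sites on the Watson strand
#'
#' Scans each chromosome for all (IUPAC-aware) motif matches and records
#' the cut coordinate `match_start + cut_offset` (0-based). Sites from all
#' enzymes are pooled, sorted and deduplicated.
#'
#' @param genome a `GenomeRef` with sequences.
#' @param enzymes list of [enzyme_spec()]s.
#' @param chroms chromosomes to scan (default all).
#' @return a `RegionSet` of 1-bp cut coordinates, `name` = enzyme.
#' @export
find_cut_sites <- function(genome, enzymes, chroms = genome$chrom_names) {
  if (inherits(enzymes, "EnzymeSpec")) enzymes <- list(enzymes)
  if (is.null(genome$seq)) stop("genome must carry sequences")
  hits <- list()
  for (ch in chroms) {
    subject <- genome$seq[[ch]]
    for (ez in enzymes) {
      m <- Biostrings::matchPattern(ez$motif, subject, fixed = FALSE)
      if (length(m) == 0L) next
      cut <- BiocGenerics::start(m) - 1L + ez$cut_offset
      hits[[length(hits) + 1L]] <- data.frame(
        chrom = ch, cut = cut, name = ez$name
      )
    }
  }
  if (!length(hits)) {
    return(region_set())
  }
  df <- do.call(rbind, hits)
  df <- df[!duplicated(df[c("chrom", "cut")]), , drop = FALSE]
  sort_regions(region_set(df$chrom, df$cut, df$cut + 1L, name = df$name))
}

#' Distance from peak boundaries to the nearest cut site
#'
#' For every peak start and end, the distance to the nearest cut site is
#' computed and binned; distances `<= extend` fall in bin `"0"`
#' (boundary overlapping a site within the +/- `extend` window). Default
#' bins beyond 0 are 1-10, 11-50, 51-200 and >200 bp.
#'
#' @param peaks a `RegionSet` of peaks.
#' @param cut_sites a non-empty `RegionSet` of cut coordinates.
#' @param extend overlap slack in bp (default 5).
#' @param breaks upper edges of the distance bins after bin 0.
#' @return list: `distances` per boundary, `counts` per bin,
#'   `fraction_bin0`, and `n_boundaries`.
#' @export
boundary_distances <- function(peaks, cut_sites, extend = 5,
                               breaks = c(10, 50, 200)) {
  if (nrow(cut_sites) == 0L) stop("empty cut site set")
  stopifnot(extend >= 0)
  sites <- split(cut_sites$start, cut_sites$chrom)
  bchrom <- rep(peaks$chrom, 2L)
  bpos <- c(peaks$start, peaks$end)
  d <- rep(NA_real_, length(bpos))
  for (ch in unique(bchrom)) {
    s <- sort(sites[[ch]])
    k <- bchrom == ch
    if (is.null(s) || !length(s)) next
    near <- snap_nearest(bpos[k], s)
    d[k] <- abs(bpos[k] - near)
  }
  if (anyNA(d)) {
    stop("no cut sites on chromosome(s): ",
         paste(unique(bchrom[is.na(d)]), collapse = ", "))
  }
  edges <- c(extend, breaks[breaks > extend], Inf)
  labels <- c("0", paste0(c(extend, breaks[breaks > extend])[
    seq_len(length(edges) - 2L)] + 1, "-",
    breaks[breaks > extend]),
    paste0(">", max(breaks)))
  bin <- cut(d, breaks = c(-1, edges), labels = labels)
  counts <- table(bin)
  list(
    distances = d,
    counts = counts,
    fraction_bin0 = unname(counts[["0"]]) / length(d),
    n_boundaries = length(d)
  )
}
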