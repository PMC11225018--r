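#' Generate a random genome
#'
#' Draws i.i.d. bases with P(G) = P(C) = `gc_content`/2 and
#' P(A) = P(T) = (1 - `gc_content`)/2, so the background has zero expected
#' GC and AT skew. Deterministic for a given seed.
#'
#' @param chrom_lengths named vector of chromosome lengths (>= 1000 bp).
#' @param gc_content overall GC fraction in (0, 1]; the default 0.41
#'   mirrors a typical vertebrate genome.
#' @param seed RNG seed (optional).
#' @param spikein_chroms,ignored_chroms passed to [genome_ref()].
#' @return a `GenomeRef` with sequences; the GC content used is stored in
#'   the `gc_content` element.
#' @export
make_genome <- function(chrom_lengths, gc_content = 0.41, seed = NULL,
                        spikein_chroms = character(),
                        ignored_chroms = "chrM") {
  stopifnot(all(chrom_lengths >= 1000), gc_content > 0, gc_content <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  seqs <- vapply(chrom_lengths, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  g <- genome_ref(sequences = Biostrings::DNAStringSet(seqs),
                  spikein_chroms = spikein_chroms,
                  ignored_chroms = ignored_chroms)
  g$gc_content <- gc_content
  g
}

sample_skewed_bases <- function(n, gc, skew, sign = +1) {
  # Watson-strand composition inside a planted R-loop region: the strand
  # carrying the unpaired ssDNA is G- and A-rich by `skew`
  s <- sign * skew
  p <- c(A = (1 - gc) / 2 * (1 + s), C = gc / 2 * (1 - s),
         G = gc / 2 * (1 + s), T = (1 - gc) / 2 * (1 - s))
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Plant strand-specific, skew-biased R-loop regions into a genome
#'
#' Rewrites the Watson strand inside each planted span with a skewed base
#' composition: a `+` (wR-loop) region gets P(G) = gc/2 (1 + skew) versus
#' P(C) = gc/2 (1 - skew), and analogously A over T, so its expected GC and
#' AT skew equal `skew_strength`; `-` (cR-loop) regions are mirrored and
#' show the negative signature on the Watson strand. Regions are placed
#' uniformly without overlap on non-ignored target chromosomes.
#'
#' @param genome a `GenomeRef` from [make_genome()] (sequences required).
#' @param n_regions number of regions to plant.
#' @param length_range min/max region length, sampled uniformly.
#' @param strand_mix probability a region is `+` (wR) (default 0.5).
#' @param skew_strength expected skew inside planted regions, in [0, 1).
#' @param weight_range per-region enrichment weight range (uniform).
#' @param seed RNG seed (optional).
#' @param max_tries placement retries before giving up.
#' @return list with `genome` (sequences rewritten) and `truth`, a
#'   `RegionSet` whose `score` column is the enrichment weight.
#' @export
plant_rloops <- function(genome, n_regions, length_range = c(500, 2000),
                         strand_mix = 0.5, skew_strength = 0.3,
                         weight_range = c(1, 1), seed = NULL,
                         max_tries = 200L) {
  stopifnot(inherits(genome, "GenomeRef"), skew_strength >= 0,
            skew_strength < 1)
  if (is.null(genome$seq)) stop("genome must carry sequences")
  if (!is.null(seed)) set.seed(seed)
  gc <- if (is.null(genome$gc_content)) 0.5 else genome$gc_content
  chroms <- norm_chroms(genome, "target")
  if (!length(chroms)) stop("no plantable target chromosomes")
  clen <- genome$chrom_lengths[chroms]
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  lens <- round(stats::runif(n_regions, length_range[1], length_range[2]))
  strands <- ifelse(stats::runif(n_regions) < strand_mix, "+", "-")
  weights <- stats::runif(n_regions, weight_range[1], weight_range[2])
  for (i in seq_len(n_regions)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1L, prob = clen)
      if (clen[[ch]] <= lens[i]) next
      s <- floor(stats::runif(1, 0, clen[[ch]] - lens[i]))
      e <- s + lens[i]
      same <- placed$chrom == ch
      if (!any(same & placed$start < e & placed$end > s)) {
        placed <- rbind(placed,
                        data.frame(chrom = ch, start = s, end = e))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place ", n_regions, " non-overlapping regions")
  }
  seqs <- as.character(genome$seq)
  for (i in seq_len(n_regions)) {
    ch <- placed$chrom[i]
    sgn <- if (strands[i] == "+") +1 else -1
    patch <- sample_skewed_bases(placed$end[i] - placed$start[i], gc,
                                 skew_strength, sgn)
    substr(seqs[[ch]], placed$start[i] + 1L, placed$end[i]) <- patch
  }
  new_genome <- genome_ref(
    sequences = Biostrings::DNAStringSet(seqs),
    spikein_chroms = genome$chrom_names[genome$namespace == "spikein"],
    ignored_chroms = genome$ignored_chroms
  )
  new_genome$gc_content <- gc
  truth <- sort_regions(region_set(
    chrom = placed$chrom, start = placed$start, end = placed$end,
    name = sprintf("rloop_%d", seq_len(n_regions)),
    score = weights, strand = strands
  ))
  list(genome = new_genome, truth = truth)
}
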