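#' Artificial half R-loop substrate designs
#'
#' A `SubstrateDesign` describes a linear substrate used to probe nuclease
#' boundary precision: a double-stranded segment, an RNA:DNA hybrid
#' segment, and an optional single-stranded tail, laid out along one
#' coordinate frame (the cDNA strand, 0-based). The junction between the
#' duplex and the hybrid — the coordinate a single-strand-specific nuclease
#' is expected to cut at — is `h_start`.
#'
#' @param sequence substrate sequence (cDNA strand, 5'->3').
#' @param ds_len length of the double-stranded segment at the 5' end.
#' @param hybrid_len length of the RNA:DNA hybrid segment following it.
#' @param ss_len length of the single-stranded 3' tail (default 0).
#' @return an object of class `SubstrateDesign` with `h_start`, `h_end`,
#'   `junction` (= `h_start`) and span accessors.
#' @export
substrate_design <- function(sequence, ds_len, hybrid_len,
                             ss_len = nchar(sequence) - ds_len - hybrid_len) {
  n <- nchar(sequence)
  stopifnot(ds_len >= 0, hybrid_len > 0, ss_len >= 0)
  if (ds_len + hybrid_len + ss_len != n) {
    stop("ds + hybrid + ss spans must partition the substrate")
  }
  structure(
    list(
      sequence = toupper(sequence), length = n,
      ds = c(0L, ds_len),
      h_start = ds_len, h_end = ds_len + hybrid_len,
      ss = c(ds_len + hybrid_len, n),
      junction = ds_len
    ),
    class = "SubstrateDesign"
  )
}

#' @export
print.SubstrateDesign <- function(x, ...) {
  cat(sprintf(
    "SubstrateDesign: %d nt (ds [0,%d) | hybrid [%d,%d) | ss [%d,%d)), junction at %d\n",
    x$length, x$ds[2], x$h_start, x$h_end, x$ss[1], x$ss[2], x$junction
  ))
  invisible(x)
}

#' The bundled half R-loop substrate design
#'
#' Built from the component sequences shipped with the package: the cDNA
#' strand is the synthesis primer (53 nt, paired to a DNA oligo to form the
#' duplex segment) followed by the reverse complement of the 203-nt RNA
#' (the hybrid segment). The 6-nt primer overhang beyond the oligo duplex
#' is treated as part of the ds segment, so the junction sits at
#' position 53.
#'
#' @return a `SubstrateDesign`.
#' @export
default_substrate_design <- function() {
  path <- system.file("extdata", "half_rloop_substrate.txt",
                      package = "rloopkit", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("part", "seq"),
                           stringsAsFactors = FALSE)
  parts <- stats::setNames(tab$seq, tab$part)
  rna_dna <- chartr("U", "T", parts[["rna"]])
  hybrid <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(rna_dna))
  )
  substrate_design(
    sequence = paste0(parts[["primer"]], hybrid),
    ds_len = nchar(parts[["primer"]]),
    hybrid_len = nchar(hybrid)
  )
}

#' Simulate nuclease-digested reads from a substrate
#'
#' Under the `"mbn"` model the single-strand-specific nuclease removes the
#' ss tail and RNA and cuts exactly at the duplex/hybrid junctions, so
#' every fragment spans the hybrid `[h_start, h_end)`. The `"noisy"` model
#' jitters both fragment ends with Gaussian sd `sigma`, emulating a less
#' precise enzyme. Each fragment is read from both ends: the Watson read's
#' 5' end is the fragment start, the Crick read's 5' end the last fragment
#' base.
#'
#' @param design a `SubstrateDesign`.
#' @param nuclease_model `"mbn"` or `"noisy"`.
#' @param n_reads number of fragments (= read pairs).
#' @param sigma end jitter sd for the noisy model (bp).
#' @param seed RNG seed (optional).
#' @return data frame with one row per fragment (`start`, `end`) plus
#'   columns `watson_5p` and `crick_5p`; class `substrate_reads`.
#' @export
simulate_substrate_reads <- function(design,
                                     nuclease_model = c("mbn", "noisy"),
                                     n_reads, sigma = 5, seed = NULL) {
  nuclease_model <- match.arg(nuclease_model)
  stopifnot(inherits(design, "SubstrateDesign"), n_reads >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_reads == 0L) {
    out <- data.frame(start = integer(), end = integer(),
                      watson_5p = integer(), crick_5p = integer())
    class(out) <- c("substrate_reads", "data.frame")
    return(out)
  }
  s <- rep(design$h_start, n_reads)
  e <- rep(design$h_end, n_reads)
  if (nuclease_model == "noisy") {
    s <- s + round(stats::rnorm(n_reads, 0, sigma))
    e <- e + round(stats::rnorm(n_reads, 0, sigma))
    s <- pmax(s, 0L)
    e <- pmin(e, design$length)
    e <- pmax(e, s + 1L)
  }
  out <- data.frame(start = s, end = e, watson_5p = s, crick_5p = e - 1L)
  class(out) <- c("substrate_reads", "data.frame")
  out
}

#' First-base (5'-end) profile of substrate reads
#'
#' Counts read 5' ends per position and strand and reports the modal
#' position per strand together with its deviation from the expected
#' junction (Watson reads should start at `h_start`, Crick reads at
#' `h_end - 1`).
#'
#' @param reads output of [simulate_substrate_reads()] (or any data frame
#'   with `watson_5p` / `crick_5p` columns).
#' @param design the `SubstrateDesign` the reads map to.
#' @return list with per-strand count vectors over substrate positions,
#'   modal positions, and deviations from the expected junctions.
#' @export
first_base_profile <- function(reads, design) {
  stopifnot(inherits(design, "SubstrateDesign"))
  if (nrow(reads) == 0L) stop("empty read set")
  pos <- seq_len(design$length) - 1L
  count_at <- function(p) {
    tabulate(p + 1L, nbins = design$length)
  }
  watson <- stats::setNames(count_at(reads$watson_5p), pos)
  crick <- stats::setNames(count_at(reads$crick_5p), pos)
  modal <- function(v) unname(which.max(v)) - 1L
  list(
    watson_counts = watson,
    crick_counts = crick,
    watson_mode = modal(watson),
    crick_mode = modal(crick),
    watson_deviation = modal(watson) - design$h_start,
    crick_deviation = modal(crick) - (design$h_end - 1L),
    n = nrow(reads)
  )
}
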