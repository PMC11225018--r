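#' Partition fragments into wR-loop and cR-loop sets
#'
#' A wR-loop leaves the Watson strand as the unpaired ssDNA, a cR-loop the
#' Crick strand. Under the `mate1-forward` convention a `+` fragment is a
#' wR-loop and a `-` fragment a cR-loop; flipping the convention swaps the
#' two sets. Unstranded (`"."`) fragments in an R-loop library are excluded
#' with a warning and counted.
#'
#' @param fragments a `FragmentSet` with strand.
#' @param strand_convention `"mate1-forward"` or `"mate1-reverse"`.
#' @return list with `wR` and `cR` `FragmentSet`s and `excluded`, the
#'   number of unstranded fragments left out.
#' @export
split_strands <- function(fragments,
                          strand_convention = c("mate1-forward",
                                                "mate1-reverse")) {
  strand_convention <- match.arg(strand_convention)
  undecided <- fragments$strand == "."
  if (any(undecided)) {
    warning(sum(undecided), " unstranded fragment(s) excluded from the ",
            "wR/cR partition")
  }
  w_strand <- if (strand_convention == "mate1-forward") "+" else "-"
  keep_class <- function(df) {
    class(df) <- c("FragmentSet", "data.frame")
    rownames(df) <- NULL
    df
  }
  list(
    wR = keep_class(fragments[fragments$strand == w_strand, , drop = FALSE]),
    cR = keep_class(fragments[fragments$strand ==
                                setdiff(c("+", "-"), w_strand), ,
                              drop = FALSE]),
    excluded = sum(undecided)
  )
}

#' RPGC (1x depth) normalization factor
#'
#' The scale that makes genome-wide mean coverage equal 1:
#' `L_eff / B`, with `L_eff` the summed lengths of non-ignored target
#' chromosomes and `B` the summed span lengths of fragments on those
#' chromosomes. Ignored chromosomes (mitochondrial DNA by default) affect
#' neither numerator nor denominator.
#'
#' @param fragments a `FragmentSet`.
#' @param genome a `GenomeRef`.
#' @return the multiplicative RPGC scale.
#' @export
rpgc_factor <- function(fragments, genome) {
  chroms <- norm_chroms(genome, "target")
  l_eff <- effective_genome_size(genome, "target")
  keep <- fragments$chrom %in% chroms
  b <- sum(fragments$end[keep] - fragments$start[keep])
  if (b == 0) stop("no fragments on non-ignored target chromosomes")
  l_eff / b
}

#' Binned coverage track from fragments
#'
#' Bin value = (fragment bases overlapping the bin) / bin_size x scale;
#' total track mass times bin size therefore equals total fragment span
#' length times scale. Spike-in fragments never enter coverage tracks.
#'
#' @param fragments a `FragmentSet`.
#' @param genome a `GenomeRef`; one array per target chromosome.
#' @param bin_size bin width (default 50 bp).
#' @param strand `"+"`, `"-"` (filter fragments first) or `"both"`.
#' @param scale multiplicative normalization, e.g. from [rpgc_factor()].
#' @return a `SignalTrack`.
#' @export
coverage_track <- function(fragments, genome, bin_size = 50,
                           strand = "both", scale = 1) {
  stopifnot(bin_size >= 1)
  if (strand %in% c("+", "-")) {
    fragments <- fragments[fragments$strand == strand, , drop = FALSE]
  }
  fragments <- fragments[fragments$namespace == "target", , drop = FALSE]
  chroms <- genome$chrom_names[genome$namespace == "target"]
  values <- vector("list", length(chroms))
  names(values) <- chroms
  for (ch in chroms) {
    len <- genome$chrom_lengths[[ch]]
    n_bins <- ceiling(len / bin_size)
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0L) {
      values[[ch]] <- numeric(n_bins)
      next
    }
    # per-base depth by difference array, then per-bin base sums
    d <- numeric(len + 1L)
    add <- tabulate(f$start + 1L, nbins = len + 1L)
    sub <- tabulate(pmin(f$end, len) + 1L, nbins = len + 1L)
    depth <- cumsum(add - sub)[seq_len(len)]
    mass <- cumsum(depth)
    bnd <- pmin(seq_len(n_bins) * bin_size, len)
    bin_mass <- diff(c(0, mass[bnd]))
    values[[ch]] <- bin_mass / bin_size * scale
  }
  signal_track(values, genome, bin_size, strand = strand,
               norm_factor = scale)
}

count_namespace <- function(fragments, genome, namespace) {
  if (namespace == "target") {
    chroms <- norm_chroms(genome, "target")
  } else {
    chroms <- genome$chrom_names[genome$namespace == "spikein"]
  }
  sum(fragments$chrom %in% chroms)
}

#' Spike-in quantitative factors and the final normalization chain
#'
#' For each sample n, with fragment counts T_Rloop (R-loop library on the
#' target genome), T_input, S_Rloop and S_input (spike-in genome), the
#' quantitative factor is
#' `QF(n) = [T_Rloop(n) x S_input(n)] / [S_Rloop(n) x T_input(n)]`,
#' and the final normalization factor chains through the reference sample:
#' `FNF(n) = QF(n) x NF(ref) / QF(ref)`, where `NF(ref)` is the RPGC
#' factor of the reference sample's target R-loop fragments. The reference
#' sample's FNF is exactly its RPGC factor. Counts are fragments (pairs) on
#' non-ignored chromosomes.
#'
#' @param samples named list; each element a list with `rloop` and `input`
#'   `FragmentSet`s over the combined namespace.
#' @param genome the combined `GenomeRef`.
#' @param reference name or index of the reference sample (default first;
#'   the choice is reported by `print`).
#' @return a `QuantTable` data frame: raw counts, `QF` and `FNF` per
#'   sample, with the reference recorded in attributes.
#' @export
quant_factors <- function(samples, genome, reference = 1L) {
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  ref <- if (is.character(reference)) reference else names(samples)[reference]
  if (!ref %in% names(samples)) stop("unknown reference sample: ", reference)
  rows <- lapply(names(samples), function(nm) {
    s <- samples[[nm]]
    cnt <- as.numeric(c(
      T_rloop = count_namespace(s$rloop, genome, "target"),
      T_input = count_namespace(s$input, genome, "target"),
      S_rloop = count_namespace(s$rloop, genome, "spikein"),
      S_input = count_namespace(s$input, genome, "spikein")
    ))
    names(cnt) <- c("T_rloop", "T_input", "S_rloop", "S_input")
    zero <- names(cnt)[cnt == 0 & names(cnt) %in%
                         c("T_input", "S_rloop")]
    if (length(zero)) {
      stop("sample ", nm, ": zero ", paste(zero, collapse = ", "),
           " count, quantitative factor undefined")
    }
    data.frame(sample = nm, t(cnt))
  })
  tab <- do.call(rbind, rows)
  tab$QF <- tab$T_rloop * tab$S_input / (tab$S_rloop * tab$T_input)
  nf_ref <- rpgc_factor(samples[[ref]]$rloop, genome)
  qf_ref <- tab$QF[tab$sample == ref]
  tab$FNF <- tab$QF * nf_ref / qf_ref
  attr(tab, "reference") <- ref
  attr(tab, "NF_ref") <- nf_ref
  class(tab) <- c("QuantTable", "data.frame")
  tab
}

#' @export
print.QuantTable <- function(x, digits = 4, ...) {
  cat("Spike-in quantification (reference sample: ",
      attr(x, "reference"), ", RPGC factor ",
      format(attr(x, "NF_ref"), digits = digits), ")\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Relative total R-loop levels
#'
#' `level(n) = T_Rloop(n)/T_input(n) x S_input(n)/S_Rloop(n)`, reported
#' relative to the reference sample (reference = 1). Algebraically this is
#' `QF(n)/QF(ref)`: the input-normalized target signal calibrated by the
#' constant spike-in content.
#'
#' @param quant a `QuantTable` from [quant_factors()].
#' @param reference reference sample name; default the table's own.
#' @return named vector of relative levels.
#' @export
total_rloop_level <- function(quant, reference = attr(quant, "reference")) {
  stopifnot(inherits(quant, "QuantTable"))
  level <- quant$T_rloop / quant$T_input * quant$S_input / quant$S_rloop
  names(level) <- quant$sample
  if (!reference %in% names(level)) stop("unknown reference: ", reference)
  level / level[[reference]]
}
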