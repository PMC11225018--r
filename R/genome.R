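#' Genome reference with target/spike-in namespacing
#'
#' A `GenomeRef` is the coordinate frame used throughout the package: an
#' ordered set of chromosomes with lengths, an optional sequence set, a
#' namespace map assigning every chromosome to the target or the spike-in
#' genome, and a set of chromosomes excluded from depth normalization
#' (mitochondrial DNA by default, whose copy number varies between samples).
#'
#' All coordinates in the package are 0-based, half-open. Conversion to the
#' 1-based conventions of SAM and of Bioconductor ranges happens only at the
#' format boundary.
#'
#' @param sequences named character vector or `DNAStringSet` of chromosome
#'   sequences, or `NULL` if only lengths are known.
#' @param chrom_lengths named numeric vector of chromosome lengths; ignored
#'   when `sequences` is given.
#' @param spikein_chroms chromosome names belonging to the spike-in genome;
#'   everything else is target.
#' @param ignored_chroms chromosomes excluded from normalization counts
#'   (default `"chrM"`); names absent from the genome are dropped.
#' @return an object of class `GenomeRef`.
#' @export
genome_ref <- function(sequences = NULL, chrom_lengths = NULL,
                       spikein_chroms = character(),
                       ignored_chroms = "chrM") {
  if (!is.null(sequences)) {
    if (!methods::is(sequences, "DNAStringSet")) {
      sequences <- Biostrings::DNAStringSet(toupper(unlist(sequences)))
    }
    nm <- names(sequences)
    if (is.null(nm) || anyNA(nm) || any(nm == "")) {
      stop("every sequence must be named")
    }
    if (anyDuplicated(nm)) {
      stop("duplicate sequence name: ", nm[duplicated(nm)][1L])
    }
    chrom_lengths <- stats::setNames(Biostrings::width(sequences), nm)
  }
  if (is.null(chrom_lengths) || length(chrom_lengths) == 0L) {
    stop("a GenomeRef needs sequences or chromosome lengths")
  }
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1")
  nm <- names(chrom_lengths)
  unknown <- setdiff(spikein_chroms, nm)
  if (length(unknown)) {
    stop("spike-in chromosomes not in genome: ", paste(unknown, collapse = ", "))
  }
  namespace <- stats::setNames(
    ifelse(nm %in% spikein_chroms, "spikein", "target"), nm
  )
  obj <- structure(
    list(
      seq = sequences,
      chrom_names = nm,
      chrom_lengths = chrom_lengths,
      namespace = namespace,
      ignored_chroms = intersect(ignored_chroms, nm)
    ),
    class = "GenomeRef"
  )
  obj
}

#' @export
print.GenomeRef <- function(x, ...) {
  n_t <- sum(x$namespace == "target")
  n_s <- sum(x$namespace == "spikein")
  cat(sprintf(
    "GenomeRef: %d chromosome(s) (%d target, %d spike-in), %.0f bp total\n",
    length(x$chrom_names), n_t, n_s, sum(x$chrom_lengths)
  ))
  if (length(x$ignored_chroms)) {
    cat("  ignored for normalization:", paste(x$ignored_chroms, collapse = ", "), "\n")
  }
  if (is.null(x$seq)) cat("  (lengths only, no sequence attached)\n")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' Sequences are upper-cased on read; order is preserved.
#'
#' @param path FASTA file.
#' @inheritParams genome_ref
#' @return a `GenomeRef` with sequences attached.
#' @export
read_fasta <- function(path, spikein_chroms = character(),
                       ignored_chroms = "chrM") {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  # FASTA headers may carry descriptions; the identifier is the first word
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence name in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1L])
  }
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  genome_ref(sequences = seqs, spikein_chroms = spikein_chroms,
             ignored_chroms = ignored_chroms)
}

#' Write a genome to FASTA
#' @param genome a `GenomeRef` with sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "GenomeRef"))
  if (is.null(genome$seq)) stop("GenomeRef carries no sequences")
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

# chromosomes that enter normalization denominators
norm_chroms <- function(genome, namespace = "target") {
  keep <- genome$namespace == namespace &
    !(genome$chrom_names %in% genome$ignored_chroms)
  genome$chrom_names[keep]
}

# total bases of non-ignored chromosomes in one namespace
effective_genome_size <- function(genome, namespace = "target") {
  sum(genome$chrom_lengths[norm_chroms(genome, namespace)])
}

genome_sequence <- function(genome, chrom) {
  if (is.null(genome$seq)) stop("GenomeRef carries no sequences")
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  as.character(genome$seq[[chrom]])
}
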