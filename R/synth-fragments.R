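rtrunc_norm_len <- function(n, mean, sd, min_len = 30, max_len = Inf) {
  len <- round(stats::rnorm(n, mean, sd))
  pmin(pmax(len, min_len), max_len)
}

# snap positions to the nearest member of a sorted site vector
snap_nearest <- function(pos, sites) {
  i <- findInterval(pos, sites)
  lo <- sites[pmax(i, 1L)]
  hi <- sites[pmin(i + 1L, length(sites))]
  ifelse(i == 0L, hi,
         ifelse(i >= length(sites), lo,
                ifelse(pos - lo <= hi - pos, lo, hi)))
}

#' Simulate an R-loop fragment library over planted truth regions
#'
#' Each fragment is a signal draw with probability
#' `p_sig = enrichment * W / (enrichment * W + B)` — `W` the (weight-scaled)
#' planted bases, `B` the background bases of the namespace — or a uniform
#' background draw otherwise. Signal fragments take the planted region's
#' strand; background strands are random.
#'
#' Boundary models emulate the two fragmentation chemistries:
#' `"mbn"` (single-strand nuclease) excises the structure between its
#' duplex junctions, so both fragment ends snap to the planted region
#' boundaries plus Gaussian jitter (`mbn_sigma`, default 2 bp);
#' `"re"` (restriction digest) snaps every fragment end — signal and
#' background — to the nearest cut site of the given enzymes.
#'
#' @param genome a `GenomeRef` (sequences needed for the `"re"` model).
#' @param truth planted regions (`RegionSet`, `score` = enrichment weight);
#'   may be empty for pure-background libraries.
#' @param depth number of fragments to draw.
#' @param frag_len_mean,frag_len_sd background fragment length (truncated
#'   normal); defaults 250/50 match a 250 bp sonication target.
#' @param enrichment signal enrichment factor (>= 1).
#' @param boundary_model `"mbn"` or `"re"`.
#' @param mbn_sigma boundary jitter sd in bp for the mbn model (0 = exact).
#' @param enzymes list of [enzyme_spec()] for the `"re"` model.
#' @param cut_sites precomputed cut sites (`RegionSet`); computed from
#'   `enzymes` when missing.
#' @param rnaseh_null RNase-H-style null library: background-only sampling.
#' @param library,namespace labels for the emitted fragments.
#' @param seed RNG seed (optional).
#' @return a `FragmentSet`; attribute `"is_signal"` flags truth-derived
#'   fragments, attribute `"region"` gives the source region index (NA for
#'   background).
#' @export
simulate_fragments <- function(genome, truth, depth, frag_len_mean = 250,
                               frag_len_sd = 50, enrichment = 20,
                               boundary_model = c("mbn", "re"),
                               mbn_sigma = 2, enzymes = NULL,
                               cut_sites = NULL, rnaseh_null = FALSE,
                               library = "rloop", namespace = "target",
                               seed = NULL) {
  boundary_model <- match.arg(boundary_model)
  stopifnot(inherits(genome, "GenomeRef"), enrichment >= 1, depth >= 0)
  if (!is.null(seed)) set.seed(seed)
  chroms <- genome$chrom_names[genome$namespace == namespace]
  if (!length(chroms)) stop("no chromosomes in namespace ", namespace)
  clen <- genome$chrom_lengths[chroms]
  widths <- truth$end - truth$start
  W <- sum(widths * truth$score)
  B <- sum(clen) - sum(widths)
  p_sig <- if (rnaseh_null || W == 0) 0 else
    enrichment * W / (enrichment * W + B)
  n_sig <- stats::rbinom(1L, depth, p_sig)
  n_bg <- depth - n_sig

  sites <- NULL
  if (boundary_model == "re") {
    if (is.null(cut_sites)) {
      if (is.null(enzymes)) stop("re boundary model needs enzymes or cut_sites")
      cut_sites <- find_cut_sites(genome, enzymes)
    }
    sites <- split(cut_sites$start, cut_sites$chrom)
  }
  get_sites <- function(ch) {
    s <- sites[[ch]]
    if (is.null(s) || length(s) < 2L) {
      stop("no usable cut sites on chromosome ", ch)
    }
    s
  }

  # --- signal fragments -------------------------------------------------
  sig <- NULL
  if (n_sig > 0L) {
    ri <- sample.int(nrow(truth), n_sig, replace = TRUE,
                     prob = widths * truth$score)
    ch <- truth$chrom[ri]
    if (boundary_model == "mbn") {
      s <- truth$start[ri] + round(stats::rnorm(n_sig, 0, mbn_sigma))
      e <- truth$end[ri] + round(stats::rnorm(n_sig, 0, mbn_sigma))
      pad <- max(10, 6 * mbn_sigma)
      s <- pmax(pmax(s, truth$start[ri] - pad), 0)
      e <- pmin(pmin(e, truth$end[ri] + pad), clen[ch])
      e <- pmax(e, s + 1)
    } else {
      len <- rtrunc_norm_len(n_sig, frag_len_mean, frag_len_sd,
                             max_len = pmax(widths[ri], 30))
      s <- truth$start[ri] +
        floor(stats::runif(n_sig) * pmax(widths[ri] - len, 1))
      e <- pmin(s + len, truth$end[ri])
      for (c1 in unique(ch)) {
        sv <- get_sites(c1)
        k <- ch == c1
        s[k] <- snap_nearest(s[k], sv)
        e[k] <- snap_nearest(e[k], sv)
        deg <- k & (s >= e)
        if (any(deg)) {
          j <- pmin(findInterval(s[deg], sv) + 1L, length(sv))
          e[deg] <- sv[j]
          still <- deg & (s >= e)
          if (any(still)) {
            s[still] <- sv[pmax(findInterval(s[still], sv) - 1L, 1L)]
          }
        }
      }
    }
    sig <- data.frame(chrom = ch, start = s, end = e,
                      strand = truth$strand[ri], region = ri)
  }

  # --- background fragments --------------------------------------------
  bg <- NULL
  if (n_bg > 0L) {
    ch <- sample(chroms, n_bg, replace = TRUE, prob = clen)
    len <- rtrunc_norm_len(n_bg, frag_len_mean, frag_len_sd,
                           max_len = clen[ch] - 1)
    s <- floor(stats::runif(n_bg) * (clen[ch] - len))
    e <- s + len
    if (boundary_model == "re") {
      for (c1 in unique(ch)) {
        sv <- get_sites(c1)
        k <- ch == c1
        s[k] <- snap_nearest(s[k], sv)
        e[k] <- snap_nearest(e[k], sv)
        deg <- k & (s >= e)
        if (any(deg)) {
          j <- pmin(findInterval(s[deg], sv) + 1L, length(sv))
          e[deg] <- sv[j]
          still <- deg & (s >= e)
          if (any(still)) {
            s[still] <- sv[pmax(findInterval(s[still], sv) - 1L, 1L)]
          }
        }
      }
    }
    bg <- data.frame(chrom = ch, start = s, end = e,
                     strand = sample(c("+", "-"), n_bg, replace = TRUE),
                     region = NA_integer_)
  }

  all <- rbind(sig, bg)
  if (is.null(all)) all <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), strand = character(),
                                      region = integer())
  out <- fragment_set(all$chrom, all$start, all$end, strand = all$strand,
                      namespace = namespace, library = library)
  attr(out, "is_signal") <- !is.na(all$region)
  attr(out, "region") <- all$region
  attr(out, "p_sig") <- p_sig
  out
}

#' Combine a target and a spike-in genome into one reference
#'
#' @param target,spike `GenomeRef`s with disjoint chromosome names; all
#'   spike chromosomes become the `spikein` namespace.
#' @export
combine_genomes <- function(target, spike) {
  if (length(intersect(target$chrom_names, spike$chrom_names))) {
    stop("target and spike-in chromosome names must be disjoint")
  }
  seqs <- c(target$seq, spike$seq)
  g <- genome_ref(sequences = seqs, spikein_chroms = spike$chrom_names,
                  ignored_chroms = target$ignored_chroms)
  g$gc_content <- target$gc_content
  g
}

#' Simulate a spike-in quantification pair (R-loop + input library)
#'
#' Emulates the spike-in design: every sample receives the same foreign
#' genome at fixed R-loop content while the target's global R-loop level
#' varies. In the R-loop library, target fragments are drawn with total
#' weight proportional to `target_global_level` times the planted target
#' R-loop mass, spike-in fragments proportional to `spike_global_level`
#' times the spike R-loop mass. The input library samples both genomes
#' uniformly by genomic mass, ignoring the truth, with strand `"."`.
#' The ratio of two samples' `target_global_level` is the ground truth that
#' spike-in quantification must recover.
#'
#' @param genome combined reference from [combine_genomes()].
#' @param target_truth,spike_truth planted regions on the respective
#'   namespaces.
#' @param target_global_level,spike_global_level global R-loop levels (> 0).
#' @param depth_rloop,depth_input fragments per library (input must be > 0).
#' @param enrichment,frag_len_mean,frag_len_sd,boundary_model,mbn_sigma
#'   passed to [simulate_fragments()].
#' @param seed RNG seed (optional).
#' @return list with `rloop` and `input` `FragmentSet`s over the combined
#'   namespace and a `manifest` of all parameters.
#' @export
simulate_spikein_pair <- function(genome, target_truth, spike_truth,
                                  target_global_level,
                                  spike_global_level = 1,
                                  depth_rloop = 1e5, depth_input = 1e5,
                                  enrichment = 20, frag_len_mean = 250,
                                  frag_len_sd = 50, boundary_model = "mbn",
                                  mbn_sigma = 2, seed = NULL) {
  stopifnot(target_global_level > 0, spike_global_level > 0)
  if (depth_input <= 0) stop("zero-depth input library")
  if (depth_rloop <= 0) stop("zero-depth rloop library")
  if (!is.null(seed)) set.seed(seed)
  mass <- function(truth) sum((truth$end - truth$start) * truth$score)
  w_t <- target_global_level * mass(target_truth)
  w_s <- spike_global_level * mass(spike_truth)
  n_t <- stats::rbinom(1L, depth_rloop, w_t / (w_t + w_s))
  rl_t <- simulate_fragments(genome, target_truth, n_t,
                             frag_len_mean, frag_len_sd, enrichment,
                             boundary_model, mbn_sigma,
                             namespace = "target", library = "rloop")
  rl_s <- simulate_fragments(genome, spike_truth, depth_rloop - n_t,
                             frag_len_mean, frag_len_sd, enrichment,
                             boundary_model, mbn_sigma,
                             namespace = "spikein", library = "rloop")
  g_t <- sum(genome$chrom_lengths[genome$namespace == "target"])
  g_s <- sum(genome$chrom_lengths[genome$namespace == "spikein"])
  n_ti <- stats::rbinom(1L, depth_input, g_t / (g_t + g_s))
  in_t <- simulate_fragments(genome, target_truth[0, ], n_ti,
                             frag_len_mean, frag_len_sd,
                             rnaseh_null = TRUE, namespace = "target",
                             library = "input")
  in_s <- simulate_fragments(genome, spike_truth[0, ], depth_input - n_ti,
                             frag_len_mean, frag_len_sd,
                             rnaseh_null = TRUE, namespace = "spikein",
                             library = "input")
  rloop <- rbind(rl_t, rl_s)
  input <- rbind(in_t, in_s)
  input$strand <- "."
  class(rloop) <- class(input) <- c("FragmentSet", "data.frame")
  list(
    rloop = rloop, input = input,
    manifest = list(
      target_global_level = target_global_level,
      spike_global_level = spike_global_level,
      depth_rloop = depth_rloop, depth_input = depth_input,
      enrichment = enrichment, frag_len_mean = frag_len_mean,
      frag_len_sd = frag_len_sd, boundary_model = boundary_model,
      mbn_sigma = mbn_sigma, seed = seed
    )
  )
}

#' Write a simulated library to disk (BAM + truth BED + JSON manifest)
#'
#' @param fragments a `FragmentSet`.
#' @param genome the `GenomeRef` the fragments live on.
#' @param prefix output path prefix; writes `<prefix>.bam`,
#'   `<prefix>.truth.bed` (if truth given) and `<prefix>.manifest.json`.
#' @param truth optional truth `RegionSet`.
#' @param manifest optional named list of run parameters.
#' @param ... passed to [write_fragments_bam()].
#' @export
write_library <- function(fragments, genome, prefix, truth = NULL,
                          manifest = NULL, ...) {
  bam <- write_fragments_bam(fragments, genome, paste0(prefix, ".bam"), ...)
  if (!is.null(truth)) write_bed(truth, paste0(prefix, ".truth.bed"))
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, paste0(prefix, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(bam)
}
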