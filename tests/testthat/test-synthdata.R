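test_that("generated genomes hit the requested base composition", {
  g <- make_genome(c(chr1 = 10000), gc_content = 0.5, seed = 1,
                   ignored_chroms = character())
  s <- as.character(g$seq[["chr1"]])
  counts <- table(strsplit(s, "")[[1]])
  gc <- sum(counts[c("G", "C")]) / 10000
  # binomial 99.99% interval around 0.5 at n = 10000 is well inside this
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)

  # determinism
  g2 <- make_genome(c(chr1 = 10000), gc_content = 0.5, seed = 1,
                    ignored_chroms = character())
  expect_identical(as.character(g$seq), as.character(g2$seq))

  # GC-only limit
  g3 <- make_genome(c(chr1 = 1000), gc_content = 1, seed = 2,
                    ignored_chroms = character())
  expect_true(all(strsplit(as.character(g3$seq[[1]]), "")[[1]] %in% c("G", "C")))
})

test_that("planted regions carry the designed skew signature", {
  g0 <- make_genome(c(chr1 = 60000), gc_content = 0.5, seed = 3,
                    ignored_chroms = character())
  # zero skew: planted composition indistinguishable from background
  pl0 <- plant_rloops(g0, 5, c(1000, 2000), skew_strength = 0,
                      seed = 4)
  sk0 <- gc_skew(substring(as.character(pl0$genome$seq[[1]]),
                           pl0$truth$start + 1, pl0$truth$end))
  expect_lt(max(abs(sk0)), 0.1)

  # strong skew, forced + strand: measured skew near skew_strength
  pl <- plant_rloops(g0, 5, c(2000, 2000), strand_mix = 1,
                     skew_strength = 0.5, seed = 5)
  sk <- gc_skew(substring(as.character(pl$genome$seq[[1]]),
                          pl$truth$start + 1, pl$truth$end))
  expect_true(all(sk > 0.4 & sk < 0.6))

  # minus regions mirror: Watson-strand skew negative
  plm <- plant_rloops(g0, 5, c(2000, 2000), strand_mix = 0,
                      skew_strength = 0.5, seed = 6)
  skm <- gc_skew(substring(as.character(plm$genome$seq[[1]]),
                           plm$truth$start + 1, plm$truth$end))
  expect_true(all(skm < -0.4))

  # truth regions are in-bounds and strand-disjoint
  expect_true(all(pl$truth$end <= 60000 & pl$truth$start >= 0))
  gr <- rloopkit:::regions_to_granges(pl$truth)
  expect_equal(sum(IRanges::width(IRanges::reduce(IRanges::ranges(gr)))),
               sum(pl$truth$end - pl$truth$start))
})

test_that("fragment simulation respects the signal sampling probability", {
  pl <- planted_genome()
  fr <- simulate_fragments(pl$genome, pl$truth, depth = 1e5,
                           enrichment = 20, seed = 7)
  p <- attr(fr, "p_sig")
  obs <- mean(attr(fr, "is_signal"))
  # binomial sd at n = 1e5 is ~0.0016; allow 4 sd
  expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / 1e5))
  # signal fragments inherit the planted strand
  sig <- which(attr(fr, "is_signal"))
  reg <- attr(fr, "region")[sig]
  expect_true(all(fr$strand[sig] == pl$truth$strand[reg]))
})

test_that("RNase-H-style null libraries contain no truth-derived fragments", {
  pl <- planted_genome()
  fr <- simulate_fragments(pl$genome, pl$truth, depth = 5000,
                           enrichment = 20, rnaseh_null = TRUE, seed = 8)
  expect_equal(sum(attr(fr, "is_signal")), 0)
  expect_equal(nrow(fr), 5000)
})

test_that("restriction boundary model snaps every fragment end to a cut site", {
  pl <- planted_genome()
  mboi <- builtin_enzymes("MboI")
  cs <- find_cut_sites(pl$genome, mboi)
  fr <- simulate_fragments(pl$genome, pl$truth, depth = 2000,
                           enrichment = 20, boundary_model = "re",
                           enzymes = mboi, seed = 9)
  by_chr <- split(cs$start, cs$chrom)
  ok_start <- mapply(function(ch, s) s %in% by_chr[[ch]], fr$chrom, fr$start)
  ok_end <- mapply(function(ch, e) e %in% by_chr[[ch]], fr$chrom, fr$end)
  expect_true(all(ok_start))
  expect_true(all(ok_end))
  expect_true(all(fr$start < fr$end))
})

test_that("no cut sites on a chromosome is an error under the re model", {
  g <- make_genome(c(chr1 = 2000), gc_content = 1, seed = 10,
                   ignored_chroms = character())  # no GATC possible? force:
  # a GC-only genome cannot contain TTAA
  expect_error(
    simulate_fragments(g, region_set("chr1", 100, 600, strand = "+"),
                       depth = 100, boundary_model = "re",
                       enzymes = builtin_enzymes("MseI"), seed = 11),
    "cut sites"
  )
})

test_that("simulation is deterministic under a fixed seed", {
  pl <- planted_genome()
  a <- simulate_fragments(pl$genome, pl$truth, depth = 2000, seed = 12)
  b <- simulate_fragments(pl$genome, pl$truth, depth = 2000, seed = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(pl$truth, f1)
  write_bed(pl$truth, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("spike-in pairs honor their library contracts", {
  ref <- spikein_reference()
  pair <- simulate_spikein_pair(ref$genome, ref$target_truth,
                                ref$spike_truth, target_global_level = 1,
                                depth_rloop = 5000, depth_input = 5000,
                                seed = 13)
  expect_true(all(pair$input$strand == "."))
  expect_equal(nrow(pair$rloop), 5000)
  expect_equal(nrow(pair$input), 5000)
  expect_setequal(unique(pair$rloop$namespace), c("target", "spikein"))
  expect_error(
    simulate_spikein_pair(ref$genome, ref$target_truth, ref$spike_truth,
                          target_global_level = 1, depth_input = 0),
    "input"
  )
})

test_that("substrate reads follow the nuclease model", {
  des <- default_substrate_design()
  # spans partition the substrate; junction inside
  expect_equal(des$ds[2] - des$ds[1] + (des$h_end - des$h_start) +
                 (des$ss[2] - des$ss[1]), des$length)
  expect_equal(des$h_end - des$h_start, 203)
  expect_true(des$junction > 0 && des$junction < des$length)

  rd <- simulate_substrate_reads(des, "mbn", 500, seed = 14)
  expect_true(all(rd$watson_5p == des$h_start))
  expect_true(all(rd$crick_5p == des$h_end - 1))

  expect_equal(nrow(simulate_substrate_reads(des, "mbn", 0)), 0)

  rd2 <- simulate_substrate_reads(des, "noisy", 1000, sigma = 5, seed = 15)
  expect_gt(stats::sd(rd2$watson_5p), 1)
  expect_true(all(rd2$start < rd2$end))
})
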