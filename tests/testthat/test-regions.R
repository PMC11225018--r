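test_that("cut-site scanning handles offsets and degenerate motifs", {
  g <- genome_ref(
    sequences = Biostrings::DNAStringSet(c(a = paste0("AAGATCAA",
                                                      strrep("A", 992)))),
    ignored_chroms = character()
  )
  cs <- find_cut_sites(g, builtin_enzymes("MboI"), chroms = "a")
  expect_equal(cs$start[1], 2)  # ^GATC cuts at the motif start

  gd <- genome_ref(
    sequences = Biostrings::DNAStringSet(c(a = paste0("ACTGAGA",
                                                      strrep("T", 993)))),
    ignored_chroms = character()
  )
  csd <- find_cut_sites(gd, builtin_enzymes("DdeI"), chroms = "a")
  expect_equal(csd$start[1], 2)  # CTNAG matches CTGAG at 1, C^T offset 1

  none <- find_cut_sites(
    genome_ref(sequences = Biostrings::DNAStringSet(c(a = strrep("A", 1000))),
               ignored_chroms = character()),
    builtin_enzymes("MboI")
  )
  expect_equal(nrow(none), 0)

  expect_error(enzyme_spec("x", "GA", 1), "length")
  expect_error(enzyme_spec("x", "GATC", 5), "offset")
})

test_that("boundary distances bin as documented", {
  peaks <- region_set("a", 100, 300)
  sites <- region_set("a", c(97, 200, 350), c(98, 201, 351))
  bd <- boundary_distances(peaks, sites, extend = 5)
  # start 100 -> site 97 (d=3, bin 0); end 300 -> site 350 (d=50)
  expect_equal(sort(bd$distances), c(3, 50))
  expect_equal(unname(bd$counts[["0"]]), 1)
  expect_equal(bd$fraction_bin0, 0.5)
  expect_error(boundary_distances(peaks, region_set()), "empty")
})

test_that("the peak caller finds planted blocks and enforces the size filter", {
  pl <- planted_genome()
  fr <- simulate_fragments(pl$genome, pl$truth, depth = 5e4,
                           enrichment = 20, seed = 70)
  nf <- rpgc_factor(fr, pl$genome)
  tr <- coverage_track(fr, pl$genome, bin_size = 50, scale = nf)
  peaks <- call_peaks(tr, pl$genome, min_fold = 5)
  st <- peak_truth_stats(peaks, pl$truth)
  expect_gte(st$recall, 0.9)
  expect_gte(st$precision, 0.9)
  expect_true(all(peaks$end - peaks$start >= 200))

  # flat-zero track yields nothing
  g0 <- genome_ref(chrom_lengths = c(a = 10000), ignored_chroms = character())
  flat <- signal_track(list(a = numeric(200)), g0, bin_size = 50)
  expect_equal(nrow(call_peaks(flat, g0)), 0)

  # constant track at background yields nothing
  const <- signal_track(list(a = rep(1, 200)), g0, bin_size = 50)
  expect_equal(nrow(call_peaks(const, g0)), 0)

  # a 150 bp candidate dies, a 250 bp candidate survives min_size = 200
  v <- numeric(200)
  v[11:13] <- 50   # 150 bp at 50x
  v[41:45] <- 50   # 250 bp
  sz <- signal_track(list(a = v), g0, bin_size = 50)
  pk <- call_peaks(sz, g0, min_fold = 5, merge_gap = 0, min_size = 200)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$end - pk$start, 250)
})

test_that("strand-resolved peaks match the planted strand", {
  pl <- planted_genome()
  fr <- simulate_fragments(pl$genome, pl$truth, depth = 5e4,
                           enrichment = 20, seed = 71)
  nf <- rpgc_factor(fr, pl$genome)
  for (s in c("+", "-")) {
    tr <- coverage_track(fr, pl$genome, bin_size = 50, strand = s, scale = nf)
    pk <- call_peaks(tr, pl$genome, min_fold = 5)
    truth_s <- pl$truth[pl$truth$strand == s, ]
    class(truth_s) <- c("RegionSet", "data.frame")
    st <- peak_truth_stats(pk, truth_s)
    expect_gte(st$recall, 0.9)
    expect_gte(st$precision, 0.9)
    expect_true(all(pk$strand == s))
  }
})

test_that("compartment fractions are a priority-respecting partition", {
  fr <- fragment_set(
    chrom = c(rep("chrM", 5), rep("chr1", 5)),
    start = c(0, 10, 20, 30, 40, 100, 200, 300, 5000, 6000),
    end = c(9, 19, 29, 39, 49, 150, 260, 380, 5100, 6100)
  )
  comp <- list(
    mito = region_set("chrM", 0, 1000),
    rDNA = region_set("chr1", c(0, 5000), c(400, 5500))
  )
  cf <- compartment_fractions(fr, comp)
  expect_equal(unname(as.vector(cf$fractions)), c(0.5, 0.4, 0.1))
  expect_equal(sum(cf$fractions), 1)

  # overlap across priorities: highest priority wins
  comp2 <- list(mito = region_set("chrM", 0, 1000),
                all = region_set(c("chrM", "chr1"), c(0, 0), c(1e4, 1e4)))
  cf2 <- compartment_fractions(fr, comp2)
  expect_equal(unname(cf2$counts[["mito"]]), 5)

  # fuzz: fractions always sum to one
  set.seed(72)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    s <- sample(0:900, n, replace = TRUE)
    frz <- fragment_set(sample(c("chr1", "chrM"), n, TRUE), s, s + 10)
    cfz <- compartment_fractions(frz, comp)
    expect_equal(sum(cfz$fractions), 1)
    expect_equal(sum(cfz$counts), n)
  }
})

test_that("peak annotation partitions into promoter, gene body, intergenic", {
  genes <- region_set(c("a", "a"), c(5000, 12000), c(8000, 15000),
                      strand = c("+", "-"))
  peaks <- region_set(
    "a",
    c(4400, 6000, 100, 15300),
    c(4600, 6200, 300, 15700)
  )
  ann <- annotate_peaks(peaks, genes, promoter_flank = 1000)
  # midpoint 4500 is 500 bp upstream of the + TSS at 5000 -> promoter
  # midpoint 15500 is within 1 kb upstream of the - gene TSS at 15000
  expect_equal(ann$category, c("promoter", "gene_body", "intergenic",
                               "promoter"))
  expect_equal(sum(ann$counts), nrow(peaks))
  expect_error(annotate_peaks(peaks, region_set("a", 0, 10)), "stranded")
})

test_that("permutation test recognizes perfect nesting and rejects bad input", {
  g <- genome_ref(chrom_lengths = c(chr1 = 1e6), ignored_chroms = character())
  set.seed(73)
  starts <- sort(sample(seq(0, 9.9e5, by = 1e4), 20))
  reference <- region_set("chr1", starts, starts + 500)
  query <- reference  # fully nested, reference sparse (1% of genome)
  pt <- overlap_permutation_test(query, reference, g, n_perm = 999, seed = 74)
  expect_equal(pt$observed, 20)
  expect_lte(pt$p, 0.002)
  expect_gte(pt$p, 1 / 1000)
  expect_gt(pt$z, 3)

  expect_error(overlap_permutation_test(query, reference, g, n_perm = 0),
               "n_perm")
  big <- region_set("chr1", 0, 2e6 - 1)
  expect_error(overlap_permutation_test(big, reference,
                                        genome_ref(chrom_lengths = c(chr1 = 1e6),
                                                   ignored_chroms = character()),
                                        n_perm = 100),
               "longer")
})

test_that("signal metaprofiles behave on constant and enriched tracks", {
  g <- genome_ref(chrom_lengths = c(a = 1e5), ignored_chroms = character())
  const <- signal_track(list(a = rep(2.5, 2000)), g, bin_size = 50)
  regions <- region_set("a", c(10000, 50000), c(11000, 51000))
  mp <- signal_metaprofile(const, regions, flank = 1000, n_bins = 10)
  expect_true(all(abs(mp$profile$mean - 2.5) < 1e-12))
  expect_equal(mp$region_means, c(2.5, 2.5))

  # planted enrichment: central bins exceed flanks in center mode
  v <- rep(1, 2000)
  v[201:220] <- 20  # [10000, 11000)
  tr <- signal_track(list(a = v), g, bin_size = 50)
  one <- region_set("a", 10000, 11000)
  mpc <- signal_metaprofile(tr, one, flank = 1000, n_bins = 20)
  expect_gt(mean(mpc$profile$mean[9:12]), mean(mpc$profile$mean[c(1:2, 19:20)]))

  # scale-regions mode: body bins enriched over flank bins
  mps <- signal_metaprofile(tr, one, flank = 500, n_bins = 10,
                            mode = "scale-regions")
  nb <- length(mps$profile$mean)
  body <- mps$profile$mean[6:15]
  expect_true(all(body > mps$profile$mean[1:5]))
  expect_error(signal_metaprofile(tr, region_set(), 100, 10), "empty")
})

test_that("matched random controls preserve lengths and chromosomes exactly", {
  pl <- planted_genome()
  rnd <- matched_random_regions(pl$truth, pl$genome, seed = 75)
  expect_equal(sort(rnd$end - rnd$start),
               sort(pl$truth$end - pl$truth$start))
  expect_equal(table(rnd$chrom), table(pl$truth$chrom))
  expect_true(all(rnd$start >= 0 &
                    rnd$end <= pl$genome$chrom_lengths[rnd$chrom]))
})
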