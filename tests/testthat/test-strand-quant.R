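test_that("strand split is an exhaustive, convention-symmetric partition", {
  fr <- fragment_set(rep("a", 3), c(0, 10, 20), c(5, 15, 25),
                     strand = c("+", "+", "-"))
  sp <- split_strands(fr)
  expect_equal(nrow(sp$wR), 2)
  expect_equal(nrow(sp$cR), 1)
  expect_equal(sp$excluded, 0)
  expect_equal(nrow(sp$wR) + nrow(sp$cR) + sp$excluded, nrow(fr))

  # flipping the convention swaps the sets exactly
  sp2 <- split_strands(fr, strand_convention = "mate1-reverse")
  expect_equal(as.data.frame(sp2$wR), as.data.frame(sp$cR))
  expect_equal(as.data.frame(sp2$cR), as.data.frame(sp$wR))

  # unstranded fragments in an rloop library: warned, counted, excluded
  fr2 <- fragment_set(rep("a", 3), c(0, 10, 20), c(5, 15, 25),
                      strand = c("+", ".", "-"))
  expect_warning(sp3 <- split_strands(fr2), "unstranded")
  expect_equal(sp3$excluded, 1)
  expect_equal(nrow(sp3$wR) + nrow(sp3$cR) + sp3$excluded, nrow(fr2))
})

test_that("RPGC factor normalizes mean coverage to exactly one", {
  g <- genome_ref(chrom_lengths = c(a = 1000), ignored_chroms = character())
  fr <- fragment_set("a", 100, 600)  # one 500 bp fragment
  expect_equal(rpgc_factor(fr, g), 2.0)
  tr <- coverage_track(fr, g, bin_size = 10, scale = rpgc_factor(fr, g))
  expect_equal(mean(unlist(tr$values)), 1.0)

  # duplicating every fragment halves the factor, mean still one
  fr2 <- rbind(fr, fr)
  class(fr2) <- class(fr)
  expect_equal(rpgc_factor(fr2, g), 1.0)
  tr2 <- coverage_track(fr2, g, bin_size = 10, scale = rpgc_factor(fr2, g))
  expect_equal(mean(unlist(tr2$values)), 1.0)
})

test_that("ignored chromosomes never touch the RPGC factor", {
  g <- genome_ref(chrom_lengths = c(chr1 = 1000, chrM = 500))
  on_m <- fragment_set("chrM", 0, 100)
  expect_error(rpgc_factor(on_m, g), "non-ignored")
  both <- fragment_set(c("chr1", "chrM"), c(0, 0), c(500, 100))
  only1 <- fragment_set("chr1", 0, 500)
  expect_equal(rpgc_factor(both, g), rpgc_factor(only1, g))
  expect_equal(rpgc_factor(only1, g), 1000 / 500)
})

test_that("coverage tracks conserve fragment mass across binnings", {
  g <- genome_ref(chrom_lengths = c(a = 100), ignored_chroms = character())
  fr <- fragment_set("a", 0, 10, strand = "+")
  t10 <- coverage_track(fr, g, bin_size = 10)
  expect_equal(t10$values$a[1], 1.0)
  t5 <- coverage_track(fr, g, bin_size = 5)
  expect_equal(t5$values$a[1:2], c(1.0, 1.0))

  # mass conservation under arbitrary fragments and scales
  set.seed(40)
  s <- sample(0:80, 50, replace = TRUE)
  frs <- fragment_set(rep("a", 50), s, s + sample(1:20, 50, replace = TRUE),
                      strand = sample(c("+", "-"), 50, TRUE))
  for (bs in c(1, 7, 10)) {
    tr <- coverage_track(frs, g, bin_size = bs, scale = 3)
    expect_equal(sum(unlist(tr$values)) * bs,
                 sum(frs$end - frs$start) * 3)
  }
  # strand filter: + track only counts + fragments
  trp <- coverage_track(frs, g, bin_size = 10, strand = "+")
  expect_equal(sum(unlist(trp$values)) * 10,
               sum((frs$end - frs$start)[frs$strand == "+"]))
})

test_that("quantitative factor follows the count formula and its invariances", {
  g <- genome_ref(chrom_lengths = c(chr1 = 1000, spk = 500),
                  spikein_chroms = "spk", ignored_chroms = character())
  mk <- function(t_r, t_i, s_r, s_i) {
    list(
      rloop = fragment_set(
        c(rep("chr1", t_r), rep("spk", s_r)),
        seq_len(t_r + s_r) - 1, seq_len(t_r + s_r) + 99, strand = "+"
      ),
      input = fragment_set(
        c(rep("chr1", t_i), rep("spk", s_i)),
        seq_len(t_i + s_i) - 1, seq_len(t_i + s_i) + 99
      )
    )
  }
  q <- quant_factors(list(s1 = mk(100, 10, 20, 10)), g)
  expect_equal(q$QF, (100 * 10) / (20 * 10))  # = 5
  # reference sample: FNF equals its own RPGC factor exactly
  expect_equal(q$FNF, attr(q, "NF_ref"))

  # rescaling the rloop library depth by k leaves QF unchanged
  q2 <- quant_factors(list(s1 = mk(300, 10, 60, 10)), g)
  expect_equal(q2$QF, q$QF)
  # rescaling the input library depth by k leaves QF unchanged
  q3 <- quant_factors(list(s1 = mk(100, 30, 20, 30)), g)
  expect_equal(q3$QF, q$QF)

  # zero denominator is a named error
  expect_error(quant_factors(list(bad = mk(100, 10, 0, 10)), g), "S_rloop")
})

test_that("relative total levels are reciprocal under reference swap", {
  ref <- spikein_reference()
  samples <- lapply(c(a = 1, b = 2), function(r) {
    simulate_spikein_pair(ref$genome, ref$target_truth, ref$spike_truth,
                          target_global_level = r,
                          depth_rloop = 2e4, depth_input = 2e4,
                          seed = 50 + 10 * r)
  })
  q <- quant_factors(samples, ref$genome, reference = "a")
  lev_a <- total_rloop_level(q)
  expect_equal(unname(lev_a[["a"]]), 1.0)
  lev_b <- total_rloop_level(q, reference = "b")
  expect_equal(unname(lev_b[["a"]]), 1 / unname(lev_a[["b"]]))
})
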