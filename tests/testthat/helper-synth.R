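# shared synthetic fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# small target genome with planted mixed-strand R-loops
planted_genome <- function() {
  fixture("planted", function() {
    g0 <- make_genome(c(chr1 = 3e5, chrM = 2e4), gc_content = 0.41,
                      seed = 101)
    pl <- plant_rloops(g0, n_regions = 12, length_range = c(800, 1500),
                       skew_strength = 0.4, seed = 102)
    pl
  })
}

# combined target + spike-in reference with planted truth on both
spikein_reference <- function() {
  fixture("spikein", function() {
    gt <- make_genome(c(chr1 = 4e5, chrM = 2e4), seed = 201)
    gs <- make_genome(c(spk1 = 1e5), gc_content = 0.36, seed = 202,
                      ignored_chroms = character())
    pt <- plant_rloops(gt, 15, c(800, 1500), seed = 203)
    ps <- plant_rloops(gs, 6, c(600, 1200), seed = 204)
    list(genome = combine_genomes(pt$genome, ps$genome),
         target_truth = pt$truth, spike_truth = ps$truth)
  })
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# independent nested-loop implementation of the fuzzy c-means updates,
# consuming the RNG exactly like fuzzy_cmeans(n_start = 1) does at init
fcm_oracle <- function(x, c, m, tol = 1e-6, max_iter = 200, seed = 1) {
  set.seed(seed)
  n <- nrow(x)
  p <- ncol(x)
  u <- matrix(stats::rexp(n * c), n, c)
  u <- u / rowSums(u)
  for (iter in seq_len(max_iter)) {
    v <- matrix(0, c, p)
    for (k in seq_len(c)) {
      num <- rep(0, p)
      den <- 0
      for (i in seq_len(n)) {
        w <- u[i, k]^m
        num <- num + w * x[i, ]
        den <- den + w
      }
      v[k, ] <- num / den
    }
    u_new <- matrix(0, n, c)
    for (i in seq_len(n)) {
      d2 <- rep(0, c)
      for (k in seq_len(c)) d2[k] <- sum((x[i, ] - v[k, ])^2)
      if (any(d2 < .Machine$double.eps)) {
        u_new[i, which(d2 < .Machine$double.eps)[1L]] <- 1
      } else {
        for (k in seq_len(c)) {
          u_new[i, k] <- 1 / sum((d2[k] / d2)^(1 / (m - 1)))
        }
      }
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  list(u = u, v = v)
}

# planted six-profile stage dynamics with Gaussian noise
planted_stage_matrix <- function(n_per = 40, noise = 0.3, seed = 11) {
  set.seed(seed)
  profiles <- rbind(
    c(3, 1, 0, 0, 0), c(0, 3, 1, 0, 0), c(0, 0, 3, 1, 0),
    c(0, 0, 0, 3, 1), c(1, 0, 0, 0, 3), c(2, 2, 0, 2, 2)
  )
  x <- do.call(rbind, lapply(seq_len(nrow(profiles)), function(k) {
    matrix(rep(profiles[k, ], each = n_per), n_per)
  }))
  x <- rloopkit:::standardize_rows(x) +
    matrix(stats::rnorm(length(x), 0, noise), nrow(x))
  list(x = rloopkit:::standardize_rows(x),
       labels = rep(seq_len(nrow(profiles)), each = n_per),
       profiles = rloopkit:::standardize_rows(profiles))
}

# agreement of hard labels with truth under the best cluster matching
label_agreement <- function(truth, labels) {
  tab <- table(truth, labels)
  sum(apply(tab, 1, max)) / length(truth)
}
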