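# small panmictic simulation shared across tests in this file
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- scenario_clean_split(75, haplotypes_per_deme = 2L,
                                 chrom_length_bp = 2e6, n_chrom = 2L)
      sp$demes <- sp$demes["pop1"]
      sp$events <- list()
      sp$samples <- c(pop1 = 4L)
      cache <<- list(spec = sp,
                     files = simulate_sequences(sp, seed = 5,
                                                out_dir = tempfile("simcache")))
    }
    cache
  }
})

test_that("simulation is reproducible and readable", {
  s <- sim_small()
  again <- simulate_sequences(s$spec, seed = 5, out_dir = tempfile())
  expect_identical(readLines(s$files[1]), readLines(again[1]))
  rec <- read_multihetsep(s$files[1])
  expect_equal(imtracer:::n_haplotypes(rec), 4L)
  expect_true(all(diff(rec$pos) > 0))
})

test_that("panmictic heterozygosity is close to 4 N mu", {
  s <- sim_small()
  het <- 0; len <- 0
  for (f in s$files) {
    rec <- read_multihetsep(f)
    het <- het + sum(substr(rec$alleles, 1, 1) != substr(rec$alleles, 2, 2))
    len <- len + s$spec$chrom_length_bp
  }
  pi_hat <- het / len
  expect_gt(pi_hat, 1e-3 * 0.7)
  expect_lt(pi_hat, 1e-3 * 1.3)
})

test_that("isolated demes show higher cross- than within-pair divergence", {
  sp <- scenario_clean_split(300, haplotypes_per_deme = 1L,
                             chrom_length_bp = 2e6, n_chrom = 1L)
  sp$samples <- c(pop1 = 2L, pop2 = 2L)
  f <- simulate_sequences(sp, seed = 9, out_dir = tempfile())
  rec <- read_multihetsep(f[1])
  d <- function(i, j)
    sum(substr(rec$alleles, i, i) != substr(rec$alleles, j, j))
  within <- (d(1, 2) + d(3, 4)) / 2
  cross <- (d(1, 3) + d(1, 4) + d(2, 3) + d(2, 4)) / 4
  expect_gt(cross, within)
})

test_that("switch errors at rate zero are the identity", {
  s <- sim_small()
  out <- inject_switch_errors(s$files, 0, seed = 1, out_dir = tempfile())
  expect_identical(readLines(out[1]), readLines(s$files[1]))
})

test_that("switch counts scale with rate and two swaps restore phase", {
  s <- sim_small()
  rec <- read_multihetsep(s$files[1])
  # high-rate corruption changes many records; determinism under the seed
  out1 <- inject_switch_errors(s$files[1], 5e-4, seed = 3,
                               out_dir = tempfile())
  out2 <- inject_switch_errors(s$files[1], 5e-4, seed = 3,
                               out_dir = tempfile())
  expect_identical(readLines(out1[1]), readLines(out2[1]))
  corr <- read_multihetsep(out1[1])
  expect_equal(nrow(corr), nrow(rec))
  changed <- mean(corr$alleles != rec$alleles)
  expect_gt(changed, 0.05)
  # involution: swapping haplotypes of individual 1 twice restores them
  once <- imtracer:::swap_alleles(rec$alleles, 1L, 2L, rep(TRUE, nrow(rec)))
  twice <- imtracer:::swap_alleles(once, 1L, 2L, rep(TRUE, nrow(rec)))
  expect_identical(twice, rec$alleles)
})

test_that("switch count matches the Poisson expectation", {
  # one individual, long chromosome: expected switches = rate * length
  s <- sim_small()
  rate <- 2e-4
  L <- max(read_multihetsep(s$files[1])$pos)
  counts <- vapply(1:20, function(seed) {
    out <- inject_switch_errors(s$files[1], rate, seed = seed,
                                out_dir = tempfile())
    corr <- read_multihetsep(out[1])
    orig <- read_multihetsep(s$files[1])
    # runs of changed records correspond to odd parity stretches; count
    # parity flips as a proxy for switch points seen by the data
    sum(diff(c(FALSE, corr$alleles != orig$alleles)) != 0)
  }, numeric(1))
  lambda <- 2 * rate * L  # two individuals in a 4-haplotype file
  expect_gt(mean(counts), lambda * 0.5)
  expect_lt(mean(counts), lambda * 1.5)
})
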