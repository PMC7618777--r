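test_that("make_reference satisfies all pairing and segment constraints", {
  for (seed in c(1, 7, 123)) {
    ref <- make_reference(seed)
    ch <- strsplit(ref$seq, "")[[1]]
    expect_equal(ref$length, 45)
    expect_equal(substr(ref$seq, 22, 27), "AUUGAU")
    expect_equal(ch[c(6, 41)], c("G", "C"))
    expect_equal(ch[c(7, 40)], c("G", "C"))
    expect_equal(ch[c(8, 39)], c("C", "G"))
    expect_equal(ch[c(10, 36)], c("G", "C"))
    expect_equal(ch[c(11, 35)], c("C", "U"))
    expect_equal(ch[c(16, 34)], c("U", "A"))
    expect_equal(ch[c(18, 30)], c("G", "C"))
  }
  expect_identical(make_reference(9)$seq, make_reference(9)$seq)
  expect_false(make_reference(1)$seq == make_reference(2)$seq)
})

test_that("selection simulator is seed-deterministic and neutral when flat", {
  ref <- toy_ref()
  genos <- c("wt", enumerate_mutants(ref, 1)$genotype[1:9])
  freq <- setNames(rep(0.1, 10), genos)
  flat <- setNames(rep(0, 10), genos)
  spec <- landscape_sim_spec(ref, flat, freq, read_depth = 1e5, replicates = 2, seed = 11)
  a <- simulate_selection_round(spec)
  b <- simulate_selection_round(spec)
  expect_identical(a, b)
  # neutral landscape: post consistent with pre (chi-square on frequencies)
  one <- a[a$replicate == 1, ]
  pre <- one$count[one$round == "pre"]
  post <- one$count[one$round == "post"]
  expect_gt(suppressWarnings(stats::chisq.test(rbind(pre, post))$p.value), 0.001)
  # replicates differ (independent substreams)
  expect_false(identical(a$count[a$replicate == 1], a$count[a$replicate == 2]))
})

test_that("selection reweighting converges to the closed form with depth", {
  ref <- reference_sequence("GGCAU")
  # two genotypes, f_wt = 0, f_v = -1 (base 2), equal input: post ratio 2:1
  fit <- c(wt = 0, C3A = -1)
  freq <- c(wt = 0.5, C3A = 0.5)
  get_ratio <- function(depth) {
    spec <- landscape_sim_spec(ref, fit, freq, read_depth = depth, replicates = 1, seed = 5)
    cts <- simulate_selection_round(spec)
    post <- cts[cts$round == "post", ]
    post$count[post$genotype == "C3A"] / post$count[post$genotype == "wt"]
  }
  # infinite-depth limit is exactly 0.5; a depth sweep must close in on it
  err <- vapply(c(1e3, 1e5), function(d) abs(get_ratio(d) - 0.5), numeric(1))
  expect_lt(err[2], 0.01)
  expect_lte(err[2], err[1])
  # fitness missing for a library genotype is a specification error
  expect_error(
    landscape_sim_spec(ref, c(wt = 0), freq, seed = 1),
    "fitness missing"
  )
  expect_error(
    landscape_sim_spec(ref, fit, c(wt = 0.6, C3A = 0.5), seed = 1),
    "sum to 1"
  )
})

test_that("product simulator respects error, wobble and stall parameters", {
  ref <- qt_ref()
  # no errors, no stalling: all reads perfect full length
  clean <- simulate_products(product_sim_spec(ref$seq, 9,
    triplet_error_rate = 0, stall_prob = 0, n_reads = 50, seed = 2
  ))
  expect_true(all(clean$seq == ref$seq))

  # stall 0.5 with 4 triplets: full length requires passing 3 internal
  # junctions, so the expected full-length fraction is 0.5^3
  tmpl <- substr(ref$seq, 1, 9 + 12)
  st <- simulate_products(product_sim_spec(tmpl, 9,
    triplet_error_rate = 0, stall_prob = 0.5, n_reads = 4000, seed = 3
  ))
  frac_full <- mean(nchar(st$seq) == nchar(tmpl))
  se <- sqrt(0.125 * 0.875 / 4000)
  expect_lt(abs(frac_full - 0.125), 3 * se)
  # length distribution is geometric over triplet counts
  n_trip <- (nchar(st$seq) - 9) / 3
  obs <- table(factor(n_trip, levels = 1:4))
  expected <- 4000 * c(0.5, 0.25, 0.125, 0.125)
  expect_gt(stats::chisq.test(obs, p = expected / 4000)$p.value, 0.001)

  # per-position error rate recovered within 3 binomial SD
  err <- simulate_products(product_sim_spec(ref$seq, 9,
    triplet_error_rate = 0.059, stall_prob = 0, n_reads = 10000, seed = 4
  ))
  calls <- qtsuite:::calls_matrix(align_products(err, ref$seq, 9)$calls)
  rates <- colMeans(calls[, 10:45] != "=")
  se <- sqrt(0.059 * 0.941 / 10000)
  expect_true(all(abs(rates - 0.059) < 3 * se + 1e-12))
})

test_that("timecourse generator follows the closed form and clips to [0,1]", {
  tc0 <- simulate_timecourse(0.8, 0.05, c(0, 10, 1e6), noise_sd = 0, seed = 1)
  expect_equal(tc0$y[1], 0)
  expect_equal(tc0$y[3], 0.8, tolerance = 1e-12)
  tc1 <- simulate_timecourse(1, log(2), 1, noise_sd = 0, seed = 1)
  expect_equal(tc1$y, 0.5)
  noisy <- simulate_timecourse(0.99, 0.1, seq(0, 100, 2), noise_sd = 0.3, seed = 2)
  expect_true(all(noisy$y >= 0 & noisy$y <= 1))
  expect_error(simulate_timecourse(0.5, 0.1, c(-1, 2)), "non-negative")
})
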