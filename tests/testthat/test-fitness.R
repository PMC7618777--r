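test_that("count_genotypes tallies classified reads and pools the rest", {
  ref <- toy_ref()
  mut <- ref$seq
  substr(mut, 3, 3) <- "A" # C3A
  triple <- ref$seq
  substr(triple, 1, 1) <- "A"
  substr(triple, 5, 5) <- "C"
  substr(triple, 9, 9) <- "C"
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:10),
    seq = c(rep(ref$seq, 5), rep(mut, 3), rep(triple, 2))
  )
  cts <- count_genotypes(reads, ref)
  expect_equal(cts$count[cts$genotype == "wt"], 5)
  expect_equal(cts$count[cts$genotype == "C3A"], 3)
  expect_equal(cts$count[cts$genotype == "other"], 2)

  # file round trip through FASTQ
  tmp <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, tmp)
  expect_equal(count_genotypes(tmp, ref), cts)
  expect_error(count_genotypes("no/such/file.fq", ref), "no such file")
})

test_that("log-normalized enrichment matches the closed formula", {
  ref <- toy_ref()
  # neutral variant: identical pre/post ratios to wt
  cts <- counts_from_vectors(
    pre = c(wt = 1000, G1A = 100), post = c(wt = 2000, G1A = 200)
  )
  ft <- compute_fitness(cts, ref, pseudocount = 0, min_count = 1)
  expect_equal(ft$f_mean[ft$genotype == "G1A"], 0)
  expect_equal(ft$f_mean[ft$genotype == "wt"], 0)

  # doubling relative to wt is +1 at base 2
  cts2 <- counts_from_vectors(
    pre = c(wt = 1000, G1A = 100), post = c(wt = 1000, G1A = 200)
  )
  ft2 <- compute_fitness(cts2, ref, pseudocount = 0, min_count = 1)
  expect_equal(ft2$f_mean[ft2$genotype == "G1A"], 1)

  # dropout with pseudocount 0.5: log2((0.5/1000.5)/(100.5/1000.5))
  cts3 <- counts_from_vectors(
    pre = c(wt = 1000, G1A = 100), post = c(wt = 1000, G1A = 0)
  )
  ft3 <- compute_fitness(cts3, ref, pseudocount = 0.5, min_count = 1)
  expect_equal(ft3$f_mean[ft3$genotype == "G1A"], log2(0.5 / 100.5),
    tolerance = 1e-12
  )
  expect_equal(round(ft3$f_mean[ft3$genotype == "G1A"], 2), -7.65)

  # wt must be present
  bad <- counts_from_vectors(pre = c(G1A = 10), post = c(G1A = 10))
  expect_error(compute_fitness(bad, ref), "wild type absent")
})

test_that("fitness is invariant to uniform depth rescaling at zero pseudocount", {
  ref <- toy_ref()
  cts <- counts_from_vectors(
    pre = c(wt = 500, G1A = 60, G2C = 40), post = c(wt = 800, G1A = 30, G2C = 90)
  )
  scaled <- dplyr::mutate(cts, count = .data$count * 10)
  f1 <- compute_fitness(cts, ref, pseudocount = 0, min_count = 1)
  f2 <- compute_fitness(scaled, ref, pseudocount = 0, min_count = 1)
  expect_equal(f1$f_mean, f2$f_mean, tolerance = 1e-12)
})

test_that("min_count filters low-coverage genotypes from the pre table", {
  ref <- toy_ref()
  cts <- counts_from_vectors(
    pre = c(wt = 1000, G1A = 9, G2C = 50), post = c(wt = 1000, G1A = 9, G2C = 50)
  )
  ft <- compute_fitness(cts, ref, min_count = 10)
  expect_false("G1A" %in% ft$genotype)
  expect_true("G2C" %in% ft$genotype)
})

test_that("replicate correlations behave under identity, shift, and simulation", {
  ref <- toy_ref()
  f <- seq(-5, 1, length.out = 8)
  genos <- enumerate_mutants(ref, 1)$genotype[1:8]
  ft <- tibble::tibble(
    genotype = c("wt", genos), class = c("wt", rep("single_sub", 8)),
    f_rep1 = c(0, f), f_rep2 = c(0, f), f_rep3 = c(0, f + 0.7)
  )
  ft$f_mean <- rowMeans(ft[c("f_rep1", "f_rep2", "f_rep3")])
  class(ft) <- c("fitness_table", class(ft))
  rc <- replicate_correlation(ft)
  expect_equal(rc$r[rc$rep_a == "f_rep1" & rc$rep_b == "f_rep2"], 1)
  # constant offset leaves Pearson r at 1
  expect_equal(rc$r[rc$rep_a == "f_rep1" & rc$rep_b == "f_rep3"], 1)
  expect_error(replicate_correlation(ft[1:3, ]), "fewer than 3")
})

test_that("simulated triplicates recover the true landscape", {
  ref <- qt_ref()
  land <- simulate_true_landscape(ref, seed = 21)
  keep <- land$class %in% c("wt", "single_sub", "single_del")
  genos <- land$genotype[keep]
  freq <- c(
    setNames(0.1, "wt"),
    setNames(rep(0.9 / (length(genos) - 1), length(genos) - 1), setdiff(genos, "wt"))
  )
  spec <- landscape_sim_spec(ref, land, freq,
    read_depth = 1e5, replicates = 3, seed = 22
  )
  ft <- compute_fitness(simulate_selection_round(spec), ref)

  # replicate agreement
  rc <- replicate_correlation(ft)
  expect_true(all(rc$r > 0.9))

  # parameter recovery: r > 0.95 against truth (all input frequencies ≥ 1e-4)
  truth <- setNames(land$f_true, land$genotype)
  est <- ft[ft$class != "wt", ]
  expect_gt(cor(est$f_mean, truth[est$genotype]), 0.95)

  # near-unbiased in the well-measured range: mean error within 3 SE
  mid <- est[truth[est$genotype] > -6, ]
  errs <- mid$f_mean - truth[mid$genotype]
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))

  # coverage of the mutant universe
  cov <- coverage(ft, ref)
  expect_equal(cov$coverage[cov$class == "single_sub"], 1)
  expect_equal(cov$coverage[cov$class == "double_sub"], 0)
  # counting oracle: 8346 of 8910 doubles measured is ~93.7%
  expect_equal(round(8346 / (choose(45, 2) * 9), 3), 0.937)
})

test_that("heatmap long format splits double mutants into constituent axes", {
  ref <- toy_ref()
  ft <- mini_table(c(wt = 0, G1A = -1, G2C = -2, "G1A+G2C" = -2.5), ref)
  hm <- fitness_heatmap_data(ft)
  expect_equal(nrow(hm), 1)
  expect_equal(hm$mutation_1, "G1A")
  expect_equal(hm$mutation_2, "G2C")
  expect_equal(hm$f_mean, -2.5)
})
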