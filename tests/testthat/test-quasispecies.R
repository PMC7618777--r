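test_that("mutation matrix is exact on small cases and column-stochastic", {
  ref <- reference_sequence("GG")
  ft <- mini_table(c(
    wt = 0, G1A = -1, G1C = -1, G1U = -1,
    G2A = -1, G2C = -1, G2U = -1
  ), ref)
  m <- qs_model(ft, ref, q = 0.9)
  M <- build_mutation_matrix(m)
  # hand enumeration at L = 2: P(wt -> specific single) = 0.9 * 0.1/3
  expect_equal(M["G1A", "wt"], 0.9 * 0.1 / 3, tolerance = 1e-12)
  expect_equal(M["wt", "wt"], 0.81, tolerance = 1e-12)
  # single -> single at the other position: (0.1/3)^2 * ... distance 2
  expect_equal(M["G2A", "G1A"], (0.1 / 3)^2 * 9 / 9, tolerance = 1e-12)
  expect_equal(colSums(M), rep(1, 8), ignore_attr = TRUE)

  # q = 1 collapses to the identity
  M1 <- build_mutation_matrix(qs_model(ft, ref, q = 1))
  expect_equal(unname(M1), diag(8))

  # column sums stay exactly 1 for random fitness tables on the 45-mer
  ref45 <- qt_ref()
  land <- simulate_true_landscape(ref45, 5)
  small <- truth_table(land[land$class %in% c("wt", "single_sub"), ])
  Mr <- build_mutation_matrix(qs_model(small, ref45, q = 0.93))
  expect_lt(max(abs(colSums(Mr) - 1)), 1e-9)
  expect_error(qs_model(small, ref45, q = 1.2), "\\[0, 1\\]")
})

test_that("stationary state solves known fixed points", {
  # two-genotype model: w = (2, 1), P(master->mutant) = 0.3, no back mutation
  M <- matrix(c(0.7, 0.3, 0, 1), 2, 2, dimnames = list(c("m", "v"), c("m", "v")))
  st <- stationary_distribution(M, w = c(2, 1), active = c(TRUE, FALSE))
  expect_equal(st$frequencies$frequency, c(0.4, 0.6), tolerance = 1e-9)
  expect_equal(st$active_fraction, 0.4, tolerance = 1e-9)

  # perfect copying: all mass on the fittest genotype
  ref <- reference_sequence("GG")
  ft <- mini_table(c(wt = 0, G1A = -1, G2C = -2), ref)
  s1 <- stationary_distribution(qs_model(ft, ref, q = 1))
  fr <- setNames(s1$frequencies$frequency, s1$frequencies$genotype)
  expect_equal(fr[["wt"]], 1, tolerance = 1e-9)

  # uniform fitness: stationary equals the mutation matrix's leading
  # eigenvector (independent eigen-decomposition oracle)
  ftu <- mini_table(c(
    wt = 0, G1A = 0, G1C = 0, G1U = 0, G2A = 0, G2C = 0, G2U = 0
  ), ref)
  mu <- qs_model(ftu, ref, q = 0.8, other_fitness = 0)
  M2 <- build_mutation_matrix(mu)
  st2 <- stationary_distribution(mu)
  ev <- eigen(M2)
  lead <- abs(Re(ev$vectors[, which.max(Re(ev$values))]))
  expect_equal(st2$frequencies$frequency, lead / sum(lead), tolerance = 1e-8)
})

test_that("the stationary state is a fixed point of the dynamics", {
  ref <- qt_ref()
  land <- simulate_true_landscape(ref, 5)
  ft <- truth_table(land[land$class %in% c("wt", "single_sub"), ])
  m <- qs_model(ft, ref, q = 0.95)
  st <- stationary_distribution(m)
  M <- build_mutation_matrix(m)
  w <- c(2^m$fitness, 2^m$other_fitness)
  x <- st$frequencies$frequency
  y <- as.vector(M %*% (w * x))
  y <- y / sum(y)
  expect_lt(max(abs(y - x)), 1e-10)
})

test_that("active fraction rises monotonically with copying fidelity", {
  ref <- qt_ref()
  land <- simulate_true_landscape(ref, 5)
  ft <- truth_table(land[land$class %in% c("wt", "single_sub"), ])
  sweep <- qs_sweep(ft, ref, c(0.9, 0.926, 0.941, 0.974, 0.99))
  expect_true(all(diff(sweep$active_fraction) > 0))
  # low-fidelity regime keeps the active population far below the
  # high-fidelity regime (the error-threshold signature)
  expect_lt(
    sweep$active_fraction[sweep$q == 0.926],
    sweep$active_fraction[sweep$q == 0.974] / 3
  )
})

test_that("error-threshold formulas match their closed forms", {
  expect_warning(l0 <- eigen_threshold(1, 0.95), "cannot dominate")
  expect_equal(l0, 0)
  expect_equal(eigen_threshold(exp(1), 0.974), 1 / 0.026, tolerance = 1e-12)
  expect_equal(required_fidelity(2, 45), 2^(-1 / 45), tolerance = 1e-12)
  expect_equal(round(required_fidelity(2, 45), 4), 0.9847)
  # the two forms agree at the threshold: L_max at q_min(L) returns ~L
  q <- required_fidelity(exp(1), 50)
  expect_equal(eigen_threshold(exp(1), q), 1 / (1 - q), tolerance = 1e-12)
})
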