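test_that("alignment calls matches, substitutions, truncations, and tails", {
  ref <- qt_ref()
  expected <- ref$seq

  perfect <- align_product(expected, expected, 9)
  expect_equal(perfect$length_reached, 45)
  expect_equal(perfect$calls, strrep("=", 45))
  expect_false(perfect$rejected)

  trunc <- align_product(substr(expected, 1, 18), expected, 9)
  expect_equal(trunc$length_reached, 18)
  expect_equal(trunc$calls, paste0(strrep("=", 18), strrep(".", 27)))

  # one substitution at synthesized position 5 (product position 14)
  sub <- expected
  old <- substr(sub, 14, 14)
  alt <- setdiff(c("A", "C", "G", "U"), old)[1]
  substr(sub, 14, 14) <- alt
  res <- align_product(sub, expected, 9)
  expect_equal(substr(res$calls, 14, 14), alt)
  expect_equal(gsub("[^=]", "", res$calls), strrep("=", 44))

  # tail-bearing (recombination) read is flagged and stripped
  tailed <- align_product(paste0(expected, "GGCC"), expected, 9, tail = "GGCC")
  expect_true(tailed$has_tail)
  expect_equal(tailed$length_reached, 45)

  # an internal deletion is found by the semi-global path (position 16 sits
  # between distinct neighbours, so the gap placement is unambiguous)
  deleted <- paste0(substr(expected, 1, 15), substr(expected, 17, 45))
  resd <- align_product(deleted, expected, 9)
  expect_true(resd$has_indel)
  expect_equal(substr(resd$calls, 16, 16), "-")

  # junk reads fail the identity floor
  junk <- align_product(strrep("A", 45), expected, 9)
  expect_true(junk$rejected)
  expect_error(align_product("ACGU", "ACG", 9), "beyond the primer")
})

test_that("positional fidelity counts errors per covered position", {
  ref <- qt_ref()
  expected <- ref$seq
  mut <- expected
  substr(mut, 20, 20) <- setdiff(c("A", "C", "G", "U"), substr(expected, 20, 20))[1]
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:10),
    seq = c(rep(expected, 9), mut)
  )
  aln <- align_products(reads, expected, 9)
  prof <- fidelity_profile(aln, 45, 9)
  expect_equal(prof$positional$fidelity[prof$positional$position == 20], 0.9)
  expect_true(all(prof$positional$fidelity[prof$positional$position != 20] == 1))
  expect_equal(prof$perfect_full_length_fraction, 0.9)
  expect_equal(prof$n_full_length, 10)

  allp <- fidelity_profile(align_products(reads[1:9, ], expected, 9), 45, 9)
  expect_equal(allp$average_fidelity, 1)
  expect_equal(allp$perfect_full_length_fraction, 1)
  expect_error(
    fidelity_profile(align_products(reads[10, ], expected, 9), 99, 9),
    "no full-length"
  )
})

test_that("fidelity pipeline recovers generating accuracy and wobble bias", {
  ref <- qt_ref()
  spec <- product_sim_spec(ref$seq, 9,
    triplet_error_rate = 0.05, wobble_bias = 0.8,
    stall_prob = 0.05, n_reads = 10000, seed = 31
  )
  aln <- align_products(simulate_products(spec), ref$seq, 9)
  prof <- fidelity_profile(aln, 45, 9)
  n <- prof$n_full_length
  se <- sqrt(0.95 * 0.05 / n)
  # every position within 3 binomial SD of the generating accuracy
  expect_true(all(abs(prof$positional$fidelity - 0.95) < 3 * se))
  expect_lt(abs(prof$average_fidelity - 0.95), 3 * se)
  # arithmetic and geometric means nearly coincide at high fidelity
  prof_a <- fidelity_profile(aln, 45, 9, method = "arithmetic")
  expect_lt(abs(prof_a$average_fidelity - prof$average_fidelity), 1e-3)

  # perfect-full-length fraction consistent with q^N
  q_n <- prof$average_fidelity^36
  se_p <- sqrt(q_n * (1 - q_n) / n)
  expect_lt(abs(prof$perfect_full_length_fraction - q_n), 3 * se_p + 0.01)

  # wobble bias recovered at wobble-capable positions
  spect <- error_spectrum(aln, ref$seq, 9)
  se_w <- sqrt(0.8 * 0.2 / sum(spect$matrix[c("A", "C"), ]))
  expect_lt(abs(spect$wobble_fraction - 0.8), 3 * se_w)
  expect_equal(sum(diag(spect$matrix)), 0)
  expect_true(all(spect$per_triplet_index$rate > 0))
})

test_that("error spectrum handles the no-substitution and single-sub cases", {
  ref <- qt_ref()
  reads <- tibble::tibble(read_id = "r1", seq = ref$seq)
  spect <- error_spectrum(align_products(reads, ref$seq, 9), ref$seq, 9)
  expect_equal(spect$n_substitutions, 0)
  expect_true(is.na(spect$wobble_fraction))

  # a lone A->G substitution is wobble-type by definition
  apos <- 9 + which(strsplit(substr(ref$seq, 10, 45), "")[[1]] == "A")[1]
  mut <- ref$seq
  substr(mut, apos, apos) <- "G"
  s2 <- error_spectrum(
    align_products(tibble::tibble(read_id = "r1", seq = mut), ref$seq, 9),
    ref$seq, 9
  )
  expect_equal(s2$wobble_fraction, 1)
  expect_equal(s2$overall_wobble_share, 1)
  expect_equal(s2$matrix["A", "G"], 1)
})

test_that("stalling profile exposes error-triggered terminal-triplet infidelity", {
  ref <- qt_ref()
  # misincorporation-triggered stalling: terminal rate must exceed internal
  spec <- product_sim_spec(ref$seq, 9,
    triplet_error_rate = 0.08, wobble_bias = 0.5,
    stall_prob = 0.1, stall_after_error_prob = 0.6,
    n_reads = 6000, seed = 41
  )
  aln <- align_products(simulate_products(spec), ref$seq, 9)
  st <- stalling_profile(aln, 45, 9)
  rates <- setNames(st$rates$rate, st$rates$region)
  expect_gt(rates["terminal_triplet"], rates["internal_triplets"])
  expect_gt(st$n_intermediate, 0)

  # uniform stalling gives a geometric triplet-length histogram
  spec_u <- product_sim_spec(ref$seq, 9,
    triplet_error_rate = 0, stall_prob = 0.3, n_reads = 6000, seed = 42
  )
  aln_u <- align_products(simulate_products(spec_u), ref$seq, 9)
  hist <- stalling_profile(aln_u, 45, 9)$histogram
  p_geom <- c(0.3 * 0.7^(0:10), 0.7^11)
  obs <- hist$n_reads[match(1:12, hist$n_triplets)]
  obs[is.na(obs)] <- 0
  expect_gt(stats::chisq.test(obs, p = p_geom)$p.value, 0.001)
})
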