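# Seeded generators emulating every input the pipeline consumes: a
# constrained 45-nt reference, one round of fitness-proportional selection
# with multinomial sequencing sampling, triplet-wise product synthesis with
# wobble-biased errors and stalling, and noisy exponential time courses.

# Stem pairs supported by compensatory evidence in the ribozyme core
# (5' position, 3' position, 5' nucleotide, 3' nucleotide). C11-U35 is the
# non-canonical pair and is not Watson-Crick.
QT_STEM_PAIRS <- data.frame(
  i = c(6, 7, 8, 10, 11, 16, 18),
  j = c(41, 40, 39, 36, 35, 34, 30),
  nt_i = c("G", "G", "C", "G", "C", "U", "G"),
  nt_j = c("C", "C", "G", "C", "U", "A", "C"),
  stringsAsFactors = FALSE
)

# (+)-strand apical-loop segment fixed by the defined hexamer substrate
QT_HEXAMER_SEGMENT <- list(start = 22, seq = "AUUGAU")

#' Canonical Watson-Crick stem pairs of the 45-nt reference
#'
#' The six G-C/A-U pairs used when planting compensatory epistasis in
#' simulated landscapes (the seventh, non-canonical C-U pair is excluded).
#'
#' @return Tibble with columns `i`, `j` (1-based paired positions).
#' @export
reference_stem_pairs <- function() {
  wc <- QT_STEM_PAIRS[paste0(QT_STEM_PAIRS$nt_i, QT_STEM_PAIRS$nt_j) %in%
    c("AU", "UA", "GC", "CG"), ]
  tibble::tibble(i = wc$i, j = wc$j)
}

#' Build a constrained synthetic 45-nt reference
#'
#' Produces a 45-nt RNA satisfying the structural constraints established for
#' the ribozyme: seven stem pairings (positions 6-41, 7-40, 8-39, 10-36,
#' 11-35, 16-34, 18-30 with their published identities) and the fixed
#' apical-loop segment AUUGAU at positions 22-27. All remaining positions are
#' filled pseudo-randomly from the seed, so the output is deterministic per
#' seed. The true ribozyme sequence is not published in machine-readable
#' form; this synthetic stand-in preserves the constraints the analyses rely
#' on.
#'
#' @param seed Integer seed.
#' @param name Reference name.
#' @return A [reference_sequence()] of length 45.
#' @examples
#' ref <- make_reference(1)
#' substr(ref$seq, 22, 27) # "AUUGAU"
#' @export
make_reference <- function(seed = 1L, name = "QT45-synthetic") {
  L <- 45L
  chars <- rep(NA_character_, L)
  for (k in seq_len(nrow(QT_STEM_PAIRS))) {
    chars[QT_STEM_PAIRS$i[k]] <- QT_STEM_PAIRS$nt_i[k]
    chars[QT_STEM_PAIRS$j[k]] <- QT_STEM_PAIRS$nt_j[k]
  }
  hex <- strsplit(QT_HEXAMER_SEGMENT$seq, "", fixed = TRUE)[[1]]
  idx <- QT_HEXAMER_SEGMENT$start + seq_along(hex) - 1
  stopifnot(all(is.na(chars[idx]) | chars[idx] == hex))
  chars[idx] <- hex
  free <- which(is.na(chars))
  chars[free] <- withr::with_seed(seed, sample(RNA_ALPHABET, length(free), replace = TRUE))
  reference_sequence(paste(chars, collapse = ""), name = name)
}

# Derive independent substream seeds from one master seed; kept below 2^31.
substream_seed <- function(seed, k) {
  (as.numeric(seed) * 1009 + 97 * as.numeric(k)) %% 2147483629
}

# ---- true landscape ---------------------------------------------------------

#' Simulate a ground-truth fitness landscape
#'
#' Generates per-genotype log-scale fitness for the wild type (0 by
#' definition), all single substitutions, all single deletions and all double
#' substitutions. The simulated regime mirrors the measured one: a sharp
#' fitness peak where most mutations are strongly deleterious (singles
#' spanning roughly -11 to +1.6, doubles down to about -14.5), predominantly
#' negative epistasis, and compensatory (positive) epistasis planted on the
#' six Watson-Crick stem pairs for allele combinations that restore
#' complementarity.
#'
#' @param ref A [reference_sequence()].
#' @param seed Integer seed.
#' @param single_range Range of single-substitution fitness (log scale).
#' @param deleterious_fraction Fraction of single mutants drawn from the
#'   strongly deleterious part of the range.
#' @param epistasis_mean,epistasis_sd Mean and SD of background epistasis
#'   added to double mutants (negative mean gives the negative bias).
#' @param compensatory_bonus Epistasis added to complementarity-restoring
#'   doubles at planted stem pairs.
#' @param pairs Tibble of planted pairs (columns `i`, `j`); defaults to
#'   [reference_stem_pairs()].
#' @param include_wobble_restoring Treat G:U as restoring when planting the
#'   compensatory bonus.
#' @return Tibble with columns `genotype`, `class`, `f_true`.
#' @export
simulate_true_landscape <- function(ref, seed = 1L,
                                    single_range = c(-11, 1.6),
                                    deleterious_fraction = 0.75,
                                    epistasis_mean = -0.4,
                                    epistasis_sd = 0.3,
                                    compensatory_bonus = 2,
                                    pairs = reference_stem_pairs(),
                                    include_wobble_restoring = TRUE) {
  ref <- as_reference(ref)
  singles <- enumerate_mutants(ref, 1)
  doubles <- enumerate_mutants(ref, 2)
  withr::with_seed(seed, {
    n1 <- nrow(singles)
    deep <- runif(n1) < deleterious_fraction
    f1 <- ifelse(
      deep,
      runif(n1, single_range[1], -2),
      runif(n1, -2, single_range[2])
    )
    # deletions skew strongly deleterious: frameshift-like register loss
    del <- singles$class == "single_del"
    f1[del] <- pmin(f1[del], runif(sum(del), single_range[1], -4))
    singles$f_true <- f1

    f_single <- setNames(singles$f_true, singles$genotype)
    parts <- strsplit(doubles$genotype, "+", fixed = TRUE)
    m1 <- vapply(parts, `[`, character(1), 1)
    m2 <- vapply(parts, `[`, character(1), 2)
    eps <- rnorm(nrow(doubles), epistasis_mean, epistasis_sd)
    restoring <- planted_restoring(m1, m2, pairs, include_wobble_restoring)
    eps[restoring] <- eps[restoring] + compensatory_bonus
    doubles$f_true <- f_single[m1] + f_single[m2] + eps
  })
  dplyr::bind_rows(
    tibble::tibble(genotype = "wt", class = "wt", f_true = 0),
    singles, doubles
  )
}

# TRUE where a double mutant hits a planted pair with complementary alleles
planted_restoring <- function(m1, m2, pairs, include_wobble) {
  pos1 <- as.integer(gsub("[^0-9]", "", m1))
  pos2 <- as.integer(gsub("[^0-9]", "", m2))
  alt1 <- substring(m1, nchar(m1))
  alt2 <- substring(m2, nchar(m2))
  key <- paste(pos1, pos2)
  planted <- key %in% paste(pairs$i, pairs$j)
  planted & nt_complementary(alt1, alt2, include_wobble)
}

nt_complementary <- function(a, b, include_wobble = TRUE) {
  combo <- paste0(a, b)
  wc <- combo %in% c("AU", "UA", "GC", "CG")
  if (include_wobble) wc | combo %in% c("GU", "UG") else wc
}

# ---- selection round --------------------------------------------------------

#' Specify a selection-round simulation
#'
#' @param reference A [reference_sequence()].
#' @param true_fitness Named numeric vector (or tibble with `genotype`,
#'   `f_true`): log-scale fitness per genotype, wild type 0.
#' @param library_frequencies Named numeric vector of input-library
#'   frequencies summing to 1 (tolerance 1e-9).
#' @param read_depth Reads drawn per table.
#' @param replicates Number of independent replicates.
#' @param seed Integer master seed.
#' @param log_base Base on which `true_fitness` is expressed (default 2):
#'   survival weight is `log_base ^ f`.
#' @return A validated list of class `landscape_sim_spec`.
#' @export
landscape_sim_spec <- function(reference, true_fitness, library_frequencies,
                               read_depth = 1e5, replicates = 3, seed = 1L,
                               log_base = 2) {
  if (is.data.frame(true_fitness)) {
    true_fitness <- setNames(true_fitness$f_true, true_fitness$genotype)
  }
  stopifnot(read_depth > 0, replicates >= 1, log_base > 0, log_base != 1)
  if (abs(sum(library_frequencies) - 1) > 1e-9) {
    stop("library frequencies must sum to 1 (tolerance 1e-9)")
  }
  if (any(library_frequencies < 0)) stop("library frequencies must be non-negative")
  missing <- setdiff(names(library_frequencies), names(true_fitness))
  if (length(missing) > 0) {
    stop(
      "fitness missing for library genotypes: ",
      paste(head(missing, 5), collapse = ", ")
    )
  }
  structure(
    list(
      reference = as_reference(reference), true_fitness = true_fitness,
      library_frequencies = library_frequencies, read_depth = read_depth,
      replicates = replicates, seed = seed, log_base = log_base
    ),
    class = "landscape_sim_spec"
  )
}

#' Simulate one round of activity selection with sequencing sampling
#'
#' Pre-selection counts are a multinomial draw of `read_depth` reads from the
#' library frequencies. Selection reweights each genotype's frequency by
#' `log_base ^ fitness` (fitness-proportional survival), and post-selection
#' counts are a second multinomial draw. Replicates use independent
#' substreams derived from the master seed, so reruns are byte-identical.
#'
#' @param spec A [landscape_sim_spec()].
#' @return Tibble with columns `replicate`, `round` ("pre"/"post"),
#'   `genotype`, `count`.
#' @export
simulate_selection_round <- function(spec) {
  stopifnot(inherits(spec, "landscape_sim_spec"))
  freq <- spec$library_frequencies
  w <- spec$log_base^spec$true_fitness[names(freq)]
  post_freq <- freq * w
  post_freq <- post_freq / sum(post_freq)
  purrr::map_dfr(seq_len(spec$replicates), function(r) {
    withr::with_seed(substream_seed(spec$seed, r), {
      pre <- as.integer(rmultinom(1, spec$read_depth, freq))
      post <- as.integer(rmultinom(1, spec$read_depth, post_freq))
    })
    tibble::tibble(
      replicate = r,
      round = rep(c("pre", "post"), each = length(freq)),
      genotype = rep(names(freq), 2),
      count = c(pre, post)
    )
  })
}

# ---- product synthesis ------------------------------------------------------

#' Specify a triplet-synthesis product simulation
#'
#' @param template Expected full-length product (RNA string), primer prefix
#'   included; the synthesized region (after the primer) must be a whole
#'   number of triplets.
#' @param primer_len Length of the supplied primer prefix (copied without
#'   error).
#' @param triplet_error_rate Per-synthesized-position substitution
#'   probability.
#' @param wobble_bias Fraction of substitutions that are wobble-type (product
#'   G opposite template U, i.e. expected A; product U opposite template G,
#'   i.e. expected C). At expected G or U, where no wobble product exists,
#'   errors are uniform over the three alternatives.
#' @param stall_prob Probability of stopping at each triplet junction (before
#'   each triplet after the first).
#' @param stall_after_error_prob Additional stall probability applied at the
#'   junction following a triplet that contains at least one misincorporation
#'   (models the purifying effect of error-induced stalling).
#' @param tail_seq Optional tail appended to a read (recombination product).
#' @param tail_prob Probability a full-length read carries the tail.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @return A validated list of class `product_sim_spec`.
#' @export
product_sim_spec <- function(template, primer_len,
                             triplet_error_rate = 0.074,
                             wobble_bias = 0.7,
                             stall_prob = 0.2,
                             stall_after_error_prob = 0,
                             tail_seq = NULL, tail_prob = 0,
                             n_reads = 1000, seed = 1L) {
  if (!grepl("^[ACGU]+$", template)) stop("template contains non-RNA characters")
  synth_len <- nchar(template) - primer_len
  if (synth_len <= 0 || synth_len %% 3 != 0) {
    stop("synthesized region (template minus primer) must be a positive multiple of 3")
  }
  probs <- c(triplet_error_rate, wobble_bias, stall_prob, stall_after_error_prob, tail_prob)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  structure(
    list(
      template = template, primer_len = primer_len,
      triplet_error_rate = triplet_error_rate, wobble_bias = wobble_bias,
      stall_prob = stall_prob, stall_after_error_prob = stall_after_error_prob,
      tail_seq = tail_seq, tail_prob = tail_prob,
      n_reads = n_reads, seed = seed
    ),
    class = "product_sim_spec"
  )
}

wobble_product <- c(A = "G", C = "U", G = NA, U = NA)

#' Simulate triplet-polymerase product reads
#'
#' Each read starts with the primer, then grows triplet by triplet. Before
#' each triplet after the first, synthesis stops with `stall_prob` (plus
#' `stall_after_error_prob` if the previous triplet contained an error). Each
#' synthesized position is miscopied with `triplet_error_rate`; wrong calls
#' are wobble-type with probability `wobble_bias` where a wobble product
#' exists, otherwise uniform over the remaining letters.
#'
#' @param spec A [product_sim_spec()].
#' @return Tibble with columns `read_id`, `seq`, `n_errors`, `has_tail`.
#' @export
simulate_products <- function(spec) {
  stopifnot(inherits(spec, "product_sim_spec"))
  tmpl <- strsplit(spec$template, "", fixed = TRUE)[[1]]
  n_trip <- (length(tmpl) - spec$primer_len) %/% 3
  primer <- paste(tmpl[seq_len(spec$primer_len)], collapse = "")
  withr::with_seed(spec$seed, {
    reads <- character(spec$n_reads)
    n_errors <- integer(spec$n_reads)
    has_tail <- logical(spec$n_reads)
    for (i in seq_len(spec$n_reads)) {
      synth <- character(0)
      errs <- 0L
      prev_triplet_err <- FALSE
      for (t in seq_len(n_trip)) {
        if (t > 1) {
          p_stop <- spec$stall_prob +
            if (prev_triplet_err) spec$stall_after_error_prob else 0
          if (runif(1) < min(p_stop, 1)) break
        }
        pos <- spec$primer_len + (t - 1) * 3 + 1:3
        trip <- tmpl[pos]
        wrong <- runif(3) < spec$triplet_error_rate
        if (any(wrong)) {
          trip[wrong] <- vapply(trip[wrong], miscall_nt, character(1),
            wobble_bias = spec$wobble_bias
          )
          errs <- errs + sum(wrong)
        }
        prev_triplet_err <- any(wrong)
        synth <- c(synth, trip)
      }
      s <- paste0(primer, paste(synth, collapse = ""))
      tl <- FALSE
      if (!is.null(spec$tail_seq) && length(synth) == 3 * n_trip &&
        runif(1) < spec$tail_prob) {
        s <- paste0(s, spec$tail_seq)
        tl <- TRUE
      }
      reads[i] <- s
      n_errors[i] <- errs
      has_tail[i] <- tl
    }
  })
  tibble::tibble(
    read_id = sprintf("read_%06d", seq_len(spec$n_reads)),
    seq = reads, n_errors = n_errors, has_tail = has_tail
  )
}

miscall_nt <- function(expected, wobble_bias) {
  wb <- wobble_product[[expected]]
  if (!is.na(wb) && runif(1) < wobble_bias) {
    return(wb)
  }
  pool <- setdiff(RNA_ALPHABET, expected)
  if (!is.na(wb) && wobble_bias > 0) pool <- setdiff(pool, wb)
  sample(pool, 1)
}

# ---- time courses -----------------------------------------------------------

#' Simulate a noisy bounded-exponential time course
#'
#' Generates `y = A * (1 - exp(-k t)) + noise`, clipped to the unit interval
#' (fraction cleaved).
#'
#' @param A Plateau fraction in (0, 1].
#' @param k Rate per minute (> 0).
#' @param times Non-negative times in minutes.
#' @param noise_sd Gaussian noise SD (fraction).
#' @param replicates Number of replicate traces.
#' @param seed Integer seed.
#' @return Tibble with columns `replicate`, `time`, `y`.
#' @export
simulate_timecourse <- function(A, k, times, noise_sd = 0, replicates = 1,
                                seed = 1L) {
  stopifnot(A > 0, A <= 1, k > 0)
  if (any(times < 0)) stop("times must be non-negative")
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(replicates), function(r) {
      y <- A * (1 - exp(-k * times)) + rnorm(length(times), 0, noise_sd)
      tibble::tibble(replicate = r, time = times, y = pmin(pmax(y, 0), 1))
    })
  })
}
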