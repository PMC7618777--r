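# Probability that a random sequence pool contains the functional motif,
# from per-position tolerated-nucleotide sets derived from the fitness
# landscape.

#' Per-position tolerated-nucleotide sets
#'
#' Position `i` tolerates nucleotide `n` when `n` is the wild-type base or
#' the single mutant at `i` to `n` has mean fitness at or above `cutoff`.
#' Unmeasured single mutants are treated as intolerant and counted in the
#' output. The default cutoff matches the quasispecies activity threshold so
#' one notion of "functional" is shared across modules.
#'
#' @param table A `fitness_table` containing single mutants.
#' @param ref The [reference_sequence()].
#' @param cutoff Fitness cutoff (default -1).
#' @return Object of class `tolerance_profile`: tibble with `position`,
#'   `ref_nt`, `tolerated` (string, e.g. "AG"), `n_tolerated`,
#'   `n_unmeasured`; attribute `fitness_cutoff`.
#' @export
tolerance_profile <- function(table, ref, cutoff = -1) {
  ref <- as_reference(ref)
  rc <- ref_chars(ref)
  singles <- table[table$class == "single_sub", ]
  if (nrow(singles) == 0) stop("fitness table contains no single mutants")
  f <- setNames(singles$f_mean, singles$genotype)
  out <- purrr::map_dfr(seq_len(ref$length), function(p) {
    alts <- setdiff(RNA_ALPHABET, rc[p])
    labs <- format_substitution(p, rc[p], alts)
    measured <- labs %in% names(f)
    tol_set <- c(rc[p], alts[measured & f[labs] >= cutoff])
    tol_set <- RNA_ALPHABET[RNA_ALPHABET %in% tol_set]
    tibble::tibble(
      position = p, ref_nt = rc[p],
      tolerated = paste(tol_set, collapse = ""),
      n_tolerated = length(tol_set),
      n_unmeasured = sum(!measured)
    )
  })
  n_un <- sum(out$n_unmeasured)
  if (n_un > 0) {
    message(n_un, " unmeasured single mutants treated as intolerant")
  }
  attr(out, "fitness_cutoff") <- cutoff
  class(out) <- c("tolerance_profile", class(out))
  out
}

#' Motif abundance in random sequence pools
#'
#' The probability that a uniformly random sequence matches the motif at one
#' placement is the product of per-position tolerated fractions,
#' `P = prod(|tolerated_i| / 4)`. With a pool of longer sequences, the
#' expected number of placements per molecule multiplies by
#' `pool_length - motif_length + 1` sliding windows.
#'
#' @param profile A [tolerance_profile()].
#' @param pool_length Optional pool sequence length (must be at least the
#'   motif length).
#' @return One-row tibble: `p_motif`, `log10_p_motif`, `n_placements`,
#'   `p_pool` (NA when `pool_length` is absent).
#' @examples
#' # 27 fully constrained positions among 45: (1/4)^27 ~ 5.6e-17
#' @export
motif_abundance <- function(profile, pool_length = NULL) {
  L <- nrow(profile)
  p <- prod(profile$n_tolerated / 4)
  lp <- sum(log10(profile$n_tolerated / 4))
  if (is.null(pool_length)) {
    placements <- NA_integer_
    p_pool <- NA_real_
  } else {
    if (pool_length < L) stop("pool_length shorter than the motif")
    placements <- as.integer(pool_length - L + 1)
    p_pool <- p * placements
  }
  tibble::tibble(
    p_motif = p, log10_p_motif = lp,
    n_placements = placements, p_pool = p_pool
  )
}

#' Size of RNA sequence space
#'
#' Number of distinct RNA sequences of a given length, `4^length`.
#'
#' @param length Sequence length in nucleotides.
#' @return `4^length` as a double.
#' @examples
#' sequence_space_size(40) # ~1.2e24
#' @export
sequence_space_size <- function(length) {
  stopifnot(length >= 0)
  4^length
}
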