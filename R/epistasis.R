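# Pairwise epistasis from a fitness table and compensatory evidence scoring
# for secondary-structure (base-pair) inference.

#' Pairwise epistasis of double mutants
#'
#' For each measured double mutant, epistasis is the deviation of its fitness
#' from additivity of the constituent singles: `epsilon = f_ij - f_i - f_j`
#' (all on the replicate-mean scale). Doubles whose constituent single is
#' unmeasured are skipped with a message, not an error.
#'
#' @param table A `fitness_table` from [compute_fitness()] containing singles
#'   and doubles.
#' @return Tibble with one row per double mutant: `pos_i`, `alt_i`, `pos_j`,
#'   `alt_j`, `mut_i`, `mut_j`, `f_i`, `f_j`, `f_ij`, `epsilon`, sorted by
#'   position pair then alleles.
#' @export
compute_epistasis <- function(table) {
  singles <- table[table$class == "single_sub", ]
  doubles <- table[table$class == "double_sub", ]
  if (nrow(doubles) == 0) stop("fitness table contains no double mutants")
  f_single <- setNames(singles$f_mean, singles$genotype)
  parts <- strsplit(doubles$genotype, "+", fixed = TRUE)
  m1 <- vapply(parts, `[`, character(1), 1)
  m2 <- vapply(parts, `[`, character(1), 2)
  f1 <- f_single[m1]
  f2 <- f_single[m2]
  skipped <- is.na(f1) | is.na(f2)
  if (any(skipped)) {
    message(sum(skipped), " double mutants skipped (constituent single unmeasured)")
  }
  out <- tibble::tibble(
    pos_i = as.integer(gsub("[^0-9]", "", m1)),
    alt_i = substring(m1, nchar(m1)),
    pos_j = as.integer(gsub("[^0-9]", "", m2)),
    alt_j = substring(m2, nchar(m2)),
    mut_i = m1, mut_j = m2,
    f_i = unname(f1), f_j = unname(f2), f_ij = doubles$f_mean,
    epsilon = doubles$f_mean - unname(f1) - unname(f2)
  )[!skipped, ]
  dplyr::arrange(out, .data$pos_i, .data$pos_j, .data$alt_i, .data$alt_j)
}

#' Base-pair evidence from compensatory epistasis
#'
#' For every position pair the nine double-mutant allele combinations are
#' partitioned into complementarity-restoring (the two alternative alleles
#' can pair with each other by Watson-Crick rules, optionally also G:U
#' wobble) versus non-restoring. The evidence score is the mean epistasis of
#' restoring doubles minus the mean of non-restoring doubles: a paired stem
#' position shows positive (compensatory) epistasis only when
#' complementarity is restored, so true pairs score high. Pairs with no
#' restoring combination measured are excluded.
#'
#' @param records Epistasis tibble from [compute_epistasis()].
#' @param include_wobble Count G:U as complementary (default TRUE; the
#'   landscape itself supports a non-canonical pair).
#' @return Tibble ranked by descending `score`, with `pos_i`, `pos_j`,
#'   `n_restoring`, `n_other`, `score`.
#' @export
pair_evidence <- function(records, include_wobble = TRUE) {
  if (nrow(records) == 0) stop("no epistasis records")
  records |>
    dplyr::mutate(
      restoring = nt_complementary(.data$alt_i, .data$alt_j, include_wobble)
    ) |>
    dplyr::group_by(.data$pos_i, .data$pos_j) |>
    dplyr::summarise(
      n_restoring = sum(.data$restoring),
      n_other = sum(!.data$restoring),
      score = mean(.data$epsilon[.data$restoring]) -
        mean(.data$epsilon[!.data$restoring]),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_restoring > 0, .data$n_other > 0) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$pos_i, .data$pos_j)
}

#' Greedy non-conflicting pair selection
#'
#' Walks the evidence ranking in descending score order (ties broken by the
#' smaller 5' then 3' position) and accepts a pair when neither position is
#' already paired and its score exceeds `threshold`. Accepted pairs that
#' cross an earlier accepted pair (pseudoknots) are kept but flagged.
#'
#' @param evidence Ranked tibble from [pair_evidence()].
#' @param threshold Minimum score (exclusive; default 0).
#' @return Tibble `pos_i`, `pos_j`, `score`, `crossing`.
#' @export
propose_pairs <- function(evidence, threshold = 0) {
  ev <- dplyr::arrange(evidence, dplyr::desc(.data$score), .data$pos_i, .data$pos_j)
  ev <- ev[ev$score > threshold, ]
  used <- integer(0)
  acc <- list()
  for (k in seq_len(nrow(ev))) {
    i <- ev$pos_i[k]
    j <- ev$pos_j[k]
    if (i %in% used || j %in% used) next
    crossing <- any(vapply(acc, function(p) {
      (p[1] < i && i < p[2] && p[2] < j) || (i < p[1] && p[1] < j && j < p[2])
    }, logical(1)))
    acc[[length(acc) + 1]] <- c(i, j, crossing)
    used <- c(used, i, j)
  }
  if (length(acc) == 0) {
    return(tibble::tibble(
      pos_i = integer(), pos_j = integer(),
      score = numeric(), crossing = logical()
    ))
  }
  m <- do.call(rbind, acc)
  out <- tibble::tibble(pos_i = m[, 1], pos_j = m[, 2], crossing = m[, 3] == 1)
  out$score <- ev$score[match(paste(out$pos_i, out$pos_j), paste(ev$pos_i, ev$pos_j))]
  dplyr::select(
    dplyr::arrange(out, .data$pos_i),
    "pos_i", "pos_j", "score", "crossing"
  )
}

#' Dot-bracket string for a proposed pair set
#'
#' Crossing (pseudoknotted) pairs are omitted from the string, which encodes
#' only the nested subset.
#'
#' @param pairs Tibble from [propose_pairs()].
#' @param length Sequence length.
#' @return Dot-bracket string of `length` characters.
#' @export
dot_bracket <- function(pairs, length) {
  db <- rep(".", length)
  nested <- pairs[!pairs$crossing, ]
  db[nested$pos_i] <- "("
  db[nested$pos_j] <- ")"
  paste(db, collapse = "")
}
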