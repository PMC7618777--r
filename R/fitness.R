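# Per-genotype fitness as log-normalized enrichment across one round of
# selection, with replicate handling and mutant-universe coverage.

#' Count genotypes in a read set
#'
#' Classifies every read against the reference (substitutions up to
#' `max_order`, single deletions) and tallies counts per genotype label.
#' Reads that cannot be explained are pooled into a single `"other"` bucket.
#'
#' @param reads Path to a FASTA/FASTQ file, or a tibble with a `seq` column.
#' @param ref A [reference_sequence()] or RNA string.
#' @param max_order Maximum substitution order (default 2).
#' @return Tibble with columns `genotype`, `class`, `count`, sorted by
#'   decreasing count.
#' @export
count_genotypes <- function(reads, ref, max_order = 2) {
  ref <- as_reference(ref)
  if (is.character(reads)) reads <- read_reads(reads)
  if (nrow(reads) == 0) stop("no reads to count")
  cls <- classify_reads_vec(reads$seq, ref, max_order)
  tibble::tibble(genotype = cls$genotype, class = cls$class) |>
    dplyr::count(.data$genotype, .data$class, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$genotype)
}

#' Fitness as log-normalized enrichment
#'
#' For each genotype v and replicate, fitness is
#' `f_v = log_b[ ((n_post_v + a) / (n_post_wt + a)) / ((n_pre_v + a) / (n_pre_wt + a)) ]`
#' with pseudocount `a` added to every count, so the wild type is 0 by
#' construction and dropout genotypes stay defined. Genotypes below
#' `min_count` reads in any replicate's pre-selection table are omitted; the
#' `"other"` bucket never receives a fitness value.
#'
#' @param counts Long tibble with columns `replicate`, `round` ("pre"/"post"),
#'   `genotype`, `count` — the shape produced by
#'   [simulate_selection_round()] — or, for a single replicate, columns
#'   `round`, `genotype`, `count`.
#' @param ref A [reference_sequence()] used to derive genotype classes.
#' @param pseudocount Pseudocount `a` (default 0.5).
#' @param log_base Log base, one of 2, `exp(1)`, 10 (default 2).
#' @param min_count Minimum pre-selection count (default 10; applied per
#'   replicate).
#' @return A `fitness_table`: tibble with columns `genotype`, `class`, one
#'   `f_rep<i>` column per replicate, and `f_mean`; attributes `log_base`,
#'   `pseudocount`, `min_count`.
#' @export
compute_fitness <- function(counts, ref, pseudocount = 0.5, log_base = 2,
                            min_count = 10) {
  stopifnot(pseudocount >= 0, log_base > 0, log_base != 1, min_count >= 0)
  ref <- as_reference(ref)
  if (!"replicate" %in% names(counts)) counts$replicate <- 1L
  required <- c("replicate", "round", "genotype", "count")
  if (!all(required %in% names(counts))) {
    stop("counts must have columns ", paste(required, collapse = ", "))
  }
  reps <- sort(unique(counts$replicate))

  per_rep <- purrr::map(reps, function(r) {
    cc <- counts[counts$replicate == r, ]
    pre <- setNames(cc$count[cc$round == "pre"], cc$genotype[cc$round == "pre"])
    post <- setNames(cc$count[cc$round == "post"], cc$genotype[cc$round == "post"])
    if (!"wt" %in% names(pre) || !"wt" %in% names(post)) {
      stop("wild type absent from replicate ", r, "; cannot normalize")
    }
    genos <- setdiff(names(pre)[pre >= min_count], "other")
    post_v <- ifelse(is.na(post[genos]), 0, post[genos])
    f <- log(((post_v + pseudocount) / (post[["wt"]] + pseudocount)) /
      ((pre[genos] + pseudocount) / (pre[["wt"]] + pseudocount)), base = log_base)
    tibble::tibble(genotype = genos, replicate = r, f = unname(f))
  })

  long <- dplyr::bind_rows(per_rep)
  # keep genotypes measured in every replicate so means are balanced
  keep <- long |>
    dplyr::count(.data$genotype) |>
    dplyr::filter(.data$n == length(reps)) |>
    dplyr::pull(.data$genotype)
  wide <- long |>
    dplyr::filter(.data$genotype %in% keep) |>
    tidyr::pivot_wider(
      names_from = "replicate", values_from = "f",
      names_prefix = "f_rep"
    )
  wide$f_mean <- rowMeans(wide[paste0("f_rep", reps)])
  out <- tibble::tibble(
    genotype = wide$genotype,
    class = label_class(wide$genotype)
  ) |>
    dplyr::bind_cols(wide[-1]) |>
    dplyr::arrange(.data$class != "wt", .data$genotype)
  attr(out, "log_base") <- log_base
  attr(out, "pseudocount") <- pseudocount
  attr(out, "min_count") <- min_count
  class(out) <- c("fitness_table", class(out))
  out
}

fitness_log_base <- function(table, default = 2) {
  b <- attr(table, "log_base")
  if (is.null(b)) default else b
}

#' Pairwise replicate correlation of fitness values
#'
#' Pearson correlation of per-replicate fitness over the genotypes shared by
#' each replicate pair (the wild type, identically 0, is excluded).
#'
#' @param table A `fitness_table` from [compute_fitness()].
#' @return Tibble with columns `rep_a`, `rep_b`, `n_shared`, `r`.
#' @export
replicate_correlation <- function(table) {
  repcols <- grep("^f_rep", names(table), value = TRUE)
  if (length(repcols) < 2) stop("need at least 2 replicates")
  tab <- table[table$class != "wt", ]
  combos <- utils::combn(repcols, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- tab[[combos[1, k]]]
    b <- tab[[combos[2, k]]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) stop("fewer than 3 shared genotypes between replicates")
    tibble::tibble(
      rep_a = combos[1, k], rep_b = combos[2, k],
      n_shared = sum(ok), r = cor(a[ok], b[ok])
    )
  })
}

#' Coverage of the mutant universe
#'
#' Fraction of each enumerable mutant class (single substitutions, single
#' deletions, double substitutions) present in a fitness table.
#'
#' @param table A `fitness_table`.
#' @param ref The [reference_sequence()] defining the universe.
#' @return Tibble with columns `class`, `n_measured`, `n_possible`,
#'   `coverage`.
#' @export
coverage <- function(table, ref) {
  ref <- as_reference(ref)
  L <- ref$length
  universe <- tibble::tibble(
    class = c("single_sub", "single_del", "double_sub"),
    n_possible = c(3 * L, L, choose(L, 2) * 9)
  )
  measured <- table |>
    tibble::as_tibble() |>
    dplyr::count(.data$class, name = "n_measured")
  universe |>
    dplyr::left_join(measured, by = "class") |>
    dplyr::mutate(
      n_measured = ifelse(is.na(.data$n_measured), 0L, .data$n_measured),
      coverage = .data$n_measured / .data$n_possible
    ) |>
    dplyr::select("class", "n_measured", "n_possible", "coverage")
}

#' Long heatmap-ready form of a double-mutant fitness table
#'
#' One row per double mutant with its two constituent point mutations split
#' into `mutation_1` and `mutation_2` columns, matching the
#' first-mutation-by-second-mutation layout of a landscape heatmap.
#'
#' @param table A `fitness_table`.
#' @return Tibble with columns `mutation_1`, `mutation_2`, `f_mean`.
#' @export
fitness_heatmap_data <- function(table) {
  doubles <- table[table$class == "double_sub", ]
  parts <- strsplit(doubles$genotype, "+", fixed = TRUE)
  tibble::tibble(
    mutation_1 = vapply(parts, `[`, character(1), 1),
    mutation_2 = vapply(parts, `[`, character(1), 2),
    f_mean = doubles$f_mean
  )
}
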