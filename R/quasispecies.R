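# Mutation-selection balance over the measured genotype neighborhood of the
# wild type, active-variant fraction, and Eigen error-threshold utilities.
#
# The model is deterministic: a column-stochastic per-generation mutation
# matrix built from the per-nucleotide copying fidelity q, combined with
# replication rates derived from measured fitness (w = b^f). Its stationary
# state is the leading eigenvector of M %*% diag(w), found by power
# iteration.

#' Build a quasispecies model from a fitness table
#'
#' Tracked genotypes are the wild type plus all substitution genotypes in the
#' fitness table (single deletions are length-changing and are not reachable
#' under the per-position substitution model; they contribute to the lumped
#' compartment like every other unmeasured genotype). Replication rates are
#' `w = b^f` with `b` the fitness log base. Probability mass mutating outside
#' the tracked set accumulates in an `"other"` compartment with no back
#' mutation and a configurable fitness (default: the minimum measured
#' fitness, a conservative choice).
#'
#' @param table A `fitness_table` (or tibble with `genotype`, `class`,
#'   `f_mean`).
#' @param ref The [reference_sequence()].
#' @param q Per-nucleotide copying fidelity in `[0, 1]`.
#' @param log_base Fitness log base; defaults to the table's `log_base`
#'   attribute (2 if absent).
#' @param other_fitness Fitness of the lumped compartment (default
#'   `min(f_mean)`).
#' @param activity_threshold A genotype counts as active when its fitness is
#'   at or above this value (default -1); the lumped compartment is always
#'   inactive.
#' @return List of class `qs_model`.
#' @export
qs_model <- function(table, ref, q, log_base = NULL, other_fitness = NULL,
                     activity_threshold = -1) {
  if (q < 0 || q > 1) stop("fidelity q must lie in [0, 1]")
  ref <- as_reference(ref)
  if (is.null(log_base)) log_base <- fitness_log_base(table)
  tab <- tibble::as_tibble(table)[, c("genotype", "class", "f_mean")]
  tab <- tab[tab$class %in% c("wt", "single_sub", "double_sub"), ]
  if (!"wt" %in% tab$genotype) {
    tab <- dplyr::bind_rows(
      tibble::tibble(genotype = "wt", class = "wt", f_mean = 0), tab
    )
  }
  if (is.null(other_fitness)) other_fitness <- min(tab$f_mean)
  structure(
    list(
      genotypes = tab$genotype, classes = tab$class, fitness = tab$f_mean,
      ref = ref, q = q, L = ref$length, log_base = log_base,
      other_fitness = other_fitness, activity_threshold = activity_threshold
    ),
    class = "qs_model"
  )
}

# integer-encoded sequence matrix (genotypes x L) for the tracked set
qs_sequences <- function(model) {
  seqs <- vapply(
    model$genotypes,
    function(g) genotype_sequence(g, model$ref), character(1)
  )
  m <- matrix(
    match(
      unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
      RNA_ALPHABET
    ),
    nrow = length(seqs), byrow = TRUE
  )
  rownames(m) <- model$genotypes
  m
}

#' Per-generation mutation matrix
#'
#' Exact per-position independent-error transition probabilities between all
#' tracked genotypes: a parent-to-child copy with Hamming distance d has
#' probability `q^(L-d) * ((1-q)/3)^d` (uniform spectrum over the three
#' alternatives). Columns index parents; each column's residual mass (every
#' untracked genotype, including all triple-and-higher mutants) goes to the
#' terminal `"other"` row, so columns sum to 1 exactly.
#'
#' @param model A [qs_model()].
#' @return `(n+1) x (n+1)` column-stochastic matrix, last row/column
#'   `"other"`.
#' @export
build_mutation_matrix <- function(model) {
  stopifnot(inherits(model, "qs_model"))
  q <- model$q
  L <- model$L
  enc <- qs_sequences(model)
  n <- nrow(enc)
  # Hamming distances via one-hot inner products (single BLAS call)
  X <- matrix(0, n, 4 * L)
  X[cbind(
    rep(seq_len(n), L),
    (rep(seq_len(L), each = n) - 1) * 4 + as.vector(enc)
  )] <- 1
  D <- L - tcrossprod(X)
  M <- if (q == 1) {
    (D == 0) * 1
  } else if (q == 0) {
    (D == L) * (1 / 3)^L # degenerate: every position must change
  } else {
    q^(L - D) * ((1 - q) / 3)^D
  }
  other <- pmax(0, 1 - colSums(M))
  M <- rbind(cbind(M, 0), c(other, 1))
  dimnames(M) <- list(
    c(model$genotypes, "other"),
    c(model$genotypes, "other")
  )
  M
}

#' Stationary quasispecies distribution
#'
#' Power iteration on `M %*% diag(w)` (mutation after fitness-proportional
#' replication) to the leading eigenvector, tolerance 1e-12 on the L1 change
#' per step, at most 1e5 iterations. The active fraction is the summed
#' frequency of tracked genotypes with fitness at or above the activity
#' threshold; the lumped compartment is always inactive.
#'
#' @param model A [qs_model()], or a pre-built column-stochastic matrix (then
#'   `w` must be supplied).
#' @param w Optional replication-rate vector when `model` is a matrix.
#' @param active Optional logical vector marking active genotypes when
#'   `model` is a matrix.
#' @param tol,max_iter Convergence tolerance and iteration cap.
#' @return Object of class `qs_state`: list with `frequencies` tibble
#'   (`genotype`, `class`, `fitness`, `frequency`), `mean_fitness` (mean
#'   replication rate), `active_fraction`, `n_iter`.
#' @export
stationary_distribution <- function(model, w = NULL, active = NULL,
                                    tol = 1e-12, max_iter = 1e5) {
  if (inherits(model, "qs_model")) {
    M <- build_mutation_matrix(model)
    w <- c(model$log_base^model$fitness, model$log_base^model$other_fitness)
    active <- c(model$fitness >= model$activity_threshold, FALSE)
    labels <- rownames(M)
    classes <- c(model$classes, "other")
    fitness <- c(model$fitness, model$other_fitness)
  } else {
    M <- model
    if (is.null(w)) stop("w required when model is a plain matrix")
    labels <- rownames(M)
    if (is.null(labels)) labels <- paste0("g", seq_len(nrow(M)))
    classes <- rep(NA_character_, nrow(M))
    fitness <- rep(NA_real_, nrow(M))
    if (is.null(active)) active <- rep(FALSE, nrow(M))
  }
  if (any(w <= 0)) stop("replication rates must be positive")
  n <- nrow(M)
  x <- rep(1 / n, n)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    y <- as.vector(M %*% (w * x))
    y <- y / sum(y)
    if (sum(abs(y - x)) < tol) {
      x <- y
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged) {
    stop("power iteration did not converge in ", max_iter, " iterations")
  }
  structure(
    list(
      frequencies = tibble::tibble(
        genotype = labels, class = classes, fitness = fitness, frequency = x
      ),
      mean_fitness = sum(w * x),
      active_fraction = sum(x[active]),
      n_iter = it
    ),
    class = "qs_state"
  )
}

#' @export
print.qs_state <- function(x, ...) {
  cat(sprintf(
    "<qs_state: %d genotypes, active fraction %.3f%%, mean replication rate %.4f (%d iterations)>\n",
    nrow(x$frequencies), 100 * x$active_fraction, x$mean_fitness, x$n_iter
  ))
  invisible(x)
}

#' Sweep the stationary state over copying fidelities
#'
#' @param table,ref,log_base,other_fitness,activity_threshold Passed to
#'   [qs_model()].
#' @param q_values Fidelities to evaluate.
#' @return Tibble with columns `q`, `active_fraction`, `wt_frequency`,
#'   `other_frequency`, `mean_fitness`.
#' @export
qs_sweep <- function(table, ref, q_values, log_base = NULL,
                     other_fitness = NULL, activity_threshold = -1) {
  purrr::map_dfr(q_values, function(q) {
    st <- stationary_distribution(
      qs_model(table, ref, q,
        log_base = log_base, other_fitness = other_fitness,
        activity_threshold = activity_threshold
      )
    )
    fr <- st$frequencies
    tibble::tibble(
      q = q,
      active_fraction = st$active_fraction,
      wt_frequency = fr$frequency[fr$genotype == "wt"],
      other_frequency = fr$frequency[fr$genotype == "other"],
      mean_fitness = st$mean_fitness
    )
  })
}

#' Eigen error threshold: maximum sustainable length
#'
#' Classical approximation of the error threshold `q^L * sigma > 1` with
#' `ln q ~ -(1-q)`: the longest genome a master sequence with superiority
#' `sigma` (its replication-rate advantage over the mutant average) can
#' maintain at per-nucleotide fidelity `q` is `L_max = ln(sigma) / (1 - q)`.
#'
#' @param sigma Superiority ratio (> 0).
#' @param q Per-nucleotide fidelity in (0, 1).
#' @return `L_max` (0 with a warning when `sigma <= 1`: the master cannot
#'   dominate at any length).
#' @examples
#' eigen_threshold(exp(1), 0.974) # ~38.5 nt
#' @export
eigen_threshold <- function(sigma, q) {
  stopifnot(sigma > 0, q > 0, q < 1)
  if (sigma <= 1) {
    warning("superiority <= 1: master cannot dominate; L_max = 0")
    return(0)
  }
  log(sigma) / (1 - q)
}

#' Minimum fidelity to sustain a given length
#'
#' Exact form of the threshold condition `q^L * sigma = 1`:
#' `q_min = sigma^(-1/L)`.
#'
#' @param sigma Superiority ratio (> 1 for a finite answer).
#' @param L Sequence length.
#' @return Minimum per-nucleotide fidelity `q_min`.
#' @examples
#' required_fidelity(2, 45) # ~0.9847
#' @export
required_fidelity <- function(sigma, L) {
  stopifnot(sigma > 0, L > 0)
  sigma^(-1 / L)
}
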