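# Positional and average per-nucleotide fidelity, substitution spectra,
# perfect-full-length fractions and stalling behavior of triplet-synthesis
# product reads against the expected product sequence.
#
# Per-read calls are stored as a compact string over expected-product
# positions: "=" match, "A"/"C"/"G"/"U" the substituted base, "-" deletion,
# "." not reached (3' truncation).

CALL_NOT_REACHED <- "."
CALL_MATCH <- "="
CALL_DELETION <- "-"

#' Align one product read to the expected product
#'
#' Reads without indels (the overwhelming majority) are resolved by direct
#' positional comparison; reads that compare poorly are realigned
#' semi-globally (match +1, mismatch -1, gap -2, free end gap at the read 3'
#' end) with [Biostrings::pairwiseAlignment()]. A read whose identity over
#' the aligned span falls below `min_identity` is rejected with a reason. If
#' `tail` is given and occurs at the read end, the read is flagged as a
#' tail-bearing (recombination) product and the tail is stripped before
#' alignment.
#'
#' @param read RNA string.
#' @param expected Expected full-length product (primer prefix included).
#' @param primer_len Length of the primer prefix.
#' @param tail Optional tail sequence.
#' @param min_identity Minimum identity over the aligned span (default 0.7).
#' @return One-row tibble: `read_id`, `calls`, `length_reached`, `has_tail`,
#'   `has_indel`, `rejected`, `reason`.
#' @export
align_product <- function(read, expected, primer_len, tail = NULL,
                          min_identity = 0.7) {
  if (nchar(expected) <= primer_len) {
    stop("expected product must extend beyond the primer")
  }
  align_products(
    tibble::tibble(read_id = "read", seq = read),
    expected, primer_len,
    tail = tail, min_identity = min_identity
  )
}

#' Align a set of product reads
#'
#' Vectorized driver for [align_product()]; see there for the model.
#'
#' @param reads Tibble with columns `read_id`, `seq`, or a FASTA/FASTQ path.
#' @inheritParams align_product
#' @return Tibble with one row per read: `read_id`, `calls`,
#'   `length_reached`, `has_tail`, `has_indel`, `rejected`, `reason`.
#' @export
align_products <- function(reads, expected, primer_len, tail = NULL,
                           min_identity = 0.7) {
  if (is.character(reads)) reads <- read_reads(reads)
  if (nchar(expected) <= primer_len) {
    stop("expected product must extend beyond the primer")
  }
  exp_chars <- strsplit(expected, "", fixed = TRUE)[[1]]
  N <- length(exp_chars)

  seqs <- reads$seq
  has_tail <- rep(FALSE, nrow(reads))
  if (!is.null(tail) && nzchar(tail)) {
    has_tail <- endsWith(seqs, tail)
    seqs[has_tail] <- substr(seqs[has_tail], 1, nchar(seqs[has_tail]) - nchar(tail))
  }

  out <- purrr::map(seq_along(seqs), function(i) {
    align_one(seqs[i], exp_chars, min_identity)
  })
  tibble::tibble(
    read_id = reads$read_id,
    calls = vapply(out, `[[`, character(1), "calls"),
    length_reached = vapply(out, `[[`, integer(1), "length_reached"),
    has_tail = has_tail,
    has_indel = vapply(out, `[[`, logical(1), "has_indel"),
    rejected = vapply(out, `[[`, logical(1), "rejected"),
    reason = vapply(out, `[[`, character(1), "reason")
  )
}

align_one <- function(seq, exp_chars, min_identity) {
  N <- length(exp_chars)
  n <- nchar(seq)
  if (n == 0) {
    return(list(
      calls = strrep(CALL_NOT_REACHED, N), length_reached = 0L,
      has_indel = FALSE, rejected = TRUE, reason = "empty read"
    ))
  }
  # fast path: positional comparison, no indels
  span <- min(n, N)
  rc <- strsplit(substr(seq, 1, span), "", fixed = TRUE)[[1]]
  mism <- rc != exp_chars[seq_len(span)]
  if (n <= N && mean(mism) <= 0.1) {
    calls <- rep(CALL_NOT_REACHED, N)
    calls[seq_len(span)] <- CALL_MATCH
    calls[which(mism)] <- rc[mism]
    identity <- 1 - mean(mism)
    return(list(
      calls = paste(calls, collapse = ""), length_reached = span,
      has_indel = FALSE,
      rejected = identity < min_identity,
      reason = if (identity < min_identity) "low identity" else ""
    ))
  }
  align_one_indel(seq, exp_chars, min_identity)
}

# semi-global alignment path for reads with likely indels
align_one_indel <- function(seq, exp_chars, min_identity) {
  N <- length(exp_chars)
  submat <- matrix(-1, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  diag(submat) <- 1
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::RNAString(seq),
    subject = Biostrings::RNAString(paste(exp_chars, collapse = "")),
    substitutionMatrix = submat,
    gapOpening = 0, gapExtension = 2,
    type = "global-local"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "", fixed = TRUE)[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "", fixed = TRUE)[[1]]
  s_start <- Biostrings::start(Biostrings::subject(al))
  s_end <- Biostrings::end(Biostrings::subject(al))
  calls <- rep(CALL_NOT_REACHED, N)
  if (s_start > 1) calls[seq_len(s_start - 1)] <- CALL_DELETION
  pos <- s_start - 1
  matches <- 0L
  aligned <- 0L
  has_indel <- s_start > 1
  for (k in seq_along(p)) {
    if (s[k] == "-") { # insertion in read
      has_indel <- TRUE
      next
    }
    pos <- pos + 1
    aligned <- aligned + 1L
    if (p[k] == "-") {
      calls[pos] <- CALL_DELETION
      has_indel <- TRUE
    } else if (p[k] == s[k]) {
      calls[pos] <- CALL_MATCH
      matches <- matches + 1L
    } else {
      calls[pos] <- p[k]
    }
  }
  identity <- if (aligned > 0) matches / aligned else 0
  list(
    calls = paste(calls, collapse = ""), length_reached = as.integer(s_end),
    has_indel = has_indel,
    rejected = identity < min_identity,
    reason = if (identity < min_identity) "low identity" else ""
  )
}

# calls matrix (reads x positions) from the compact strings
calls_matrix <- function(calls) {
  if (length(calls) == 0) return(matrix(character(0), 0, 0))
  matrix(unlist(strsplit(calls, "", fixed = TRUE), use.names = FALSE),
    nrow = length(calls), byrow = TRUE
  )
}

# full-length, tail-free, indel-free, accepted alignments
clean_full_length <- function(alignments, expected_len) {
  alignments[
    alignments$length_reached == expected_len &
      !alignments$has_tail & !alignments$has_indel & !alignments$rejected,
  ]
}

#' Positional and average per-nucleotide fidelity
#'
#' Positional fidelity is the fraction of correct calls at each synthesized
#' position among full-length, tail-free, indel-free reads; primer positions
#' are excluded (the primer is supplied, not synthesized). The scalar average
#' is the geometric mean of positional fidelities by default — the
#' "per nucleotide" multiplicative reading, under which
#' `average_fidelity ^ n_positions` approximates the perfect-read fraction —
#' with the arithmetic mean as an option. The perfect-full-length fraction is
#' the proportion of those reads with no substitution.
#'
#' @param alignments Tibble from [align_products()].
#' @param expected_len Length of the expected product.
#' @param primer_len Primer prefix length.
#' @param method "geometric" (default) or "arithmetic".
#' @return An object of class `fidelity_profile`: list with `positional`
#'   (tibble `position`, `n_reads`, `fidelity`), `average_fidelity`,
#'   `perfect_full_length_fraction`, `n_full_length`, `method`.
#' @export
fidelity_profile <- function(alignments, expected_len, primer_len,
                             method = c("geometric", "arithmetic")) {
  method <- match.arg(method)
  fl <- clean_full_length(alignments, expected_len)
  if (nrow(fl) == 0) stop("no full-length reads; cannot estimate fidelity")
  mat <- calls_matrix(fl$calls)
  synth <- (primer_len + 1):expected_len
  correct <- mat[, synth, drop = FALSE] == CALL_MATCH
  pos_fid <- colMeans(correct)
  avg <- switch(method,
    geometric = exp(mean(log(pos_fid))),
    arithmetic = mean(pos_fid)
  )
  perfect <- rowSums(!correct) == 0
  structure(
    list(
      positional = tibble::tibble(
        position = synth, n_reads = nrow(fl), fidelity = unname(pos_fid)
      ),
      average_fidelity = avg,
      perfect_full_length_fraction = mean(perfect),
      n_full_length = nrow(fl),
      method = method
    ),
    class = "fidelity_profile"
  )
}

#' @export
print.fidelity_profile <- function(x, ...) {
  cat(sprintf(
    "<fidelity_profile: %d full-length reads, average fidelity %.1f%% (%s), perfect %.1f%%>\n",
    x$n_full_length, 100 * x$average_fidelity, x$method,
    100 * x$perfect_full_length_fraction
  ))
  invisible(x)
}

#' Substitution spectrum of product reads
#'
#' Counts every substitution in full-length, tail-free, indel-free reads into
#' a 4x4 expected-by-observed matrix. Wobble-type errors are product G where
#' the expected product base is A (the template base is U, paired G:U) and
#' product U where the expected base is C (template G). `wobble_fraction` is
#' the wobble share among substitutions at wobble-capable expected bases
#' (A or C), the positions where a wobble product exists;
#' `overall_wobble_share` is the wobble share among all substitutions. The
#' within-triplet index of each synthesized position is
#' `((pos - primer_len - 1) mod 3) + 1`.
#'
#' @inheritParams fidelity_profile
#' @return List of class `error_spectrum`: `matrix` (4x4 counts),
#'   `wobble_fraction` and `overall_wobble_share` (NA when no substitutions),
#'   `n_substitutions`, `per_triplet_index` tibble (`index`, `n_errors`,
#'   `n_sites`, `rate`).
#' @export
error_spectrum <- function(alignments, expected, primer_len) {
  expected_len <- nchar(expected)
  exp_chars <- strsplit(expected, "", fixed = TRUE)[[1]]
  fl <- clean_full_length(alignments, expected_len)
  if (nrow(fl) == 0) stop("no full-length reads; cannot estimate spectrum")
  mat <- calls_matrix(fl$calls)
  synth <- (primer_len + 1):expected_len
  sub_counts <- matrix(0L, 4, 4, dimnames = list(
    expected = RNA_ALPHABET, observed = RNA_ALPHABET
  ))
  idx_err <- integer(3)
  idx_sites <- integer(3)
  for (p in synth) {
    obs <- mat[, p]
    expnt <- exp_chars[p]
    tridx <- ((p - primer_len - 1) %% 3) + 1
    idx_sites[tridx] <- idx_sites[tridx] + length(obs)
    subs <- obs %in% RNA_ALPHABET
    idx_err[tridx] <- idx_err[tridx] + sum(subs)
    if (any(subs)) {
      tab <- table(obs[subs])
      sub_counts[expnt, names(tab)] <- sub_counts[expnt, names(tab)] + as.integer(tab)
    }
  }
  n_sub <- sum(sub_counts)
  n_wobble <- sub_counts["A", "G"] + sub_counts["C", "U"]
  n_capable <- sum(sub_counts[c("A", "C"), ])
  structure(
    list(
      matrix = sub_counts,
      wobble_fraction = if (n_capable == 0) NA_real_ else n_wobble / n_capable,
      overall_wobble_share = if (n_sub == 0) NA_real_ else n_wobble / n_sub,
      n_substitutions = n_sub,
      per_triplet_index = tibble::tibble(
        index = 1:3, n_errors = idx_err, n_sites = idx_sites,
        rate = ifelse(idx_sites > 0, idx_err / idx_sites, NA_real_)
      )
    ),
    class = "error_spectrum"
  )
}

#' Stalling profile and terminal-triplet fidelity
#'
#' Histogram of synthesis length in triplet units over accepted tail-free
#' reads, and — for intermediate (prematurely terminated) products — the
#' substitution rate in the 3'-terminal triplet versus all upstream
#' triplets, with exact binomial confidence intervals. A terminal rate above
#' the internal rate is the signature of misincorporation-induced stalling.
#'
#' @inheritParams fidelity_profile
#' @return List of class `stalling_profile`: `histogram` tibble
#'   (`n_triplets`, `n_reads`), `rates` tibble (`region`, `n_errors`,
#'   `n_sites`, `rate`, `conf_low`, `conf_high`), `n_intermediate`.
#' @export
stalling_profile <- function(alignments, expected_len, primer_len) {
  ok <- alignments[!alignments$rejected & !alignments$has_tail &
    !alignments$has_indel, ]
  n_trip_full <- (expected_len - primer_len) %/% 3
  n_trip <- pmax((ok$length_reached - primer_len) %/% 3, 0)
  hist <- tibble::tibble(n_triplets = n_trip) |>
    dplyr::count(.data$n_triplets, name = "n_reads")

  inter <- ok[n_trip >= 1 & n_trip < n_trip_full, ]
  nt_inter <- pmax((inter$length_reached - primer_len) %/% 3, 0)
  term_err <- 0L
  term_sites <- 0L
  int_err <- 0L
  int_sites <- 0L
  if (nrow(inter) > 0) {
    mat <- calls_matrix(inter$calls)
    for (r in seq_len(nrow(inter))) {
      last <- primer_len + 3 * nt_inter[r]
      term <- (last - 2):last
      term_err <- term_err + sum(mat[r, term] %in% RNA_ALPHABET)
      term_sites <- term_sites + 3L
      if (nt_inter[r] > 1) {
        up <- (primer_len + 1):(last - 3)
        int_err <- int_err + sum(mat[r, up] %in% RNA_ALPHABET)
        int_sites <- int_sites + length(up)
      }
    }
  }
  ci <- function(x, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    binom.test(x, n)$conf.int
  }
  ci_t <- ci(term_err, term_sites)
  ci_i <- ci(int_err, int_sites)
  structure(
    list(
      histogram = hist,
      rates = tibble::tibble(
        region = c("terminal_triplet", "internal_triplets"),
        n_errors = c(term_err, int_err),
        n_sites = c(term_sites, int_sites),
        rate = c(
          if (term_sites > 0) term_err / term_sites else NA_real_,
          if (int_sites > 0) int_err / int_sites else NA_real_
        ),
        conf_low = c(ci_t[1], ci_i[1]),
        conf_high = c(ci_t[2], ci_i[2])
      ),
      n_intermediate = nrow(inter)
    ),
    class = "stalling_profile"
  )
}
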