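# Reference sequence, 1-based coordinates, mutation notation, and
# read-to-genotype classification shared by all downstream modules.

RNA_ALPHABET <- c("A", "C", "G", "U")
DELETION_MARK <- "\u0394" # capital delta prefix marks a deletion, e.g. position 12

#' Construct a reference sequence
#'
#' A light container for the wild-type RNA sequence all coordinates refer to.
#' Positions are 1-based and inclusive throughout the package, so "G10" means
#' the G at the tenth nucleotide.
#'
#' @param seq RNA string over the alphabet A, C, G, U.
#' @param name Identifier for the reference.
#' @return An object of class `reference_sequence` with fields `seq`, `length`
#'   and `name`.
#' @examples
#' ref <- reference_sequence("GGCAU", name = "toy")
#' ref$length
#' @export
reference_sequence <- function(seq, name = "ref") {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) > 0)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), RNA_ALPHABET)
  if (length(bad) > 0) {
    stop("non-RNA characters in reference: ", paste(bad, collapse = ", "))
  }
  structure(
    list(seq = seq, length = nchar(seq), name = name),
    class = "reference_sequence"
  )
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("<reference_sequence '%s', %d nt>\n%s\n", x$name, x$length, x$seq))
  invisible(x)
}

as_reference <- function(ref) {
  if (inherits(ref, "reference_sequence")) return(ref)
  reference_sequence(ref)
}

ref_chars <- function(ref) strsplit(ref$seq, "", fixed = TRUE)[[1]]

#' Reverse complement of an RNA sequence
#'
#' Complements A with U and G with C, then reverses. Applying it twice returns
#' the input. Used to move between the ribozyme (+) strand and the (-) strand
#' template of its own synthesis.
#'
#' @param seq Character vector of RNA strings (A, C, G, U).
#' @return Character vector of reverse complements, same length as `seq`.
#' @examples
#' revcomp("AUGC")
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  ok <- grepl("^[ACGU]*$", seq)
  if (!all(ok)) {
    stop("non-RNA characters in sequence: ", seq[!ok][1])
  }
  comp <- chartr("ACGU", "UGCA", seq)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

# ---- mutation notation ------------------------------------------------------

# A genotype is serialized as "wt", "G10A" (substitution), "<delta>12"
# (single-nucleotide deletion), or combinations joined with "+", positions
# strictly increasing: "G10A+C36U".

format_substitution <- function(position, ref_nt, alt_nt) {
  paste0(ref_nt, position, alt_nt)
}

format_deletion <- function(position) paste0(DELETION_MARK, position)

#' Parse a genotype label into a mutation table
#'
#' @param label Genotype label such as `"wt"`, `"G10A"`, a deletion
#'   (capital delta followed by the position) or `"G10A+C36U"`.
#' @param ref A [reference_sequence()] (or plain RNA string) used to validate
#'   reference nucleotides.
#' @return A tibble with columns `position`, `ref_nt`, `alt_nt` (deletions use
#'   `alt_nt = "-"`), zero rows for `"wt"`.
#' @export
parse_genotype <- function(label, ref) {
  ref <- as_reference(ref)
  rc <- ref_chars(ref)
  if (identical(label, "wt")) {
    return(tibble::tibble(position = integer(), ref_nt = character(), alt_nt = character()))
  }
  parts <- strsplit(label, "+", fixed = TRUE)[[1]]
  out <- purrr::map_dfr(parts, function(p) {
    if (startsWith(p, DELETION_MARK)) {
      pos <- as.integer(substring(p, 2))
      if (is.na(pos) || pos < 1 || pos > ref$length) stop("bad deletion position in '", p, "'")
      tibble::tibble(position = pos, ref_nt = rc[pos], alt_nt = "-")
    } else {
      m <- regmatches(p, regexec("^([ACGU])([0-9]+)([ACGU])$", p))[[1]]
      if (length(m) != 4) stop("unparseable mutation '", p, "'")
      pos <- as.integer(m[3])
      if (pos < 1 || pos > ref$length) stop("position out of range in '", p, "'")
      if (rc[pos] != m[2]) {
        stop("reference mismatch in '", p, "': reference has ", rc[pos], " at ", pos)
      }
      tibble::tibble(position = pos, ref_nt = m[2], alt_nt = m[4])
    }
  })
  if (is.unsorted(out$position, strictly = TRUE)) {
    stop("mutation positions must be strictly increasing in '", label, "'")
  }
  out
}

genotype_class <- function(mutations) {
  n_sub <- sum(mutations$alt_nt != "-")
  n_del <- sum(mutations$alt_nt == "-")
  if (n_sub == 0 && n_del == 0) return("wt")
  if (n_sub == 1 && n_del == 0) return("single_sub")
  if (n_sub == 2 && n_del == 0) return("double_sub")
  if (n_sub == 0 && n_del == 1) return("single_del")
  "other"
}

# Vectorized class from label shape alone (no reference validation);
# used on label sets the package itself produced.
label_class <- function(labels) {
  sub_re <- "^[ACGU][0-9]+[ACGU]$"
  dbl_re <- paste0("^[ACGU][0-9]+[ACGU]\\+[ACGU][0-9]+[ACGU]$")
  del_re <- paste0("^", DELETION_MARK, "[0-9]+$")
  dplyr::case_when(
    labels == "wt" ~ "wt",
    grepl(sub_re, labels) ~ "single_sub",
    grepl(dbl_re, labels) ~ "double_sub",
    grepl(del_re, labels) ~ "single_del",
    .default = "other"
  )
}

#' Sequence carried by a genotype
#'
#' Applies the substitutions/deletions of a genotype label to the reference.
#'
#' @inheritParams parse_genotype
#' @return RNA string of the mutant sequence.
#' @export
genotype_sequence <- function(label, ref) {
  ref <- as_reference(ref)
  rc <- ref_chars(ref)
  mut <- parse_genotype(label, ref)
  for (i in seq_len(nrow(mut))) {
    rc[mut$position[i]] <- mut$alt_nt[i]
  }
  paste(rc[rc != "-"], collapse = "")
}

# ---- classification ---------------------------------------------------------

#' Classify a read against the reference
#'
#' Exact-length reads are classified by Hamming comparison: up to `max_order`
#' substitutions give a substitution genotype, more give class `"other"`.
#' Reads one nucleotide short are tested for a single-deletion explanation;
#' when a homopolymer makes the deletion position ambiguous the leftmost
#' placement is reported, giving a canonical form. Everything else is
#' `"other"`.
#'
#' @param read RNA string.
#' @param ref A [reference_sequence()] or RNA string.
#' @param max_order Maximum number of substitutions (default 2).
#' @return A one-row tibble with columns `genotype` (label) and `class`.
#' @examples
#' ref <- reference_sequence("GGCAUCC")
#' classify_read("GGGAUCC", ref) # C3G
#' @export
classify_read <- function(read, ref, max_order = 2) {
  stopifnot(max_order >= 1)
  if (!is.character(read) || length(read) != 1 || nchar(read) == 0) {
    stop("read must be a single non-empty RNA string")
  }
  ref <- as_reference(ref)
  res <- classify_reads_vec(read, ref, max_order)
  tibble::tibble(genotype = res$genotype, class = res$class)
}

# Vectorized classifier used by count_genotypes(); returns list of two
# character vectors. Kept base-R and matrix-based for speed at 1e5+ reads.
classify_reads_vec <- function(reads, ref, max_order = 2) {
  L <- ref$length
  rc <- ref_chars(ref)
  n <- length(reads)
  genotype <- rep("other", n)
  class <- rep("other", n)
  len <- nchar(reads)

  full <- which(len == L)
  if (length(full) > 0) {
    m <- matrix(unlist(strsplit(reads[full], "", fixed = TRUE), use.names = FALSE),
      ncol = L, byrow = TRUE
    )
    diff <- m != matrix(rc, nrow = length(full), ncol = L, byrow = TRUE)
    d <- rowSums(diff)
    wt_idx <- full[d == 0]
    genotype[wt_idx] <- "wt"
    class[wt_idx] <- "wt"
    hit <- which(d >= 1 & d <= max_order)
    for (i in hit) {
      pos <- which(diff[i, ])
      lab <- paste(format_substitution(pos, rc[pos], m[i, pos]), collapse = "+")
      genotype[full[i]] <- lab
      class[full[i]] <- if (length(pos) == 1) "single_sub" else if (length(pos) == 2) "double_sub" else "other"
    }
    class[full[d > max_order]] <- "other"
  }

  short <- which(len == L - 1)
  for (i in short) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    # leftmost position where read diverges from reference
    pre <- which(ch != rc[seq_len(L - 1)])
    p <- if (length(pre) == 0) L else pre[1]
    # deleting reference position p must explain the remainder exactly
    if (p == L || all(ch[p:(L - 1)] == rc[(p + 1):L])) {
      # canonical leftmost placement: rewind through the homopolymer run
      while (p > 1 && rc[p - 1] == rc[p]) p <- p - 1
      genotype[i] <- format_deletion(p)
      class[i] <- "single_del"
    }
  }

  list(genotype = genotype, class = class)
}

#' Enumerate the mutant universe around a reference
#'
#' Order 1 yields all `3 * L` single substitutions plus the `L` single
#' deletions; order 2 yields all `choose(L, 2) * 9` double substitutions.
#' Enumeration is deterministic: by position (then allele in A<C<G<U order),
#' substitutions before deletions.
#'
#' @param ref A [reference_sequence()] or RNA string.
#' @param order 1 or 2.
#' @return Tibble with columns `genotype` and `class`.
#' @examples
#' nrow(enumerate_mutants(reference_sequence("GGCAU"), order = 1)) # 15 + 5
#' @export
enumerate_mutants <- function(ref, order) {
  ref <- as_reference(ref)
  if (!order %in% c(1, 2)) stop("unsupported order ", order, "; must be 1 or 2")
  rc <- ref_chars(ref)
  L <- ref$length
  if (order == 1) {
    subs <- purrr::map_dfr(seq_len(L), function(p) {
      alts <- setdiff(RNA_ALPHABET, rc[p])
      tibble::tibble(
        genotype = format_substitution(p, rc[p], alts),
        class = "single_sub"
      )
    })
    dels <- tibble::tibble(genotype = format_deletion(seq_len(L)), class = "single_del")
    return(dplyr::bind_rows(subs, dels))
  }
  pairs <- utils::combn(L, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    ai <- setdiff(RNA_ALPHABET, rc[i])
    aj <- setdiff(RNA_ALPHABET, rc[j])
    combo <- expand.grid(a = ai, b = aj, stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; reorder for lexicographic
    combo <- combo[order(combo$a, combo$b), ]
    out[[k]] <- paste0(
      format_substitution(i, rc[i], combo$a), "+",
      format_substitution(j, rc[j], combo$b)
    )
  }
  tibble::tibble(genotype = unlist(out), class = "double_sub")
}
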