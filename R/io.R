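# File-format helpers: FASTA/FASTQ through Biostrings, tables through readr.

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is taken from the file extension (`.fastq`/`.fq` vs anything else);
#' DNA alphabets are converted to RNA (T to U).
#'
#' @param path Path to a FASTA or FASTQ file.
#' @return Tibble with columns `read_id` and `seq`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("cannot read reads: no such file '", path, "'")
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) stop("failed to parse '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0) stop("no reads found in '", path, "'")
  seqs <- chartr("Tt", "Uu", toupper(as.character(set)))
  tibble::tibble(read_id = names(set), seq = unname(seqs))
}

#' Write reads to FASTQ with constant placeholder qualities
#'
#' Base qualities are not modeled anywhere in the pipeline, so every base is
#' written with a constant Phred 40 ("I") quality.
#'
#' @param reads Tibble with columns `read_id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::BStringSet(setNames(reads$seq, reads$read_id))
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write a reference as FASTA
#'
#' @param ref A [reference_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  ref <- as_reference(ref)
  set <- Biostrings::BStringSet(setNames(ref$seq, ref$name))
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read a reference from FASTA
#'
#' The first record is used; DNA alphabets are converted to RNA.
#'
#' @param path FASTA path.
#' @return A [reference_sequence()].
#' @export
read_reference_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read reference: no such file '", path, "'")
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0) stop("no sequences in '", path, "'")
  reference_sequence(chartr("Tt", "Uu", toupper(as.character(set[[1]]))),
    name = names(set)[1]
  )
}

write_tsv_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(x, tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  file.rename(tmp, path)
  invisible(path)
}
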