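#' Read a reference set from FASTA
#'
#' Loads a FASTA file into a reference-set tibble. Sequences are uppercased,
#' multi-line records are concatenated, and any IUPAC ambiguity code other
#' than `N` is replaced by `N` with a warning. Gzipped files are read
#' transparently.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return A tibble with columns `name`, `sequence` and `length`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGT", "ACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  # FASTA headers keep only the first whitespace-delimited token as the name
  nm <- sub("\\s.*$", "", names(set))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup) > 0)
    stop("duplicate FASTA header(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ", path)
  n_amb <- sum(vapply(seqs, function(s) nchar(gsub("[ACGTN]", "", s)),
                      numeric(1)))
  if (n_amb > 0) {
    warning(n_amb, " ambiguous (non-ACGTN) base(s) replaced by N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  reference_set(nm, unname(seqs))
}

#' Construct a reference set
#'
#' @param name Character vector of unique sequence names.
#' @param sequence Character vector of nucleotide sequences over `ACGTN`.
#' @return A tibble with columns `name`, `sequence`, `length`.
#' @export
reference_set <- function(name, sequence) {
  stopifnot(length(name) == length(sequence))
  if (anyDuplicated(name)) stop("reference names must be unique")
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("reference sequences must be non-empty")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("reference sequence contains non-ACGTN characters: ",
         paste(name[bad], collapse = ", "))
  tibble::tibble(name = as.character(name), sequence = sequence,
                 length = nchar(sequence))
}

check_reference_set <- function(refs) {
  if (!is.data.frame(refs) || !all(c("name", "sequence") %in% names(refs)))
    stop("expected a reference set tibble with columns `name` and `sequence`")
  if (is.null(refs$length)) refs$length <- nchar(refs$sequence)
  refs
}

#' Write a reference set to FASTA
#'
#' @param refs Reference-set tibble (see [reference_set()]).
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path, width = 70L) {
  refs <- check_reference_set(refs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(refs))) {
    writeLines(paste0(">", refs$name[i]), con)
    s <- refs$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read single-end reads from FASTQ
#'
#' Parses a 4-line-record FASTQ file into a read tibble. Sequences are
#' uppercased; characters other than `ACGTN` are an error, as is a quality
#' string whose length differs from its sequence (reported with the record
#' number). Gzipped files are read transparently.
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  # structural validation first: 4-line records, matching lengths, with
  # record numbers in the error messages
  con <- gzfile(path, "r")
  ln <- readLines(con)
  close(con)
  if (length(ln) == 0) {
    return(tibble::tibble(id = character(), sequence = character(),
                          quality = character()))
  }
  if (length(ln) %% 4 != 0)
    stop("truncated FASTQ record at end of ", path)
  rec_at <- seq(1L, length(ln), by = 4L)
  if (any(substring(ln[rec_at], 1, 1) != "@") ||
      any(substring(ln[rec_at + 2L], 1, 1) != "+"))
    stop("malformed FASTQ record ",
         which(substring(ln[rec_at], 1, 1) != "@" |
                 substring(ln[rec_at + 2L], 1, 1) != "+")[1],
         " in ", path)
  len_mismatch <- which(nchar(ln[rec_at + 1L]) != nchar(ln[rec_at + 3L]))
  if (length(len_mismatch) > 0)
    stop("sequence/quality length mismatch in FASTQ record ",
         len_mismatch[1])
  parsed <- tryCatch({
    set <- Biostrings::readBStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(names = names(set), seqs = toupper(as.character(set)),
         qual = as.character(S4Vectors::mcols(set)$qualities))
  }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                              conditionMessage(e)))
  if (length(parsed$seqs) == 0) {
    return(tibble::tibble(id = character(), sequence = character(),
                          quality = character()))
  }
  seqs <- parsed$seqs
  qual <- parsed$qual
  bad_chr <- which(grepl("[^ACGTN]", seqs))
  if (length(bad_chr) > 0)
    stop("non-nucleotide characters (not ACGTN) in FASTQ record ",
         bad_chr[1])
  bad_len <- which(nchar(qual) != nchar(seqs))
  if (length(bad_len) > 0)
    stop("sequence/quality length mismatch in FASTQ record ", bad_len[1])
  if (any(!nzchar(seqs))) stop("zero-length read in FASTQ: ", path)
  tibble::tibble(id = sub("\\s.*$", "", parsed$names),
                 sequence = unname(seqs), quality = unname(qual))
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with columns `id`, `sequence` and optionally
#'   `quality` (defaults to maximal Sanger quality `I`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  qual <- reads$quality
  if (is.null(qual))
    qual <- vapply(nchar(reads$sequence),
                   function(n) strrep("I", n), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", qual), con)
  invisible(path)
}
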