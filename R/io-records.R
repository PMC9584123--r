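NATIVE_HEADER <- "#read_id\tref\tpos\tstrand\tedits\talign"

#' Write mapping records to the native three-file output
#'
#' Uniquely mapped records go to `unique_path`, multi-mapped records (one
#' line per best location) to `multi_path`, and unmapped read ids to
#' `unmapped_path`, so downstream analyses that use only unique reads can
#' work from a single file. The native format is tab-separated with header
#' `#read_id ref pos strand edits align`; `pos` is 1-based in this
#' human-readable output (coordinates are 0-based internally).
#'
#' @param records Mapping-record tibble from [map_reads()].
#' @param unique_path,multi_path,unmapped_path Output paths.
#' @return Invisibly, a named list of the three paths.
#' @export
write_mapping_records <- function(records, unique_path, multi_path,
                                  unmapped_path) {
  stopifnot(all(c("read_id", "status") %in% names(records)))
  fmt <- function(df) {
    if (nrow(df) == 0) return(character(0))
    paste(df$read_id, df$ref_name, df$ref_start + 1L, df$strand,
          df$edit_distance, df$alignment, sep = "\t")
  }
  uq <- dplyr::filter(records, .data$status == "unique")
  mu <- dplyr::filter(records, .data$status == "multi")
  un <- dplyr::distinct(dplyr::filter(records, .data$status == "unmapped"),
                        .data$read_id)
  writeLines(c(NATIVE_HEADER, fmt(uq)), unique_path)
  writeLines(c(NATIVE_HEADER, fmt(mu)), multi_path)
  writeLines(c("#read_id", un$read_id), unmapped_path)
  invisible(list(unique = unique_path, multi = multi_path,
                 unmapped = unmapped_path))
}

parse_native_tsv <- function(path, status) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != NATIVE_HEADER)
    stop("not a native mapping file (missing header): ", path)
  lines <- lines[-1]
  if (length(lines) == 0)
    return(tibble::tibble(read_id = character(), status = character(),
                          ref_name = character(), strand = character(),
                          ref_start = integer(), edit_distance = integer(),
                          alignment = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6)
  if (length(bad) > 0)
    stop("malformed record at line ", bad[1] + 1, " of ", path)
  m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
  tibble::tibble(read_id = m[, 1], status = status, ref_name = m[, 2],
                 strand = m[, 4], ref_start = as.integer(m[, 3]) - 1L,
                 edit_distance = as.integer(m[, 5]), alignment = m[, 6])
}

TRANSCRIPT_TOKEN_RE <- "[0-9]+=|[0-9]+D|X[ACGTN]|I[ACGTN]+"

# Reference columns consumed by an alignment transcript (matches + X + D).
transcript_ref_span <- function(alignment) {
  vapply(alignment, function(cig) {
    toks <- regmatches(cig, gregexpr(TRANSCRIPT_TOKEN_RE, cig))[[1]]
    span <- 0L
    for (t in toks) {
      if (grepl("^[0-9]+[=D]$", t))
        span <- span + as.integer(sub("[=D]", "", t))
      else if (startsWith(t, "X")) span <- span + 1L
    }
    span
  }, integer(1), USE.NAMES = FALSE)
}

transcript_mismatches <- function(alignment) {
  lengths(regmatches(alignment, gregexpr("X[ACGTN]", alignment)))
}

#' Read native mapping records back
#'
#' Reconstructs a mapping-record tibble from the three-file native output;
#' `mismatches`, `ref_end` and `n_best` are recovered from the alignment
#' transcripts.
#'
#' @param unique_path,multi_path,unmapped_path Paths written by
#'   [write_mapping_records()].
#' @return A mapping-record tibble.
#' @export
read_mapping_records <- function(unique_path, multi_path, unmapped_path) {
  uq <- parse_native_tsv(unique_path, "unique")
  mu <- parse_native_tsv(multi_path, "multi")
  aln <- dplyr::bind_rows(uq, mu)
  aln$ref_end <- aln$ref_start + transcript_ref_span(aln$alignment)
  aln$mismatches <- as.integer(transcript_mismatches(aln$alignment))
  aln <- dplyr::mutate(
    dplyr::group_by(aln, .data$read_id), n_best = dplyr::n(),
    .keep = "all")
  aln <- dplyr::ungroup(aln)
  un_lines <- readLines(unmapped_path)
  if (length(un_lines) == 0 || un_lines[1] != "#read_id")
    stop("not a native unmapped file (missing header): ", unmapped_path)
  un <- tibble::tibble(read_id = un_lines[-1], status = "unmapped",
                       n_best = 0L)
  out <- dplyr::bind_rows(aln, un)
  out$reason <- ifelse(out$status == "unmapped", "no_alignment", "")
  out <- dplyr::relocate(out, "read_id", "status", "reason", "ref_name",
                         "strand", "ref_start", "ref_end", "mismatches",
                         "edit_distance", "alignment", "n_best")
  class(out) <- c("seedmap_records", class(out))
  out
}

#' Export mapping records as single-end SAM
#'
#' Optional interoperability output. Emits unpaired records with standard
#' CIGAR (`=`/`X` collapsed to `M`); the native record does not carry the
#' read sequence, so SEQ/QUAL are `*`. Multi-mapped locations beyond the
#' first are flagged secondary (0x100).
#'
#' @param records Mapping-record tibble.
#' @param refs Reference-set tibble (for `@SQ` headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, refs, path) {
  refs <- check_reference_set(refs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(paste0("@SQ\tSN:", refs$name, "\tLN:", refs$length), con)
  mapped <- dplyr::filter(records, .data$status != "unmapped")
  if (nrow(mapped) > 0) {
    cig <- vapply(mapped$alignment, function(tr) {
      toks <- regmatches(tr, gregexpr(TRANSCRIPT_TOKEN_RE, tr))[[1]]
      ops <- character(0)
      for (t in toks) {
        if (grepl("^[0-9]+=$", t)) ops <- c(ops, paste0(sub("=", "", t), "M"))
        else if (grepl("^[0-9]+D$", t)) ops <- c(ops, t)
        else if (startsWith(t, "X")) ops <- c(ops, "1M")
        else ops <- c(ops, paste0(nchar(t) - 1L, "I"))
      }
      # merge adjacent M runs
      rl <- rle(gsub("[0-9]+", "", ops))
      n <- as.integer(gsub("[MID]", "", ops))
      out <- character(0)
      i <- 1
      for (k in seq_along(rl$lengths)) {
        tot <- sum(n[i:(i + rl$lengths[k] - 1)])
        out <- c(out, paste0(tot, rl$values[k]))
        i <- i + rl$lengths[k]
      }
      paste(out, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    first <- !duplicated(mapped$read_id)
    flag <- ifelse(mapped$strand == "-", 16L, 0L) +
      ifelse(first, 0L, 256L)
    writeLines(paste(mapped$read_id, flag, mapped$ref_name,
                     mapped$ref_start + 1L, ifelse(first, 60L, 0L), cig,
                     "*", 0L, 0L, "*", "*",
                     paste0("NM:i:", mapped$edit_distance), sep = "\t"), con)
  }
  unm <- dplyr::filter(records, .data$status == "unmapped")
  if (nrow(unm) > 0)
    writeLines(paste(unm$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, "*",
                     "*", sep = "\t"), con)
  invisible(path)
}

#' Write variant calls to VCF 4.2
#'
#' Minimal VCF: `QUAL = -10 log10(p)` capped at 999; `INFO` carries `DP`,
#' `AC` (alt observation count), `TYPE` and the informational genotype flag.
#' Deletions are anchored at the reference base before the event per VCF
#' convention.
#'
#' @param calls Variant-call tibble from [call_variants()], sorted by
#'   (reference, position).
#' @param refs Reference-set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, refs, path) {
  refs <- check_reference_set(refs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pile-up depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt observation count\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"snv, ins or del\">",
    "##INFO=<ID=GT,Number=1,Type=String,Description=\"Informational het/hom flag\">",
    paste0("##contig=<ID=", refs$name, ",length=", refs$length, ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0) {
    idx <- match(calls$ref_name, refs$name)
    if (anyNA(idx)) stop("call on unknown reference")
    pos1 <- calls$position
    refseq <- refs$sequence[idx]
    reflen <- refs$length[idx]
    ref_a <- calls$ref_allele
    alt_a <- calls$alt_allele
    # anchor indels at the preceding base
    for (i in seq_len(nrow(calls))) {
      if (calls$type[i] == "del") {
        end <- pos1[i] + nchar(ref_a[i]) - 1L
        if (end > reflen[i]) stop("call position exceeds reference length")
        if (pos1[i] > 1L) {
          anchor <- substring(refseq[i], pos1[i] - 1L, pos1[i] - 1L)
          ref_a[i] <- paste0(anchor, ref_a[i])
          alt_a[i] <- anchor
          pos1[i] <- pos1[i] - 1L
        } else {
          alt_a[i] <- substring(refseq[i], end + 1L, end + 1L)
          ref_a[i] <- paste0(ref_a[i], alt_a[i])
        }
      } else if (calls$type[i] == "ins") {
        if (pos1[i] > reflen[i]) stop("call position exceeds reference length")
        anchor <- substring(refseq[i], pos1[i], pos1[i])
        ref_a[i] <- anchor
        alt_a[i] <- paste0(anchor, calls$alt_allele[i])
      } else if (pos1[i] > reflen[i]) {
        stop("call position exceeds reference length")
      }
    }
    qual <- pmin(999, round(-10 * log10(pmax(calls$p_value, 1e-300)), 1))
    info <- paste0("DP=", calls$depth, ";AC=", calls$alt_count, ";TYPE=",
                   calls$type, ";GT=", calls$genotype)
    writeLines(paste(calls$ref_name, pos1, ".", ref_a, alt_a, qual, "PASS",
                     info, sep = "\t"), con)
  }
  invisible(path)
}
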