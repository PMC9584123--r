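#' Count uniquely mapped reads per transcript
#'
#' Only `unique` records count; multi-mapped and unmapped reads are
#' excluded, matching the downstream convention of analyzing the
#' unique-read file alone.
#'
#' @param records Mapping-record tibble from a run against a spliced-RNA
#'   reference set.
#' @return Tibble: `transcript_id`, `unique_count`.
#' @export
count_unique <- function(records) {
  uq <- dplyr::filter(records, .data$status == "unique")
  dplyr::count(uq, transcript_id = .data$ref_name, name = "unique_count")
}

#' RPKM from a read count
#'
#' `1e9 * count / (total_mapped * length_nt)` — reads per kilobase of
#' transcript per million mapped reads.
#'
#' @param count Unique-read count for the transcript.
#' @param length_nt Transcript length in nucleotides (> 0).
#' @param total_mapped Total mapped reads in the run (> 0).
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop("length_nt must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  1e9 * count / (total_mapped * length_nt)
}

#' Expression table in RPKM
#'
#' Builds the per-transcript expression table from a mapping run:
#' unique-read counts and RPKM over the full transcript universe of the
#' reference set (transcripts with no unique reads get count 0, RPKM 0).
#' `total_mapped` defaults to the number of reads counted (unique), so that
#' RPKM is internally consistent with the unique-only counting rule.
#'
#' @param records Mapping-record tibble.
#' @param refs Reference-set tibble (transcript universe and lengths).
#' @param total_mapped Denominator for RPKM; defaults to the total unique
#'   count in `records`.
#' @return Tibble: `transcript_id`, `length_nt`, `unique_count`, `rpkm`.
#' @export
quantify_expression <- function(records, refs, total_mapped = NULL) {
  refs <- check_reference_set(refs)
  counts <- count_unique(records)
  out <- tibble::tibble(transcript_id = refs$name, length_nt = refs$length)
  out <- dplyr::left_join(out, counts, by = "transcript_id")
  out$unique_count <- dplyr::coalesce(out$unique_count, 0L)
  if (is.null(total_mapped)) total_mapped <- sum(out$unique_count)
  if (total_mapped <= 0) stop("no mapped reads: total_mapped must be > 0")
  out$rpkm <- compute_rpkm(out$unique_count, out$length_nt, total_mapped)
  out
}

#' Correlation between two quantifications
#'
#' Pearson correlation of `log10(rpkm + pseudo)` (or raw RPKM with
#' `transform = "identity"`) over transcripts detected (count > 0) in at
#' least one of the two tables. Used to measure how robust a
#' quantification is to the mapping error allowance.
#'
#' @param table_a,table_b Expression tibbles from [quantify_expression()]
#'   over the same transcript universe.
#' @param transform `"log10"` (default) or `"identity"`.
#' @param pseudo Pseudo-count added before the log (default 0.01 RPKM).
#' @return One-row tibble: `r` (Pearson), `n` (transcripts used).
#' @export
quant_correlation <- function(table_a, table_b, transform = "log10",
                              pseudo = 0.01) {
  transform <- match.arg(transform, c("log10", "identity"))
  j <- dplyr::inner_join(table_a, table_b, by = "transcript_id",
                         suffix = c("_a", "_b"))
  if (nrow(j) < nrow(table_a) || nrow(j) < nrow(table_b))
    warning("transcript universes differ; using the intersection")
  j <- dplyr::filter(j, .data$unique_count_a > 0 | .data$unique_count_b > 0)
  if (nrow(j) < 3) stop("fewer than 3 shared detected transcripts")
  xa <- j$rpkm_a
  xb <- j$rpkm_b
  if (transform == "log10") {
    xa <- log10(xa + pseudo)
    xb <- log10(xb + pseudo)
  }
  tibble::tibble(r = cor(xa, xb, method = "pearson"), n = nrow(j))
}
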