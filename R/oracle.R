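#' Exhaustive best placements of a read (reference aligner)
#'
#' Brute-force validation aligner: unit-cost semi-global dynamic
#' programming of the read (both orientations) against every full
#' reference sequence, with no seeding, banding or pruning. Returns the
#' global minimum edit distance and every alignment end position achieving
#' it. Quadratic in reference length — intended for validating the mapper
#' on small genomes, not for production mapping.
#'
#' @param sequence Read sequence.
#' @param refs Reference-set tibble.
#' @param allowance Maximum edit distance considered.
#' @return A tibble with columns `ref_name`, `strand`, `ref_end` (0-based
#'   half-open end on the forward reference) and `edit_distance`; zero rows
#'   when no placement is within the allowance.
#' @export
exhaustive_best_alignments <- function(sequence, refs, allowance) {
  refs <- check_reference_set(refs)
  res <- cpp_oracle_best(refs$sequence, toupper(sequence),
                         as.integer(allowance))
  if (res$dist < 0) {
    return(tibble::tibble(ref_name = character(), strand = character(),
                          ref_end = integer(), edit_distance = integer()))
  }
  tibble::tibble(ref_name = refs$name[res$ref + 1L],
                 strand = c("+", "-")[res$strand + 1L],
                 ref_end = res$end,
                 edit_distance = res$dist)
}

#' Cluster equivalent end positions of exhaustive placements
#'
#' Adjacent end positions (gap at most `band`, same reference and strand)
#' describe the same physical locus differing only in boundary tie-breaks;
#' this collapses them to one row per locus.
#'
#' @param best Tibble from [exhaustive_best_alignments()].
#' @param band Clustering gap, normally the mapper's `indel_band`.
#' @return Tibble: `ref_name`, `strand`, `end_min`, `end_max`,
#'   `edit_distance`, one row per locus.
#' @export
cluster_best_ends <- function(best, band = 5L) {
  if (nrow(best) == 0) {
    return(tibble::tibble(ref_name = character(), strand = character(),
                          end_min = integer(), end_max = integer(),
                          edit_distance = integer()))
  }
  best <- dplyr::arrange(best, .data$ref_name, .data$strand, .data$ref_end)
  grp <- dplyr::group_by(best, .data$ref_name, .data$strand)
  best <- dplyr::mutate(grp, cluster = cumsum(
    c(1L, as.integer(diff(.data$ref_end) > band))))
  best <- dplyr::ungroup(best)
  dplyr::summarise(
    dplyr::group_by(best, .data$ref_name, .data$strand, .data$cluster),
    end_min = min(.data$ref_end), end_max = max(.data$ref_end),
    edit_distance = .data$edit_distance[1], .groups = "drop")[
      , c("ref_name", "strand", "end_min", "end_max", "edit_distance")]
}
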