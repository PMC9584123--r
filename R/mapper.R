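#' Mapping parameters
#'
#' Bundles the tunable parameters of the mapper. Exactly one of
#' `max_errors` (absolute edit-distance allowance per read) or
#' `error_percent` (fraction of the read length; the per-read allowance is
#' `floor(error_percent * read_length)`, re-evaluated per read so
#' variable-length data get a proportional budget) must be given.
#'
#' @param seed_length Seed length in `[6, 14]`. Default 10.
#' @param max_errors Absolute per-read error allowance (mismatches plus
#'   inserted/deleted bases share one budget). Default 5.
#' @param error_percent Per-read allowance as a fraction of read length,
#'   e.g. `0.05` for 5\%.
#' @param allow_indels Detect short indels (default `TRUE`).
#' @param indel_band Maximum net indel length tolerated; also the diagonal
#'   band used in hotspot grouping and the window slack in verification.
#'   Default 5 when indels are on; forced to 0 when they are off.
#' @param max_reported_locations Cap on reported best locations for a
#'   multi-mapped read. Default 100.
#' @return A list of class `mapping_params`.
#' @export
mapping_params <- function(seed_length = 10L, max_errors = NULL,
                           error_percent = NULL, allow_indels = TRUE,
                           indel_band = 5L, max_reported_locations = 100L) {
  seed_length <- as.integer(seed_length)
  if (is.na(seed_length) || seed_length < 6L || seed_length > 14L)
    stop("seed_length must be in [6, 14]")
  if (!is.null(max_errors) && !is.null(error_percent))
    stop("give exactly one of max_errors or error_percent")
  if (is.null(max_errors) && is.null(error_percent)) max_errors <- 5L
  if (!is.null(max_errors) && max_errors < 0)
    stop("max_errors must be >= 0")
  if (!is.null(error_percent) &&
      (error_percent < 0 || error_percent >= 1))
    stop("error_percent must be in [0, 1)")
  if (!isTRUE(allow_indels)) indel_band <- 0L
  indel_band <- as.integer(indel_band)
  if (indel_band < 0) stop("indel_band must be >= 0")
  max_reported_locations <- as.integer(max_reported_locations)
  if (max_reported_locations < 1) stop("max_reported_locations must be >= 1")
  structure(list(seed_length = seed_length,
                 max_errors = if (is.null(max_errors)) NULL
                              else as.integer(max_errors),
                 error_percent = error_percent,
                 allow_indels = isTRUE(allow_indels),
                 indel_band = indel_band,
                 max_reported_locations = max_reported_locations),
            class = "mapping_params")
}

#' Split a read into seeds
#'
#' Non-overlapping seeds at offsets `0, s, 2s, ...`; when the read length is
#' not a multiple of the seed length, one extra seed is anchored at
#' `L - s` (overlapping the last full seed) so the read tail is covered.
#' Seeds containing `N` are emitted but can match nothing in the index.
#'
#' @param sequence Read sequence.
#' @param seed_length Seed length.
#' @return A tibble with columns `read_offset` (0-based) and `kmer`; zero
#'   rows if the read is shorter than the seed length.
#' @export
split_into_seeds <- function(sequence, seed_length) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  s <- as.integer(seed_length)
  L <- nchar(sequence)
  if (L < s)
    return(tibble::tibble(read_offset = integer(), kmer = character()))
  off <- seq(0L, L - s, by = s)
  if (L %% s != 0L) off <- c(off, L - s)
  tibble::tibble(read_offset = off,
                 kmer = substring(sequence, off + 1L, off + s))
}

#' Reverse complement
#'
#' @param sequence Nucleotide string over `ACGTN` (case-insensitive).
#' @return The reverse complement, uppercase; `N` maps to `N`.
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence))
  up <- toupper(sequence)
  if (any(grepl("[^ACGTN]", up)))
    stop("invalid nucleotide character in sequence")
  out <- character(length(up))
  nz <- nzchar(up)
  if (any(nz))
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(up[nz])))
  out
}

#' Collect hotspots for one read orientation
#'
#' Each seed hit at reference position `p` with read offset `o` proposes the
#' candidate read start `p - o` (clamped at `-indel_band`). Candidates on the
#' same reference are grouped greedily in sorted order so that within a group
#' `max - min <= indel_band`; this "fuzzy" banding lets seeds on either side
#' of a short indel vote for the same locus. Votes count distinct read
#' offsets.
#'
#' @param seeds Seed tibble from [split_into_seeds()] (one orientation).
#' @param index A `seed_index`.
#' @param indel_band Diagonal band width (0 = exact diagonal).
#' @param strand `"+"` or `"-"`, recorded on the hotspots.
#' @return Tibble: `ref`, `ref_name`, `strand`, `candidate_start` (0-based),
#'   `votes`, `diagonal_spread`.
#' @export
collect_hotspots <- function(seeds, index, indel_band, strand = "+") {
  check_seed_index(index)
  stopifnot(all(c("read_offset", "kmer") %in% names(seeds)))
  if (!strand %in% c("+", "-")) stop('strand must be "+" or "-"')
  # Reconstruct the oriented read: seeds tile it completely by construction.
  if (nrow(seeds) == 0)
    return(tibble::tibble(ref = integer(), ref_name = character(),
                          strand = character(), candidate_start = integer(),
                          votes = integer(), diagonal_spread = integer()))
  L <- max(seeds$read_offset) + index$seed_length
  chars <- character(L)
  for (i in seq_len(nrow(seeds))) {
    o <- seeds$read_offset[i]
    chars[(o + 1):(o + index$seed_length)] <-
      strsplit(seeds$kmer[i], "")[[1]]
  }
  read <- paste(chars, collapse = "")
  h <- cpp_collect_hotspots(read, if (strand == "+") 0L else 1L,
                            index$code, index$ref, index$pos,
                            index$seed_length, as.integer(indel_band))
  tibble::tibble(ref = h$ref, ref_name = index$ref_names[h$ref + 1L],
                 strand = strand, candidate_start = h$candidate_start,
                 votes = h$votes, diagonal_spread = h$diagonal_spread)
}

#' Prioritize hotspots
#'
#' Orders pooled hotspots (both orientations) by votes descending, with a
#' total deterministic tie-break: reference ordinal, candidate start, then
#' strand (`+` before `-`).
#'
#' @param hotspots Hotspot tibble as from [collect_hotspots()].
#' @return The same tibble, reordered.
#' @export
prioritize_hotspots <- function(hotspots) {
  dplyr::arrange(hotspots, dplyr::desc(.data$votes), .data$ref,
                 .data$candidate_start,
                 factor(.data$strand, levels = c("+", "-")))
}

#' Verify one candidate locus
#'
#' End-to-end alignment of the full (oriented) read against the reference
#' window `[candidate_start - indel_band, candidate_start + read_length +
#' indel_band)`, scored by unit-cost edit distance (mismatch 1, each inserted
#' or deleted base 1). Windows extending past a reference boundary are
#' truncated. With `allow_indels = FALSE` the check degenerates to a Hamming
#' comparison at `candidate_start`.
#'
#' @param read_seq Oriented read sequence (already reverse-complemented for
#'   minus-strand candidates).
#' @param refs Reference-set tibble.
#' @param ref Reference name or 0-based ordinal of the candidate.
#' @param candidate_start 0-based putative read start.
#' @param allowance Maximum accepted edit distance.
#' @param params A [mapping_params()] object (band and indel mode).
#' @return A one-row tibble (`ref_start`, `ref_end` 0-based half-open,
#'   `mismatches`, `ins_bases`, `del_bases`, `edit_distance`, `alignment`)
#'   or a zero-row tibble when no alignment within the allowance exists.
#' @export
verify_candidate <- function(read_seq, refs, ref, candidate_start, allowance,
                             params = mapping_params()) {
  refs <- check_reference_set(refs)
  if (is.character(ref)) ref <- match(ref, refs$name) - 1L
  if (is.na(ref) || ref < 0 || ref >= nrow(refs)) stop("unknown reference")
  v <- cpp_verify(refs$sequence[ref + 1L], toupper(read_seq),
                  as.integer(candidate_start), params$indel_band,
                  as.integer(allowance), params$allow_indels)
  if (!isTRUE(v$ok))
    return(tibble::tibble(ref_start = integer(), ref_end = integer(),
                          mismatches = integer(), ins_bases = integer(),
                          del_bases = integer(), edit_distance = integer(),
                          alignment = character()))
  tibble::tibble(ref_start = v$ref_start, ref_end = v$ref_end,
                 mismatches = v$mismatches, ins_bases = v$ins_bases,
                 del_bases = v$del_bases, edit_distance = v$edit_distance,
                 alignment = v$cigar)
}

aln_to_tibble <- function(res, index, read_ids) {
  a <- res$aln
  tibble::tibble(
    read_id = read_ids[a$read_idx],
    ref = a$ref,
    ref_name = index$ref_names[a$ref + 1L],
    strand = c("+", "-")[a$strand + 1L],
    ref_start = a$ref_start,
    ref_end = a$ref_end,
    mismatches = a$mismatches,
    edit_distance = a$edit_distance,
    alignment = a$alignment)
}

#' Map reads against a seed index
#'
#' The core per-read pipeline: seeds are generated for the read and its
#' reverse complement, hotspots collected and prioritized, and candidates
#' verified in priority order. Verification stops early only when the
#' remaining hotspots' vote counts cannot beat the best edit distance found
#' (pigeonhole bound). All distinct locations achieving the minimal edit
#' distance are retained (up to `max_reported_locations`); two locations are
#' distinct if they differ in reference, strand, or by more than
#' `indel_band` in start position. A read is `unique` with exactly one best
#' location, `multi` with several, `unmapped` otherwise.
#'
#' @param reads Read tibble (`id`, `sequence`, optionally `quality`), e.g.
#'   from [read_fastq()]. Qualities are carried but never used in scoring.
#' @param index A `seed_index` from [build_index()].
#' @param params A [mapping_params()] object.
#' @return A tibble of mapping records, one row per reported alignment and
#'   one row per unmapped read (alignment columns `NA`): `read_id`,
#'   `status` (`unique`/`multi`/`unmapped`), `reason`, `ref_name`, `strand`,
#'   `ref_start`/`ref_end` (0-based half-open), `mismatches`,
#'   `edit_distance`, `alignment`, `n_best`. The run summary is attached as
#'   attribute `"summary"` and available via [glance.seedmap_records()].
#' @export
map_reads <- function(reads, index, params = mapping_params()) {
  check_seed_index(index)
  stopifnot(all(c("id", "sequence") %in% names(reads)))
  percent_mode <- !is.null(params$error_percent)
  res <- cpp_map_reads(
    toupper(reads$sequence), index$code, index$ref, index$pos,
    index$sequences, params$seed_length,
    if (percent_mode) 0 else params$max_errors,
    if (percent_mode) params$error_percent else 0,
    percent_mode, params$allow_indels, params$indel_band,
    params$max_reported_locations)
  status <- c("unmapped", "unique", "multi")[res$status + 1L]
  per_read <- tibble::tibble(read_id = reads$id, status = status,
                             reason = res$reason, n_best = res$n_best)
  aln <- aln_to_tibble(res, index, reads$id)
  out <- dplyr::left_join(per_read, aln, by = "read_id")
  out <- dplyr::relocate(out, "read_id", "status", "reason", "ref_name",
                         "strand", "ref_start", "ref_end", "mismatches",
                         "edit_distance", "alignment", "n_best")
  out$ref <- NULL
  n <- nrow(reads)
  counts <- table(factor(status, levels = c("unique", "multi", "unmapped")))
  summary <- tibble::tibble(
    total = n,
    unique = as.integer(counts[["unique"]]),
    multi = as.integer(counts[["multi"]]),
    unmapped = as.integer(counts[["unmapped"]]),
    mapping_rate = if (n == 0) 0 else
      (counts[["unique"]] + counts[["multi"]]) / n,
    empty_input = n == 0)
  attr(out, "summary") <- summary
  class(out) <- c("seedmap_records", class(out))
  out
}

#' Map a single read
#'
#' Convenience wrapper around [map_reads()] for one read.
#'
#' @param sequence Read sequence (a plain string).
#' @param index A `seed_index`.
#' @param params A [mapping_params()] object.
#' @param id Read id used in the output.
#' @return A mapping-record tibble as from [map_reads()].
#' @export
map_read <- function(sequence, index, params = mapping_params(),
                     id = "read") {
  map_reads(tibble::tibble(id = id, sequence = sequence), index, params)
}

#' Run summary of a mapping
#'
#' One-row tibble with read counts by status and the mapping rate
#' `(unique + multi) / total`.
#'
#' @param x A mapping-record tibble from [map_reads()].
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance seedmap_records
#' @export
glance.seedmap_records <- function(x, ...) {
  s <- attr(x, "summary")
  if (is.null(s)) {
    per_read <- dplyr::distinct(x, .data$read_id, .data$status)
    counts <- table(factor(per_read$status,
                           levels = c("unique", "multi", "unmapped")))
    n <- nrow(per_read)
    s <- tibble::tibble(
      total = n,
      unique = as.integer(counts[["unique"]]),
      multi = as.integer(counts[["multi"]]),
      unmapped = as.integer(counts[["unmapped"]]),
      mapping_rate = if (n == 0) 0 else
        (counts[["unique"]] + counts[["multi"]]) / n,
      empty_input = n == 0)
  }
  s
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Upper bound on the per-read mismapping probability
#'
#' Binomial seed-corruption model: with per-base error rate `p`, a seed of
#' length `s` is error-free with probability `(1-p)^s`; a read yields
#' `m = floor(L/s)` non-overlapping seeds, and the true locus can only be
#' missed when every seed carries at least one error. The returned value is
#' `q^m` with `q = 1 - (1-p)^s` — for typical short-read settings (L = 100,
#' s = 10, p = 0.01) about 6.4e-11, i.e. below the 1e-9 regime.
#'
#' @param read_length Read length `L`.
#' @param seed_length Seed length `s <= L`.
#' @param per_base_error_rate Error probability `p` in `[0, 1)`.
#' @return The probability that no seed anchors the true locus.
#' @export
estimate_mismap_probability <- function(read_length, seed_length,
                                        per_base_error_rate) {
  p <- per_base_error_rate
  if (any(p < 0 | p >= 1)) stop("per_base_error_rate must be in [0, 1)")
  if (any(seed_length > read_length)) stop("seed_length must be <= read_length")
  m <- floor(read_length / seed_length)
  q <- 1 - (1 - p)^seed_length
  q^m
}
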