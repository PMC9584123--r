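#' Build a whole-reference seed index
#'
#' Indexes every position of every N-free k-mer of each reference on the
#' forward strand (the mapper queries the read and its reverse complement,
#' so a forward-only index suffices). The index covers the entire reference
#' set so the globally best hotspot can always be prioritized; it is held
#' fully in memory.
#'
#' @param refs Reference-set tibble ([reference_set()] / [read_fasta()]).
#' @param seed_length Seed length `k`, an integer in `[6, 14]`.
#' @return An object of class `seed_index`.
#' @export
#' @examples
#' refs <- reference_set("r", "ACGTACGTAC")
#' idx <- build_index(refs, 6)
#' index_stats(idx)
build_index <- function(refs, seed_length) {
  refs <- check_reference_set(refs)
  seed_length <- as.integer(seed_length)
  if (length(seed_length) != 1 || is.na(seed_length) ||
      seed_length < 6L || seed_length > 14L)
    stop("seed_length must be a single integer in [6, 14]")
  short <- refs$length < seed_length
  if (any(short))
    warning("reference(s) shorter than the seed length contribute no seeds: ",
            paste(refs$name[short], collapse = ", "))
  tab <- cpp_build_index(refs$sequence, seed_length)
  structure(
    list(seed_length = seed_length,
         ref_names = refs$name,
         ref_lengths = refs$length,
         sequences = refs$sequence,
         code = tab$code, ref = tab$ref, pos = tab$pos,
         total_positions = length(tab$code)),
    class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("<seed_index> seed length", x$seed_length, "over",
      length(x$ref_names), "reference(s),",
      format(sum(x$ref_lengths), big.mark = ","), "nt,",
      format(x$total_positions, big.mark = ","), "indexed positions\n")
  invisible(x)
}

check_seed_index <- function(index) {
  if (!inherits(index, "seed_index")) stop("expected a `seed_index` object")
  index
}

#' Query the seed index for one k-mer
#'
#' @param index A `seed_index`.
#' @param kmer A string of exactly `seed_length` characters. k-mers
#'   containing `N` match nothing.
#' @return A tibble with columns `ref` (0-based reference ordinal),
#'   `ref_name` and `position` (0-based), ordered by reference then
#'   position; zero rows if the k-mer is absent.
#' @export
query_seed <- function(index, kmer) {
  check_seed_index(index)
  if (!is.character(kmer) || length(kmer) != 1 ||
      nchar(kmer) != index$seed_length)
    stop("query length must equal the index seed length (",
         index$seed_length, ")")
  code <- cpp_encode_kmer(toupper(kmer))
  if (is.na(code)) {
    hit <- integer(0)
  } else {
    lo <- findInterval(code - 0.5, index$code)
    hi <- findInterval(code + 0.5, index$code)
    hit <- if (hi > lo) seq(lo + 1L, hi) else integer(0)
  }
  tibble::tibble(ref = index$ref[hit],
                 ref_name = index$ref_names[index$ref[hit] + 1L],
                 position = index$pos[hit])
}

#' Summary statistics of a seed index
#'
#' @param index A `seed_index`.
#' @return A one-row tibble: `seed_length`, `distinct_kmers`,
#'   `total_positions`, `max_positions_per_kmer`.
#' @export
index_stats <- function(index) {
  check_seed_index(index)
  if (index$total_positions == 0) {
    return(tibble::tibble(seed_length = index$seed_length,
                          distinct_kmers = 0L, total_positions = 0L,
                          max_positions_per_kmer = 0L))
  }
  runs <- rle(index$code)
  tibble::tibble(seed_length = index$seed_length,
                 distinct_kmers = length(runs$lengths),
                 total_positions = index$total_positions,
                 max_positions_per_kmer = max(runs$lengths))
}
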