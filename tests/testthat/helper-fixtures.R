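# Shared fixture builders. Everything is generated in code; no data files.

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}

write_temp_fastq <- function(lines) {
  f <- tempfile(fileext = ".fq")
  writeLines(lines, f)
  f
}

# A deterministic random genome + index at the given seed length.
toy_genome <- function(length = 5000, seed = 101, name = "chr1") {
  simulate_genome(length, seed = seed, name = name)
}

# Reference full DP (unit cost, semi-global over the given sequence) used as
# an independent check of alignment distances; returns the vector of
# distances by end position (1-based index j+1 = end j).
full_dp_ends <- function(read, refseq) {
  L <- nchar(read)
  T <- nchar(refseq)
  r <- strsplit(read, "")[[1]]
  s <- strsplit(refseq, "")[[1]]
  prev <- rep(0L, T + 1)
  for (i in 1:L) {
    cur <- integer(T + 1)
    cur[1] <- i
    mism <- (r[i] != s) | (r[i] == "N") | (s == "N")
    for (j in 1:T) {
      cur[j + 1] <- min(prev[j] + mism[j], prev[j + 1] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev
}

# Minimum semi-global distance of read vs both strands of a reference set.
full_dp_best <- function(read, refs) {
  best <- Inf
  for (s in refs$sequence) {
    best <- min(best, full_dp_ends(read, s),
                full_dp_ends(reverse_complement(read), s))
  }
  best
}

# Compare the mapper's best locations with the exhaustive oracle for one
# read; returns TRUE when the minimal distance and the clustered location
# sets agree. Locations are identified by alignment end position; two
# co-optimal interpretations of the same locus (e.g. a deletion vs an
# equal-cost insertion reading) share a start but can differ in end by up
# to twice the indel band, so clustering and matching use 2 * band.
mapper_matches_oracle <- function(sequence, refs, index, params) {
  allowance <- if (!is.null(params$error_percent))
    floor(params$error_percent * nchar(sequence)) else params$max_errors
  band2 <- max(2L * params$indel_band, 1L)
  oracle <- exhaustive_best_alignments(sequence, refs, allowance)
  rec <- map_read(sequence, index, params)
  mapped <- rec$status[1] != "unmapped"
  if (nrow(oracle) == 0) return(!mapped)
  if (!mapped) return(FALSE)
  if (rec$edit_distance[1] != oracle$edit_distance[1]) return(FALSE)
  clusters <- cluster_best_ends(oracle, band = band2)
  if (nrow(clusters) != rec$n_best[1]) return(FALSE)
  hit <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    m <- clusters$ref_name == rec$ref_name[i] &
      clusters$strand == rec$strand[i] &
      rec$ref_end[i] >= clusters$end_min - band2 &
      rec$ref_end[i] <= clusters$end_max + band2
    hit[i] <- any(m)
  }
  all(hit)
}
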