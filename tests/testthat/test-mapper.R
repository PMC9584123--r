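test_that("seed decomposition covers the read with a tail-anchored seed", {
  s4 <- split_into_seeds("ACGTACGT", 4)
  expect_equal(s4$read_offset, c(0L, 4L))
  s10 <- split_into_seeds("ACGTACGTAC", 4)
  expect_equal(s10$read_offset, c(0L, 4L, 6L))
  expect_equal(s10$kmer, c("ACGT", "ACGT", "GTAC"))
  long <- paste(rep("ACGTACGTAC", 10), collapse = "")
  s100 <- split_into_seeds(long, 10)
  expect_equal(s100$read_offset, seq(0L, 90L, by = 10L))
  expect_equal(nrow(split_into_seeds("ACG", 6)), 0)
})

test_that("reverse complement handles N and validates input", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AACN"), "NGTT")
  expect_equal(reverse_complement(""), "")
  expect_error(reverse_complement("ACXT"), "invalid")
})

test_that("a deletion splits or merges hotspots according to the band", {
  # 200 nt reference; read copies positions 51..150 with one base deleted
  # mid-read, so seeds left of the deletion imply start c and seeds right
  # of it imply c+1.
  g <- toy_genome(200, seed = 31)
  idx <- build_index(g, 10)
  window <- substring(g$sequence, 51, 151)  # 101 nt
  read <- paste0(substring(window, 1, 50), substring(window, 52, 101))
  expect_equal(nchar(read), 100)
  seeds <- split_into_seeds(read, 10)

  merged <- collect_hotspots(seeds, idx, indel_band = 3)
  merged <- merged[merged$votes > 1, ]
  expect_equal(nrow(merged), 1)
  expect_equal(merged$votes, 10L)
  expect_equal(merged$diagonal_spread, 1L)
  expect_equal(merged$candidate_start, 50L)

  split0 <- collect_hotspots(seeds, idx, indel_band = 0)
  split0 <- split0[split0$votes > 1, ]
  expect_equal(nrow(split0), 2)
  expect_setequal(split0$votes, c(5L, 5L))
  expect_setequal(split0$candidate_start, c(50L, 51L))

  # the full mapper agrees with the unbanded DP oracle on this read
  rec <- map_read(read, idx, mapping_params())
  expect_equal(rec$status, "unique")
  expect_equal(rec$edit_distance, 1L)
  expect_equal(full_dp_best(read, g), 1)
})

test_that("error-free reads produce a single full-vote hotspot", {
  g <- toy_genome(2000, seed = 33)
  idx <- build_index(g, 10)
  read <- substring(g$sequence, 301, 400)
  hs <- collect_hotspots(split_into_seeds(read, 10), idx, indel_band = 5)
  top <- hs[which.max(hs$votes), ]
  expect_equal(top$votes, 10L)
  expect_equal(top$diagonal_spread, 0L)
  expect_equal(top$candidate_start, 300L)
})

test_that("hotspot prioritization is total and deterministic", {
  hs <- tibble::tibble(ref = c(0L, 1L, 0L, 0L),
                       ref_name = "chr1",
                       strand = c("-", "+", "+", "+"),
                       candidate_start = c(10L, 5L, 5L, 7L),
                       votes = c(7L, 7L, 3L, 7L),
                       diagonal_spread = 0L)
  p <- prioritize_hotspots(hs)
  expect_equal(p$votes, c(7L, 7L, 7L, 3L))
  expect_equal(p$candidate_start, c(7L, 10L, 5L, 5L))
  expect_equal(p$strand, c("+", "-", "+", "+"))
})

test_that("verification scores substitutions and indels by unit cost", {
  g <- toy_genome(500, seed = 35)
  window <- substring(g$sequence, 101, 200)
  p <- mapping_params()

  identical_hit <- verify_candidate(window, g, "chr1", 100, 5, p)
  expect_equal(identical_hit$edit_distance, 0L)
  expect_equal(identical_hit$mismatches, 0L)
  expect_equal(identical_hit$ref_start, 100L)
  expect_equal(identical_hit$ref_end, 200L)
  expect_equal(identical_hit$alignment, "100=")

  sub <- window
  substring(sub, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                    substring(sub, 40, 40))[1]
  one_sub <- verify_candidate(sub, g, "chr1", 100, 5, p)
  expect_equal(one_sub$edit_distance, 1L)
  expect_equal(one_sub$mismatches, 1L)
  expect_equal(one_sub$ins_bases + one_sub$del_bases, 0L)

  # 2-nt deletion relative to the reference; agreement with unbanded DP
  del2 <- paste0(substring(window, 1, 30), substring(window, 33, 100))
  hit <- verify_candidate(del2, g, "chr1", 100, 5, p)
  expect_equal(hit$edit_distance, 2L)
  expect_equal(hit$del_bases, 2L)
  expect_equal(hit$mismatches, 0L)
  expect_equal(min(full_dp_ends(del2, g$sequence)), 2)

  # beyond allowance returns nothing
  expect_equal(nrow(verify_candidate(del2, g, "chr1", 100, 1, p)), 0)

  # Hamming mode rejects the shifted read but accepts substitutions
  ham <- mapping_params(allow_indels = FALSE)
  expect_equal(verify_candidate(sub, g, "chr1", 100, 5, ham)$edit_distance,
               1L)
  expect_equal(nrow(verify_candidate(del2, g, "chr1", 100, 5, ham)), 0)
})

test_that("reads overhanging the reference end are rejected", {
  g <- toy_genome(300, seed = 37)
  tailread <- paste0(substring(g$sequence, 281, 300), strrep("A", 30))
  p <- mapping_params()
  expect_equal(nrow(verify_candidate(tailread, g, "chr1", 280, 3, p)), 0)
})

test_that("unique, multi and unmapped classification works by construction", {
  base <- toy_genome(10000, seed = 39)
  dup <- substring(base$sequence, 2001, 2100)
  genome <- reference_set(
    "chr1", paste0(base$sequence, strrep("N", 20), dup))
  idx <- build_index(genome, 10)
  p <- mapping_params()

  uniq <- map_read(substring(base$sequence, 5001, 5100), idx, p)
  expect_equal(uniq$status, "unique")
  expect_equal(uniq$edit_distance, 0L)
  expect_equal(uniq$ref_start, 5000L)
  expect_equal(uniq$strand, "+")

  multi <- map_read(dup, idx, p)
  expect_equal(unique(multi$status), "multi")
  expect_equal(nrow(multi), 2)
  expect_equal(unique(multi$edit_distance), 0L)
  expect_setequal(multi$ref_start, c(2000L, 10020L))

  rc <- reverse_complement(substring(base$sequence, 7001, 7100))
  minus <- map_read(rc, idx, p)
  expect_equal(minus$status, "unique")
  expect_equal(minus$strand, "-")
  expect_equal(minus$ref_start, 7000L)

  random <- withr::with_seed(40, paste(
    sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""))
  nomap <- map_read(random, idx, p)
  expect_equal(nomap$status, "unmapped")
  expect_gt(full_dp_best(random, genome), p$max_errors)

  short <- map_read("ACGTA", idx, p)
  expect_equal(short$status, "unmapped")
  expect_equal(short$reason, "too_short")
})

test_that("pigeonhole completeness: the true locus is always a hotspot", {
  # exhaustive over substitution-position subsets on a fixed genome
  g <- toy_genome(1500, seed = 41)
  for (s in c(6L, 8L)) {
    idx <- build_index(g, s)
    for (L in c(18L, 24L)) {
      read0 <- substring(g$sequence, 701, 700 + L)
      m0 <- L %/% s
      for (k in 0:min(3, m0 - 1)) {
        combos <- utils::combn(L, k)
        if (ncol(combos) > 150) {
          keep <- withr::with_seed(42, sample(ncol(combos), 150))
          combos <- combos[, keep, drop = FALSE]
        }
        for (ci in seq_len(ncol(combos))) {
          read <- read0
          for (pos in combos[, ci]) {
            old <- substring(read, pos, pos)
            substring(read, pos, pos) <-
              setdiff(c("A", "C", "G", "T"), old)[(pos %% 3) + 1]
          }
          hs <- collect_hotspots(split_into_seeds(read, s), idx, 0)
          expect_true(any(hs$candidate_start == 700L))
        }
      }
    }
  }
})

test_that("mapper matches the exhaustive oracle on error-containing reads", {
  g <- toy_genome(8000, seed = 43)
  idx <- build_index(g, 10)
  p <- mapping_params()
  sim <- simulate_reads(g, 120, 100, sub_rate = 0.02, ins_rate = 0.004,
                        del_rate = 0.004, seed = 44)
  for (i in seq_len(nrow(sim$reads))) {
    expect_true(mapper_matches_oracle(sim$reads$sequence[i], g, idx, p))
  }
})

test_that("percent-mode allowance scales with read length", {
  g <- toy_genome(4000, seed = 45)
  idx <- build_index(g, 10)
  long <- substring(g$sequence, 1001, 1100)   # 100 nt -> allowance 5
  short <- substring(g$sequence, 2001, 2060)  # 60 nt  -> allowance 3
  mutate_n <- function(read, n) {
    for (pos in seq(5, by = 11, length.out = n)) {
      old <- substring(read, pos, pos)
      substring(read, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
    }
    read
  }
  p <- mapping_params(error_percent = 0.05)
  expect_equal(map_read(mutate_n(long, 5), idx, p)$status, "unique")
  expect_equal(map_read(mutate_n(short, 3), idx, p)$status, "unique")
  expect_equal(map_read(mutate_n(short, 4), idx, p)$status, "unmapped")
})

test_that("reads with N map with N counted as mismatch", {
  g <- toy_genome(3000, seed = 47)
  idx <- build_index(g, 10)
  read <- substring(g$sequence, 501, 600)
  substring(read, 25, 26) <- "NN"
  rec <- map_read(read, idx, mapping_params())
  expect_equal(rec$status, "unique")
  expect_equal(rec$edit_distance, 2L)
  expect_equal(rec$ref_start, 500L)
})

test_that("run summary conserves counts and empty input is flagged", {
  g <- toy_genome(3000, seed = 49)
  idx <- build_index(g, 10)
  sim <- simulate_reads(g, 80, 60, sub_rate = 0.05, seed = 50)
  rec <- map_reads(sim$reads, idx, mapping_params(max_errors = 2))
  s <- glance(rec)
  expect_equal(s$unique + s$multi + s$unmapped, s$total)
  expect_equal(s$total, 80L)

  empty <- map_reads(tibble::tibble(id = character(),
                                    sequence = character()), idx,
                     mapping_params())
  se <- glance(empty)
  expect_equal(se$total, 0L)
  expect_equal(se$mapping_rate, 0)
  expect_true(se$empty_input)
})

test_that("mapping rate is monotone in the error allowance", {
  g <- toy_genome(6000, seed = 51)
  idx <- build_index(g, 10)
  sim <- simulate_reads(g, 150, 100, sub_rate = 0.04, seed = 52)
  rates <- vapply(3:7, function(e) {
    glance(map_reads(sim$reads, idx, mapping_params(max_errors = e)))$
      mapping_rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 1)  # allowance 3 drops some 4+-error reads here
})

test_that("results are independent of read order and reproducible", {
  g <- toy_genome(5000, seed = 53)
  idx <- build_index(g, 10)
  sim <- simulate_reads(g, 60, 80, sub_rate = 0.02, seed = 54)
  rec1 <- map_reads(sim$reads, idx, mapping_params())
  rec2 <- map_reads(sim$reads, idx, mapping_params())
  expect_identical(as.data.frame(rec1), as.data.frame(rec2))
  perm <- withr::with_seed(55, sample(nrow(sim$reads)))
  rec3 <- map_reads(sim$reads[perm, ], idx, mapping_params())
  a <- dplyr::arrange(rec1, read_id, ref_name, ref_start)
  b <- dplyr::arrange(rec3, read_id, ref_name, ref_start)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("mismap probability follows the seed-corruption model", {
  expect_equal(estimate_mismap_probability(100, 10, 0), 0)
  q <- 1 - 0.99^10
  expect_equal(estimate_mismap_probability(100, 10, 0.01), q^10)
  expect_equal(estimate_mismap_probability(100, 10, 0.01), 6.43e-11,
               tolerance = 5e-3)
  expect_equal(estimate_mismap_probability(50, 50, 0.02), 1 - 0.98^50)
  expect_error(estimate_mismap_probability(100, 10, 1), "\\[0, 1\\)")
  expect_error(estimate_mismap_probability(8, 10, 0.1), "read_length")
})

test_that("mapping parameters are validated", {
  expect_error(mapping_params(seed_length = 5), "\\[6, 14\\]")
  expect_error(mapping_params(max_errors = 3, error_percent = 0.05),
               "exactly one")
  expect_error(mapping_params(error_percent = 1.2), "error_percent")
  expect_equal(mapping_params(allow_indels = FALSE)$indel_band, 0L)
})
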