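test_that("Fisher's exact test matches enumeration and conventions", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1.0)
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 0, 0, 0), 1.0)
  expect_equal(fisher_exact_2x2(0, 5, 0, 7), 1.0)  # zero margin
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p-values agree with stats::fisher.test", {
  tables <- withr::with_seed(61, {
    lapply(1:60, function(i) sample(0:12, 4, replace = TRUE))
  })
  for (tb in tables) {
    a <- tb[1]; b <- tb[2]; c <- tb[3]; d <- tb[4]
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    ours <- fisher_exact_2x2(a, b, c, d)
    ref <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("Fisher p-values agree with direct hypergeometric enumeration", {
  # independent oracle: enumerate all tables with the observed margins
  enum_p <- function(a, b, c, d) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    xs <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- stats::dhyper(xs, r1, n - r1, c1)
    obs <- stats::dhyper(a, r1, n - r1, c1)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  for (tb in list(c(3, 7, 9, 1), c(10, 0, 3, 12), c(2, 2, 2, 2),
                  c(1, 14, 13, 2), c(8, 4, 4, 8), c(20, 5, 2, 18))) {
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 enum_p(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-9)
  }
})

make_uniform_records <- function(g, n = 10, L = 100, start = 0L) {
  # n identical error-free reads covering [start, start+L)
  tibble::tibble(
    read_id = sprintf("r%02d", seq_len(n)), status = "unique", reason = "",
    ref_name = g$name[1], strand = "+", ref_start = start,
    ref_end = start + L, mismatches = 0L, edit_distance = 0L,
    alignment = paste0(L, "="), n_best = 1L)
}

test_that("pileup counts bases, mismatches, deletions and insertions", {
  g <- toy_genome(300, seed = 63)
  rec <- make_uniform_records(g, n = 10, L = 100)
  pu <- build_pileup(rec, g)
  td <- tidy(pu)
  expect_equal(nrow(td), 100)
  expect_true(all(td$depth == 10))
  refbase <- strsplit(substring(g$sequence, 1, 100), "")[[1]]
  counted <- mapply(function(b, i) {
    pu$counts[[1]][b, i]
  }, refbase, 1:100)
  expect_true(all(counted == 10))

  # 6 reads showing G and 4 showing T at site 51 (1-based)
  base51 <- substring(g$sequence, 51, 51)
  alt_rec <- make_uniform_records(g, n = 10, L = 100)
  seen <- rep(c("G", "T"), c(6, 4))
  alt_rec$alignment <- paste0("50=X", seen, "49=")
  pu2 <- build_pileup(alt_rec, g)
  site <- pileup_at(pu2, g$name[1], 51)
  expect_equal(site$G, 6L)
  expect_equal(site$T, 4L)
  expect_equal(site$depth, 10L)

  # a read with a 1-nt deletion contributes a del count at the deleted
  # position (site chosen so left-normalization cannot shift it)
  bases <- strsplit(g$sequence, "")[[1]]
  dpos <- which(bases[20:60] != bases[19:59])[1] + 19L  # 1-based, != left nb
  del_rec <- make_uniform_records(g, n = 1, L = 100)
  del_rec$alignment <- paste0(dpos - 1L, "=1D", 100 - dpos + 1L, "=")
  del_rec$ref_end <- 101L
  pu3 <- build_pileup(del_rec, g)
  expect_equal(pileup_at(pu3, g$name[1], dpos)$del, 1L)
  expect_equal(pileup_at(pu3, g$name[1], dpos)$depth, 1L)

  # an insertion is anchored at the preceding reference base; the inserted
  # sequence ends in a base different from the anchor so it cannot shift
  anchor <- 30L
  ins_seq <- paste0("A", setdiff(c("A", "C", "G", "T"), bases[anchor])[1])
  ins_rec <- make_uniform_records(g, n = 1, L = 100)
  ins_rec$alignment <- paste0("30=I", ins_seq, "68=")
  ins_rec$ref_end <- 98L
  pu4 <- build_pileup(ins_rec, g)
  expect_equal(pu4$insertions$position, anchor)
  expect_equal(pu4$insertions$sequence, ins_seq)
  expect_equal(pu4$insertions$count, 1L)
})

test_that("pileup_at validates its site argument", {
  g <- toy_genome(200, seed = 65)
  pu <- build_pileup(make_uniform_records(g, n = 2, L = 50), g)
  expect_error(pileup_at(pu, "chrX", 10), "unknown reference")
  expect_error(pileup_at(pu, g$name[1], 0), "1-based")
  expect_error(pileup_at(pu, g$name[1], 999), "1-based")
  uncovered <- pileup_at(pu, g$name[1], 180)
  expect_equal(uncovered$depth, 0L)
})

test_that("multi-mapped reads are excluded from the pileup", {
  g <- toy_genome(300, seed = 67)
  rec <- make_uniform_records(g, n = 4, L = 60)
  rec$status[3:4] <- "multi"
  pu <- build_pileup(rec, g)
  expect_equal(pileup_at(pu, g$name[1], 10)$depth, 2L)
  expect_equal(pu$n_reads, 2L)
})

test_that("variant calling detects a strong SNV and respects thresholds", {
  g <- toy_genome(400, seed = 69)
  rec <- make_uniform_records(g, n = 50, L = 100)
  base60 <- substring(g$sequence, 60, 60)
  alt <- setdiff(c("A", "C", "G", "T"), base60)[1]
  rec$alignment[1:25] <- paste0("59=X", alt, "40=")
  pu <- build_pileup(rec, g)
  calls <- call_variants(pu, g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$position, 60L)
  expect_equal(calls$ref_allele, base60)
  expect_equal(calls$alt_allele, alt)
  expect_equal(calls$type, "snv")
  expect_equal(calls$alt_count, 25L)
  expect_equal(calls$depth, 50L)
  expect_lt(calls$p_value, 0.01)
  expect_equal(calls$genotype, "het")
  # the p-value matches the explicit construction
  expect_equal(calls$p_value,
               fisher_exact_2x2(25, 25, round(0.01 * 50), 50 - round(0.01 * 50)))

  # a single alt observation fails min_alt
  rec2 <- make_uniform_records(g, n = 50, L = 100)
  rec2$alignment[1] <- paste0("59=X", alt, "40=")
  expect_equal(nrow(call_variants(build_pileup(rec2, g), g)), 0)

  # an error-free pileup yields no calls
  expect_equal(nrow(call_variants(pu <- build_pileup(
    make_uniform_records(g, n = 30, L = 100), g), g)), 0)
})

test_that("deletion and insertion events are called and merged", {
  g <- toy_genome(400, seed = 71)
  bases <- strsplit(g$sequence, "")[[1]]
  # 2-nt deletion at a site where left-normalization cannot shift it
  dpos <- which(bases[40:70] != bases[42:72])[1] + 40L  # 1-based start
  rec <- make_uniform_records(g, n = 30, L = 100)
  rec$alignment[1:15] <- paste0(dpos - 1L, "=2D", 100 - dpos - 1L, "=")
  pu <- build_pileup(rec, g)
  calls <- call_variants(pu, g)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "del")
  expect_equal(calls$position, dpos)
  expect_equal(calls$ref_allele, substring(g$sequence, dpos, dpos + 1L))
  expect_equal(calls$alt_count, 15L)

  ins_seq <- paste0("T", setdiff(c("A", "C", "G", "T"), bases[70])[1])
  rec2 <- make_uniform_records(g, n = 30, L = 100)
  rec2$alignment[1:12] <- paste0("70=I", ins_seq, "30=")
  calls2 <- call_variants(build_pileup(rec2, g), g)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$type, "ins")
  expect_equal(calls2$position, 70L)
  expect_equal(calls2$alt_allele, ins_seq)
  expect_equal(calls2$alt_count, 12L)
})

test_that("hom/het genotype flag follows the alt fraction", {
  g <- toy_genome(300, seed = 73)
  rec <- make_uniform_records(g, n = 40, L = 100)
  base20 <- substring(g$sequence, 20, 20)
  alt <- setdiff(c("A", "C", "G", "T"), base20)[1]
  rec$alignment <- paste0("19=X", alt, "80=")  # all 40 reads
  calls <- call_variants(build_pileup(rec, g), g)
  expect_equal(calls$genotype, "hom")
})
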