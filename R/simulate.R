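#' Simulate a random genome, optionally with planted repeats
#'
#' Bases are drawn i.i.d. at the requested GC content; optionally,
#' `n_repeats` distinct repeat units of `unit_length` nt are each copied
#' verbatim to `copies` random non-overlapping positions, giving the
#' repeat-containing genomes on which unique/multi classification is
#' exercised. Deterministic under `seed` (the RNG state of the session is
#' left untouched).
#'
#' @param length Genome length in nt.
#' @param gc GC content in `[0, 1]` (default 0.5).
#' @param repeat_spec `NULL`, or a list/vector `(n_repeats, unit_length,
#'   copies)`.
#' @param seed Integer seed.
#' @param name Reference name (default `"chr1"`).
#' @return A reference-set tibble with one entry.
#' @export
simulate_genome <- function(length, gc = 0.5, repeat_spec = NULL, seed = 1L,
                            name = "chr1") {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(probs), length, replace = TRUE, prob = probs)
    if (!is.null(repeat_spec)) {
      rs <- as.list(repeat_spec)
      names(rs) <- NULL
      n_repeats <- rs[[1]]; unit_length <- rs[[2]]; copies <- rs[[3]]
      total <- n_repeats * unit_length * copies
      if (total > length)
        stop("infeasible repeat packing: units do not fit the genome")
      # place all copies at non-overlapping random positions
      occupied <- integer(0)
      for (u in seq_len(n_repeats)) {
        unit <- sample(c("A", "C", "G", "T"), unit_length, replace = TRUE,
                       prob = probs)
        placed <- 0
        tries <- 0
        while (placed < copies) {
          if ((tries <- tries + 1) > 1000 * copies)
            stop("infeasible repeat packing: could not place all copies")
          start <- sample.int(length - unit_length + 1L, 1)
          span <- start:(start + unit_length - 1L)
          if (any(span %in% occupied)) next
          bases[span] <- unit
          occupied <- c(occupied, span)
          placed <- placed + 1
        }
      }
    }
    reference_set(name, paste(bases, collapse = ""))
  })
}

#' Simulate reads with substitution and indel errors plus ground truth
#'
#' Reads are drawn with uniform start positions and strands (start-position
#' propensity per reference given by `weights`, length-proportional by
#' default; pass abundance-weighted values to emulate an RNA-seq library).
#' Fixed read length emulates Illumina-like data; a `c(min, max)` range
#' emulates variable-length Ion-Torrent-like data. Each base substitutes
#' with probability `sub_rate` to a uniformly different base; insertion and
#' deletion events open at the stated per-base rates with lengths
#' `1 + Geometric(1/2)` capped at 3 nt. Reads are built by walking the
#' reference, so every emitted read has exactly the requested length even
#' when indels are applied. Deterministic under `seed`.
#'
#' @param refs Reference-set tibble.
#' @param n Number of reads.
#' @param read_length A single integer, or `c(min, max)` for
#'   variable-length reads (uniform over the range).
#' @param sub_rate,ins_rate,del_rate Per-base error rates in `[0, 1)`.
#' @param seed Integer seed.
#' @param weights Optional per-reference sampling propensity (default:
#'   reference length).
#' @return A list with `reads` (tibble `id`, `sequence`, `quality`) and
#'   `truth` (tibble `read_id`, `true_reference`, `true_start` 0-based,
#'   `strand`, `n_substitutions`, `n_ins_bases`, `n_del_bases`,
#'   `read_length`).
#' @export
simulate_reads <- function(refs, n, read_length, sub_rate = 0,
                           ins_rate = 0, del_rate = 0, seed = 1L,
                           weights = NULL) {
  refs <- check_reference_set(refs)
  stopifnot(n >= 0, sub_rate >= 0, sub_rate < 1, ins_rate >= 0,
            ins_rate < 1, del_rate >= 0, del_rate < 1)
  lmin <- as.integer(min(read_length))
  lmax <- as.integer(max(read_length))
  if (lmax > min(refs$length))
    stop("read_length exceeds the shortest reference")
  if (n == 0) {
    return(list(
      reads = tibble::tibble(id = character(), sequence = character(),
                             quality = character()),
      truth = tibble::tibble(read_id = character(),
                             true_reference = character(),
                             true_start = integer(), strand = character(),
                             n_substitutions = integer(),
                             n_ins_bases = integer(),
                             n_del_bases = integer(),
                             read_length = integer())))
  }
  withr::with_seed(seed, {
    if (is.null(weights)) weights <- refs$length
    ref_i <- sample.int(nrow(refs), n, replace = TRUE, prob = weights)
    L <- if (lmin == lmax) rep.int(lmin, n) else
      sample(lmin:lmax, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # per-read edit plan: substitution count and indel event counts are
    # binomial over read positions at the nominal rates
    nsub <- rbinom(n, L, sub_rate)
    nins <- rbinom(n, L, ins_rate)
    ndel <- rbinom(n, L, del_rate)
    # window slack covers the extra reference consumed by deletions
    slack <- pmin(3L * ndel, pmax(refs$length[ref_i] - L, 0L))
    start <- floor(runif(n) * (refs$length[ref_i] - L - slack + 1))
    windows <- substring(refs$sequence[ref_i], start + 1, start + L + slack)
    seqs <- character(n)
    subs_out <- integer(n)
    insb_out <- integer(n)
    delb_out <- integer(n)
    plain <- which(nsub == 0 & nins == 0 & ndel == 0)
    seqs[plain] <- substring(windows[plain], 1, L[plain])
    edited <- setdiff(seq_len(n), plain)
    indel_len <- function(k) pmin(1L + rgeom(k, 0.5), 3L)
    for (k in edited) {
      w <- strsplit(windows[k], "")[[1]]
      target <- L[k]
      sub_set <- sample.int(target, nsub[k])
      ins_at <- sample.int(target, nins[k])
      ins_len <- indel_len(nins[k])
      del_at <- sample.int(target, ndel[k])
      del_len <- indel_len(ndel[k])
      out <- character(target)
      nsub_k <- 0L; insb_k <- 0L; delb_k <- 0L
      i <- 1L  # reference walk pointer
      pos <- 1L  # read position being emitted
      while (pos <= target) {
        dj <- match(pos, del_at)
        if (!is.na(dj)) {
          i <- i + del_len[dj]
          delb_k <- delb_k + del_len[dj]
          del_at[dj] <- NA_integer_
        }
        ij <- match(pos, ins_at)
        if (!is.na(ij)) {
          il <- min(ins_len[ij], target - pos + 1L)
          out[pos:(pos + il - 1L)] <-
            sample(c("A", "C", "G", "T"), il, replace = TRUE)
          insb_k <- insb_k + il
          pos <- pos + il
          ins_at[ij] <- NA_integer_
          next
        }
        b <- if (i <= length(w)) w[i] else "A"  # pad past reference end
        i <- i + 1L
        if (pos %in% sub_set) {
          b <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
          nsub_k <- nsub_k + 1L
        }
        out[pos] <- b
        pos <- pos + 1L
      }
      seqs[k] <- paste(out, collapse = "")
      subs_out[k] <- nsub_k
      insb_out[k] <- insb_k
      delb_out[k] <- delb_k
    }
    minus <- which(strand == "-")
    if (length(minus) > 0)
      seqs[minus] <- reverse_complement(seqs[minus])
    ids <- sprintf("sim_%06d", seq_len(n))
    list(
      reads = tibble::tibble(id = ids, sequence = seqs,
                             quality = strrep("I", nchar(seqs))),
      truth = tibble::tibble(read_id = ids,
                             true_reference = refs$name[ref_i],
                             true_start = as.integer(start),
                             strand = strand,
                             n_substitutions = subs_out,
                             n_ins_bases = insb_out,
                             n_del_bases = delb_out,
                             read_length = as.integer(nchar(seqs))))
  })
}

#' Plant homozygous variants into a reference, yielding a donor genome
#'
#' Returns the donor sequence (reference with the variants applied) and
#' the truth table in reference coordinates. Variants are kept at least
#' `min_gap` nt apart and `edge` nt from the sequence ends so that planted
#' sites have full read coverage and merged events cannot collide.
#'
#' @param refs Reference-set tibble (single entry or more).
#' @param n_snv Number of SNVs.
#' @param n_ins Number of insertions (lengths 1-2 nt).
#' @param n_del Number of deletions (lengths 1-2 nt).
#' @param seed Integer seed.
#' @param min_gap Minimum spacing between planted sites (default 50).
#' @param edge Exclusion zone at sequence ends (default 200).
#' @return List with `donor` (reference-set tibble of mutated sequences)
#'   and `truth` (tibble `ref_name`, `position` 1-based, `type`,
#'   `ref_allele`, `alt_allele`).
#' @export
plant_variants <- function(refs, n_snv, n_ins = 0L, n_del = 0L, seed = 1L,
                           min_gap = 50L, edge = 200L) {
  refs <- check_reference_set(refs)
  withr::with_seed(seed, {
    total <- n_snv + n_ins + n_del
    # distribute sites over references proportionally to length
    ref_pick <- sample.int(nrow(refs), total, replace = TRUE,
                           prob = refs$length)
    truth <- list()
    donor_seqs <- refs$sequence
    for (r in seq_len(nrow(refs))) {
      k <- sum(ref_pick == r)
      if (k == 0) next
      Lr <- refs$length[r]
      lo <- edge + 1L
      hi <- Lr - edge
      if (hi - lo + 1 < k * min_gap)
        stop("reference too short to plant the requested variants")
      # greedy spacing: draw candidates, keep those >= min_gap apart
      cand <- sort(sample(seq(lo, hi), min(hi - lo + 1L, k * 20L)))
      keep <- integer(0)
      last <- -Inf
      for (p in cand) {
        if (p - last >= min_gap) {
          keep <- c(keep, p)
          last <- p
        }
      }
      if (length(keep) < k)
        stop("reference too short to plant the requested variants")
      pos <- sort(sample(keep, k))
      types <- sample(c(rep("snv", n_snv), rep("ins", n_ins),
                        rep("del", n_del)))[ref_pick == r]
      base_at <- function(s, i) substring(s, i, i)
      refseq <- refs$sequence[r]
      entries <- lapply(seq_len(k), function(j) {
        p <- pos[j]
        if (types[j] == "snv") {
          rb <- base_at(refseq, p)
          ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
          tibble::tibble(ref_name = refs$name[r], position = p,
                         type = "snv", ref_allele = rb, alt_allele = ab)
        } else if (types[j] == "ins") {
          len <- sample(1:2, 1)
          ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
          tibble::tibble(ref_name = refs$name[r], position = p,
                         type = "ins", ref_allele = base_at(refseq, p),
                         alt_allele = ins)
        } else {
          len <- sample(1:2, 1)
          tibble::tibble(ref_name = refs$name[r], position = p + 1L,
                         type = "del",
                         ref_allele = substring(refseq, p + 1L, p + len),
                         alt_allele = "-")
        }
      })
      tt <- dplyr::bind_rows(entries)
      truth[[length(truth) + 1]] <- tt
      # apply right-to-left so earlier coordinates stay valid
      s <- refseq
      for (j in rev(seq_len(nrow(tt)))) {
        p <- tt$position[j]
        if (tt$type[j] == "snv") {
          substring(s, p, p) <- tt$alt_allele[j]
        } else if (tt$type[j] == "ins") {
          s <- paste0(substring(s, 1, p), tt$alt_allele[j],
                      substring(s, p + 1))
        } else {
          dl <- nchar(tt$ref_allele[j])
          s <- paste0(substring(s, 1, p - 1), substring(s, p + dl))
        }
      }
      donor_seqs[r] <- s
    }
    list(donor = reference_set(refs$name, donor_seqs),
         truth = dplyr::arrange(dplyr::bind_rows(truth), .data$ref_name,
                                .data$position))
  })
}

#' Score a mapping run against simulation ground truth
#'
#' A uniquely mapped read is correctly placed iff it is on the true
#' reference and strand with `|ref_start - true_start| <= tolerance`.
#' Multi-mapped reads are scored separately (correct if any reported
#' location matches) and excluded from the mismap denominator.
#'
#' @param records Mapping-record tibble.
#' @param truth Truth tibble from [simulate_reads()].
#' @param tolerance Placement tolerance in nt (default 5, the default
#'   indel band).
#' @return One-row tibble: `total`, `mapped_unique`, `mapped_multi`,
#'   `unmapped`, `unique_correct`, `multi_correct`, `sensitivity`
#'   (correctly placed unique / total simulated), `mismap_rate` (wrongly
#'   placed unique / mapped unique), `tolerance`.
#' @export
evaluate_mapping <- function(records, truth, tolerance = 5L) {
  per_read <- dplyr::distinct(records, .data$read_id, .data$status)
  orphans <- union(setdiff(per_read$read_id, truth$read_id),
                   setdiff(truth$read_id, per_read$read_id))
  if (length(orphans) > 0)
    stop("read ids disagree between records and truth: ",
         paste(head(orphans, 5), collapse = ", "))
  aln <- dplyr::filter(records, .data$status != "unmapped")
  aln <- dplyr::left_join(
    aln, truth, by = "read_id", suffix = c("", "_truth"))
  aln$hit <- aln$ref_name == aln$true_reference &
    aln$strand == aln$strand_truth &
    abs(aln$ref_start - aln$true_start) <= tolerance
  by_read <- dplyr::summarise(
    dplyr::group_by(aln, .data$read_id, .data$status),
    correct = any(.data$hit), .groups = "drop")
  n_total <- nrow(truth)
  n_unique <- sum(per_read$status == "unique")
  n_multi <- sum(per_read$status == "multi")
  n_unmapped <- sum(per_read$status == "unmapped")
  uq <- dplyr::filter(by_read, .data$status == "unique")
  mu <- dplyr::filter(by_read, .data$status == "multi")
  tibble::tibble(
    total = n_total,
    mapped_unique = n_unique,
    mapped_multi = n_multi,
    unmapped = n_unmapped,
    unique_correct = sum(uq$correct),
    multi_correct = sum(mu$correct),
    sensitivity = if (n_total == 0) 0 else sum(uq$correct) / n_total,
    mismap_rate = if (n_unique == 0) 0 else
      sum(!uq$correct) / n_unique,
    tolerance = as.integer(tolerance))
}
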