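#' Build a per-position pile-up from uniquely mapped reads
#'
#' Each uniquely mapped read contributes one count per reference position it
#' covers, following its edit transcript: matches and mismatches increment
#' the observed base, deletions increment a deletion count at every deleted
#' position, and insertions are recorded as events anchored at the
#' reference base preceding the insertion. Multi-mapped and unmapped
#' records are ignored — only reads with a single best location are
#' trustworthy evidence for a site.
#'
#' @param records Mapping-record tibble ([map_reads()] or
#'   [read_mapping_records()]).
#' @param refs Reference-set tibble the records were mapped against.
#' @return An object of class `pileup`: per-reference 6 x L count matrices
#'   (rows `A,C,G,T,N,del`) plus an insertion-event table.
#' @export
build_pileup <- function(records, refs) {
  refs <- check_reference_set(refs)
  uq <- dplyr::filter(records, .data$status == "unique")
  idx <- match(uq$ref_name, refs$name)
  if (anyNA(idx)) stop("record references unknown sequence")
  res <- cpp_build_pileup(refs$sequence, idx - 1L, uq$ref_start,
                          uq$alignment)
  counts <- res$counts
  names(counts) <- refs$name
  for (i in seq_along(counts)) rownames(counts[[i]]) <-
    c("A", "C", "G", "T", "N", "del")
  ins <- tibble::tibble(ref_name = refs$name[res$insertions$ref + 1L],
                        position = res$insertions$pos + 1L,
                        sequence = as.character(res$insertions$seq),
                        count = res$insertions$count)
  structure(list(counts = counts, insertions = ins,
                 ref_names = refs$name, ref_lengths = refs$length,
                 n_reads = nrow(uq)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("<pileup> over", length(x$counts), "reference(s) from", x$n_reads,
      "uniquely mapped reads;", nrow(x$insertions), "insertion event(s)\n")
  invisible(x)
}

#' Per-base counts at one site
#'
#' @param pileup A `pileup` object.
#' @param reference_name Reference name.
#' @param position 1-based position.
#' @return One-row tibble: `ref_name`, `position`, counts `A,C,G,T,N,del`,
#'   `depth`.
#' @export
pileup_at <- function(pileup, reference_name, position) {
  i <- match(reference_name, pileup$ref_names)
  if (is.na(i)) stop("unknown reference: ", reference_name)
  if (position < 1 || position > pileup$ref_lengths[i])
    stop("position out of range (1-based): ", position)
  v <- pileup$counts[[i]][, position]
  tibble::tibble(ref_name = reference_name, position = as.integer(position),
                 A = v[["A"]], C = v[["C"]], G = v[["G"]], T = v[["T"]],
                 N = v[["N"]], del = v[["del"]], depth = sum(v))
}

#' Tidy a pile-up into a long site table
#'
#' @param x A `pileup` object.
#' @param min_depth Only sites with depth at or above this are returned.
#' @param ... Unused.
#' @return Tibble: `ref_name`, `position` (1-based), `A,C,G,T,N,del`,
#'   `depth`.
#' @method tidy pileup
#' @export
tidy.pileup <- function(x, min_depth = 1L, ...) {
  out <- lapply(seq_along(x$counts), function(i) {
    m <- x$counts[[i]]
    depth <- colSums(m)
    keep <- which(depth >= min_depth)
    if (length(keep) == 0) return(NULL)
    tibble::tibble(ref_name = x$ref_names[i], position = keep,
                   A = m["A", keep], C = m["C", keep], G = m["G", keep],
                   T = m["T", keep], N = m["N", keep],
                   del = m["del", keep], depth = depth[keep])
  })
  dplyr::bind_rows(out)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[[a, b], [c, d]]`, computed by
#' summing, in log space, the hypergeometric probabilities of all tables
#' with the same margins whose point probability does not exceed that of
#' the observed table (relative tolerance 1e-7, the usual convention). Any
#' zero margin returns 1 by convention.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)  # 2 / choose(10, 5)
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1.0)
  lp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  lps <- lp(xs)
  lobs <- lp(a)
  keep <- lps <= lobs + log(1 + 1e-7)
  m <- max(lps[keep])
  min(1, exp(m + log(sum(exp(lps[keep] - m)))))
}

#' Call variants from a pile-up
#'
#' At every site with depth `N >= min_depth`, the most frequent
#' non-reference base (and any deletion/insertion event meeting the same
#' thresholds) with count `k >= min_alt` is tested against the expectation
#' under a uniform sequencing-error model: the observed column `(k, N - k)`
#' versus the error expectation `(round(error_rate * N),
#' N - round(error_rate * N))` by [fisher_exact_2x2()]. A call is emitted
#' when `p <= alpha` and the alt fraction exceeds `5 * error_rate`. A
#' het/hom genotype flag (alt fraction cutoffs 0.2/0.8) is informational
#' only. Runs of adjacent called deletion positions are merged into one
#' multi-base deletion.
#'
#' @param pileup A `pileup` object built from uniquely mapped reads.
#' @param refs Reference-set tibble.
#' @param error_rate Assumed per-base sequencing error rate (default 0.01).
#' @param alpha Significance threshold on the Fisher p-value (default 0.01).
#' @param min_depth Minimum site depth (default 10).
#' @param min_alt Minimum alt observation count (default 3).
#' @return Tibble of calls sorted by coordinate: `ref_name`, `position`
#'   (1-based), `ref_allele`, `alt_allele`, `type` (`snv`/`ins`/`del`),
#'   `alt_count`, `depth`, `p_value`, `genotype`.
#' @export
call_variants <- function(pileup, refs, error_rate = 0.01, alpha = 0.01,
                          min_depth = 10L, min_alt = 3L) {
  refs <- check_reference_set(refs)
  stopifnot(inherits(pileup, "pileup"))
  out <- list()
  for (i in seq_along(pileup$counts)) {
    m <- pileup$counts[[i]]
    L <- ncol(m)
    if (L == 0) next
    refbase <- strsplit(refs$sequence[match(pileup$ref_names[i],
                                            refs$name)], "")[[1]]
    depth <- colSums(m)
    base_m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    # mask the reference base, find the top non-reference base per site
    ref_row <- match(refbase, c("A", "C", "G", "T"))  # NA at reference N
    masked <- base_m
    ok <- !is.na(ref_row)
    masked[cbind(ref_row[ok], which(ok))] <- -1L
    top <- max.col(t(masked), ties.method = "first")
    alt_count <- masked[cbind(top, seq_len(L))]
    alt_base <- c("A", "C", "G", "T")[top]
    cand <- which(depth >= min_depth & alt_count >= min_alt & ok)
    snv <- test_sites(pileup$ref_names[i], cand, refbase[cand],
                      alt_base[cand], alt_count[cand], depth[cand],
                      "snv", error_rate, alpha, min_alt)
    del_cand <- which(depth >= min_depth & m["del", ] >= min_alt)
    del <- test_sites(pileup$ref_names[i], del_cand, refbase[del_cand],
                      "-", m["del", del_cand], depth[del_cand], "del",
                      error_rate, alpha, min_alt)
    del <- merge_deletion_runs(del, refbase)
    out[[length(out) + 1]] <- dplyr::bind_rows(snv, del)
  }
  ins <- pileup$insertions
  if (nrow(ins) > 0) {
    # depth at the anchor base
    anchor_depth <- vapply(seq_len(nrow(ins)), function(k) {
      i <- match(ins$ref_name[k], pileup$ref_names)
      sum(pileup$counts[[i]][, ins$position[k]])
    }, numeric(1))
    keep <- which(anchor_depth >= min_depth & ins$count >= min_alt)
    if (length(keep) > 0) {
      ref_i <- match(ins$ref_name[keep], refs$name)
      anchor_base <- substring(refs$sequence[ref_i], ins$position[keep],
                               ins$position[keep])
      out[[length(out) + 1]] <- test_sites(
        ins$ref_name[keep], ins$position[keep], anchor_base,
        ins$sequence[keep], ins$count[keep], anchor_depth[keep], "ins",
        error_rate, alpha, min_alt)
    }
  }
  calls <- dplyr::bind_rows(out)
  if (nrow(calls) == 0) {
    return(tibble::tibble(ref_name = character(), position = integer(),
                          ref_allele = character(), alt_allele = character(),
                          type = character(), alt_count = integer(),
                          depth = integer(), p_value = numeric(),
                          genotype = character()))
  }
  dplyr::arrange(calls, .data$ref_name, .data$position, .data$type)
}

# Fisher test of (k, N-k) against the error expectation, shared by all
# variant types. `positions` are 1-based already.
test_sites <- function(ref_name, positions, ref_allele, alt_allele, k, N,
                       type, error_rate, alpha, min_alt) {
  if (length(positions) == 0) {
    return(tibble::tibble(ref_name = character(), position = integer(),
                          ref_allele = character(), alt_allele = character(),
                          type = character(), alt_count = integer(),
                          depth = integer(), p_value = numeric(),
                          genotype = character()))
  }
  exp_err <- round(error_rate * N)
  p <- vapply(seq_along(positions), function(j) {
    fisher_exact_2x2(k[j], N[j] - k[j], exp_err[j], N[j] - exp_err[j])
  }, numeric(1))
  frac <- k / N
  keep <- which(p <= alpha & frac > error_rate * 5)
  tibble::tibble(
    ref_name = rep_len(ref_name, length(positions))[keep],
    position = as.integer(positions[keep]),
    ref_allele = as.character(ref_allele)[keep],
    alt_allele = as.character(alt_allele)[keep],
    type = type, alt_count = as.integer(k[keep]),
    depth = as.integer(N[keep]), p_value = p[keep],
    genotype = ifelse(frac[keep] >= 0.8, "hom",
                      ifelse(frac[keep] >= 0.2, "het", "lowfrac")))
}

# Adjacent per-position deletion calls are one physical event: merge runs,
# keeping the run's conservative support (min count, max p).
merge_deletion_runs <- function(del, refbase) {
  if (nrow(del) <= 1) {
    if (nrow(del) == 1)
      del$ref_allele <- refbase[del$position]
    return(del)
  }
  del <- dplyr::arrange(del, .data$position)
  run <- cumsum(c(1L, diff(del$position) != 1L))
  parts <- split(seq_len(nrow(del)), run)
  rows <- lapply(parts, function(ix) {
    first <- ix[1]
    span <- del$position[ix]
    tibble::tibble(
      ref_name = del$ref_name[first], position = del$position[first],
      ref_allele = paste(refbase[span], collapse = ""),
      alt_allele = "-", type = "del",
      alt_count = min(del$alt_count[ix]),
      depth = max(del$depth[ix]), p_value = max(del$p_value[ix]),
      genotype = del$genotype[first])
  })
  dplyr::bind_rows(rows)
}
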