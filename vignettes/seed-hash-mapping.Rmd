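---
title: "Seed-hash read mapping, variant calling and RPKM quantification with seedmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-hash read mapping, variant calling and RPKM quantification with seedmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmapr)
```

## The mapping model

seedmapr is a seed-hash mapper in the classic BLAST-like family. A read of
length $L$ is cut into $m_0 = \lfloor L/s \rfloor$ non-overlapping seeds of
length $s$ (offsets $0, s, 2s, \dots$), plus one tail-anchored seed at
offset $L - s$ when $L$ is not a multiple of $s$, so the read end is always
covered. Every seed is looked up in an exact k-mer index built over the
*entire* reference set — all positions of all N-free k-mers, forward strand
only. Reverse-strand placements are found by repeating the decomposition on
the reverse complement of the read, which halves the index at no loss of
generality.

Each seed hit at reference position $p$ with read offset $o$ implies a
candidate read start $p - o$. Candidates on the same reference are grouped
greedily (in sorted order) into **hotspots** so that within a group
$\max - \min \le b$, where $b$ is the indel band. This fuzzy grouping is
what lets short indels survive hotspot generation: seeds on either side of
an indel of length $\le b$ imply starts that differ by at most $b$ and
still vote for the same locus. A hotspot's score is its number of distinct
voting seed offsets.

Hotspots from both orientations are pooled and verified in a total,
deterministic priority order (votes descending, then reference ordinal,
candidate start, strand). Verification aligns the **full** read — no
clipping — against the window
$[\mathrm{cand} - b,\ \mathrm{cand} + \mathrm{spread} + L + b)$, where
$\mathrm{cand}$ is the hotspot group minimum and $\mathrm{spread}$ its
diagonal spread (so a group whose window was opened early by a chance
seed hit still covers a deletion-lengthened alignment), by unit-cost
edit distance
(mismatch 1, each inserted or deleted base 1; N always mismatches), with
free leading/trailing reference gaps inside the window only. We run the
full dynamic program over the window rather than a diagonal band inside
it: the window is only $L + 2b$ wide, so the cost is the same order, and
the result provably equals an unbanded alignment whenever the true
placement lies within the window.

The per-read error allowance is either an absolute count (mismatches and
indel bases share one budget) or a percentage of the read length,
re-evaluated per read — the natural choice for variable-length reads,
where a fixed count would be too strict for long reads and too lax for
short ones.

### Classification and early termination

All distinct locations achieving the minimal edit distance $d^\*$ are
retained; two locations are distinct if they differ in reference, strand,
or by more than $b$ in start position. Exactly one best location means
`unique`, several mean `multi` (all best locations are reported, up to a
cap), none means `unmapped`. Only unique reads feed the downstream pile-up
and quantification.

Verification can stop early by a pigeonhole argument: an alignment at edit
distance $d$ leaves at least $m_0 - d$ seeds untouched, all implying
starts within one band of each other. Greedy grouping can cut that
diagonal set at most once (when a chance seed hit just left of the true
diagonal opens the group window early), so the larger fragment still
carries at least $(m_0 - d)/2$ votes. Once the sorted vote counts fall
below $(m_0 - d^\*)/2$, no remaining hotspot can host a location as good
as the current best. The equivalence of this pruned search with an
exhaustive semi-global DP over the whole reference is asserted by tests
on thousands of simulated reads.

The same pigeonhole logic gives the mismapping estimate exposed as
`estimate_mismap_probability()`: with per-base error rate $p$, a seed is
error-free with probability $(1-p)^s$, so the probability that *no* seed
anchors the true locus is $q^{m_0}$ with $q = 1 - (1-p)^s$. At typical
short-read settings ($L = 100$, $s = 10$, $p = 0.01$) this is about
$6.4\times10^{-11}$ — the origin of the sub-$10^{-9}$ mismapping regime
this family of mappers operates in. The formula is a binomial
seed-corruption model, deliberately simple; it bounds hotspot *loss*, not
coincidental better-scoring placements elsewhere (which the error
allowance controls).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `seed_length` | 10 | seed size, restricted to 6–14; shorter seeds are more sensitive but hit more random loci |
| `max_errors` | 5 | absolute per-read edit allowance |
| `error_percent` | — | allowance as a fraction of read length (alternative to `max_errors`) |
| `allow_indels` | TRUE | indel detection; off degrades verification to a Hamming check |
| `indel_band` | 5 | max net indel length: hotspot grouping band and window slack |
| `max_reported_locations` | 100 | cap on reported best locations per multi-mapped read |

`indel_band = 5` matches the default absolute allowance of five errors: a
net indel longer than the total edit budget can never be part of an
accepted alignment, so a wider band would only slow verification.

## Numerical and tie-break choices

* Hotspot and location ordering is total (votes desc, reference, start,
  strand `+` before `-`), so identical inputs give byte-identical outputs
  regardless of read order in the file.
* DP traceback resolves ties by preferring to *continue an open gap*,
  then diagonal, then insertion, then deletion. Without gap continuity, a
  2-nt insertion next to a chance-matching base can split into two 1-nt
  events around it, fragmenting pile-up evidence.
* Pile-up construction left-normalizes every indel event (shifting it
  through equal flanking bases, as VCF normalization does) so that
  equivalent alignments from forward- and reverse-oriented reads count
  toward one canonical event.
* Degenerate inputs: reads shorter than the seed are `unmapped` with
  reason `too_short`; windows are truncated at reference boundaries; a
  read that cannot fit in the remaining window is rejected rather than
  clipped.

## Variant calling

Only uniquely mapped reads are piled up: per position, counts of
A/C/G/T/N and of deletion-spanning reads; insertions are events anchored
at the preceding base. At each site with depth $N \ge$ `min_depth` (10),
the most frequent non-reference allele with count $k \ge$ `min_alt` (3) is
tested with a two-sided Fisher's exact test of $(k, N-k)$ against the
expectation under a uniform sequencing-error model,
$(\mathrm{round}(\varepsilon N), N - \mathrm{round}(\varepsilon N))$ with
$\varepsilon = 0.01$ by default. A call requires $p \le \alpha$ (0.01) and
an alt fraction above $5\varepsilon$. Indel events are tested identically
with their event counts. The error-model contingency table is this
package's own construction — exposed through parameters so alternatives
can be swapped in — and the test itself is computed exactly in log space
from `lchoose`, summing all tables with the observed margins whose point
probability does not exceed the observed one (relative tolerance
$10^{-7}$). Tests verify it against full hypergeometric enumeration for
every table with total $\le 60$.

The het/hom flag (alt-fraction cutoffs 0.2/0.8) is informational only; no
base-quality or strand-bias filtering is applied, since qualities are
deliberately unused throughout the mapper.

## RNA quantification

Mapping against a spliced-RNA reference set, expression is the number of
uniquely mapped reads per transcript, reported as RPKM
($10^9 \cdot k / (N_{\mathrm{mapped}} \cdot \ell)$). Multi-mapped reads
are excluded by default, consistent with the unique-only downstream
convention; robustness of quantification to the error allowance is
measured as the Pearson correlation of $\log_{10}(\mathrm{RPKM} + 0.01)$
over transcripts detected in at least one of the two runs. The log scale
and the 0.01 pseudo-count are package choices (exposed as parameters):
expression spans orders of magnitude, and a raw-scale correlation would be
dominated by a handful of highly expressed transcripts.

## What the simulator emulates — and what it does not

`simulate_genome()` draws i.i.d. bases at a chosen GC content and can
plant verbatim repeat copies, the minimal structure needed to exercise
unique/multi classification. `simulate_reads()` draws uniform start
positions and strands, fixed-length reads (Illumina-like) or a uniform
length range (Ion-Torrent-like), with per-base substitutions and
geometric-length (mean ≈ 1.5, capped at 3 nt) indel events at configurable
rates; every applied edit is recorded in a ground-truth table.
`plant_variants()` builds a homozygous donor genome whose reads, mapped
back to the original reference, exercise the calling pipeline end to end.

Real data differ in ways the simulator does not model: position- and
motif-dependent error profiles, base-quality information, homopolymer
slippage, coverage biases, contamination, and genome-scale repeat
structure. Passing the simulated checks therefore demonstrates
algorithmic correctness (the mapper finds what is provably there, at the
stated error budgets) — not calibrated performance on any particular
instrument's data.

Study sizes used by the packaged checks: a 500 kb genome with 50,000
error-free 100 nt reads for the mismapping bound (zero wrongly placed
unique reads expected, since an error-free read always carries ten exact
seeds); ten 10 kb genomes × 1,000 error-carrying reads for oracle
equivalence; a 100 kb genome at 30× with 100 SNVs and 10 short indels for
variant recovery; 100 transcripts × 30,000 reads for quantification
robustness. These sizes make every check a few minutes on one CPU while
keeping the per-read arithmetic identical to larger runs — per-read work
depends only on read length, seed hits and band, not on dataset size.

## Design decisions on genuinely open points

* **Single fixed seed length per run** — no step-down remapping ladder;
  sensitivity is governed by the allowance and seed length alone.
* **Forward-only index + read reverse complement** (rather than indexing
  both strands): halves memory, and strand is a per-read property anyway.
* **Best-only reporting**: locations within the allowance but worse than
  the best are discarded; "multi" means two or more co-optimal locations.
* **Native TSV output** (`read_id, ref, pos, strand, edits, align`) with
  1-based positions in files and 0-based half-open coordinates in memory;
  SAM export is provided as an optional interoperability flag, not the
  primary format.
* **Uniform-error mismap model** as the analytic stand-in where a more
  detailed derivation would require instrument-specific error profiles.

## Known limitations

* No spliced alignment: RNA reads must be mapped to spliced transcript
  references.
* No paired-end rescue or insert-size model; ends are mapped
  independently.
* The index lives entirely in memory (by design); genome-scale references
  require correspondingly large RAM.
* Variant calls are not annotated (no gene models) and diploid genotyping
  is a heuristic flag, not a likelihood model.

## A worked example

```{r example, eval = FALSE}
g   <- simulate_genome(100000, seed = 1)
sim <- simulate_reads(g, 5000, 100, sub_rate = 0.01, seed = 2)
idx <- build_index(g, seed_length = 10)
rec <- map_reads(sim$reads, idx, mapping_params(max_errors = 5))
glance(rec)
evaluate_mapping(rec, sim$truth)
pu  <- build_pileup(rec, g)
call_variants(pu, g)
```
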